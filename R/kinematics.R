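#' Per-twitcher kinematics from two system states
#'
#' Reduces per-sphere positions to per-twitcher kinematic quantities: centre
#' of mass (mean of the four unwrapped sphere positions), velocity over the
#' elapsed `tau`, speed, unit direction of motion, polar (tail-to-head)
#' orientation and the canonical nematic director.
#'
#' @param state,prev_state either matrices `(4N, 2)` of unwrapped sphere
#'   positions (four consecutive rows per twitcher, row 1 = tail, row 4 =
#'   head) or lists with a `sphere_pos_unwrapped` field. The states must be
#'   `tau` apart.
#' @param tau elapsed time between the states.
#' @return A data frame with one row per twitcher: `com_x`, `com_y`, `v_x`,
#'   `v_y`, `speed`, `vhat_x`, `vhat_y` (NA when the speed is zero — the
#'   direction of motion is then undefined), `p_x`, `p_y`, `n_x`, `n_y`.
#' @examples
#' s0 <- matrix(c(0, 1, 2, 3, 0, 0, 0, 0), ncol = 2)
#' derive_kinematics(s0 + 0.5, s0)  # moved +0.5 in x over one tau
#' @export
derive_kinematics <- function(state, prev_state, tau = 1) {
  pos <- if (is.list(state)) state$sphere_pos_unwrapped else state
  prev <- if (is.list(prev_state)) prev_state$sphere_pos_unwrapped
          else prev_state
  if (!is.matrix(pos) || ncol(pos) != 2 || nrow(pos) %% 4 != 0)
    stop("state must provide a (4N, 2) matrix of unwrapped positions",
         call. = FALSE)
  if (!identical(dim(pos), dim(prev)))
    stop("states have mismatched twitcher counts", call. = FALSE)
  N <- nrow(pos) / 4
  g <- rep(seq_len(N), each = 4)
  com <- cbind(tapply(pos[, 1], g, mean), tapply(pos[, 2], g, mean))
  com_prev <- cbind(tapply(prev[, 1], g, mean), tapply(prev[, 2], g, mean))
  v <- (com - com_prev) / tau
  speed <- sqrt(rowSums(v^2))
  vhat <- v / speed
  vhat[speed == 0, ] <- NA_real_
  hd <- 4 * seq_len(N)
  tl <- hd - 3
  pv <- pos[hd, , drop = FALSE] - pos[tl, , drop = FALSE]
  pv <- pv / sqrt(rowSums(pv^2))
  nv <- canonical_director(pv)
  data.frame(com_x = com[, 1], com_y = com[, 2],
             v_x = v[, 1], v_y = v[, 2], speed = speed,
             vhat_x = vhat[, 1], vhat_y = vhat[, 2],
             p_x = pv[, 1], p_y = pv[, 2],
             n_x = nv[, 1], n_y = nv[, 2], row.names = NULL)
}

#' Canonical form of a headless director
#'
#' A nematic director is defined up to sign (`n` and `-n` are the same
#' alignment). This stores the representative with a non-negative
#' x-component (tie broken toward non-negative y), so that a director and
#' its negation map to the same vector.
#'
#' @param n a length-2 unit vector or a matrix with one director per row.
#' @return The canonicalised director(s), same shape as the input.
#' @export
canonical_director <- function(n) {
  m <- if (is.matrix(n)) n else matrix(n, nrow = 1)
  flip <- m[, 1] < 0 | (m[, 1] == 0 & m[, 2] < 0)
  m[flip, ] <- -m[flip, , drop = FALSE]
  if (is.matrix(n)) m else m[1, ]
}
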