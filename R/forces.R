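#' WCA excluded-volume potential
#'
#' Shifted, truncated Lennard-Jones (Weeks-Chandler-Andersen) potential
#' acting between every pair of integrated spheres, including bonded
#' neighbours: `V = 4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` for
#' `r < 2^(1/6) sigma`, zero beyond. Purely repulsive and continuous at the
#' cutoff.
#'
#' @param r pair separation(s), must be positive.
#' @param params a [twitch_params()] object.
#' @return A list with numeric vectors `energy` and `force` (the scalar
#'   magnitude `-dV/dr`, positive = repulsive).
#' @examples
#' wca(2^(1 / 6))$energy  # 0 at the cutoff
#' @export
wca <- function(r, params = twitch_params()) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("separation r must be positive", call. = FALSE)
  wca_ef_cpp(r, params$sigma, params$epsilon, params$wca_cutoff)
}

#' FENE bond potential
#'
#' Finitely extensible nonlinear elastic bond joining consecutive spheres of
#' a twitcher body: `V = -1/2 kF R0^2 ln(1 - (r/R0)^2)`. The restoring force
#' diverges as `r` approaches the maximum extension `R0`.
#'
#' @param r bond length(s); must satisfy `0 <= r < fene_R0`.
#' @param params a [twitch_params()] object.
#' @return A list with `energy` and `force` (attractive restoring magnitude).
#' @export
fene <- function(r, params = twitch_params()) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("bond length must be non-negative", call. = FALSE)
  if (any(r >= params$fene_R0))
    stop("FENE bond overstretched: r >= R0 = ", params$fene_R0,
         call. = FALSE)
  fene_ef_cpp(r, params$fene_R0, params$fene_kF)
}

#' Harmonic angle potential of a sphere triple
#'
#' Rigidity potential `V = kH (theta - pi)^2 / 2` on the interior angle
#' `theta` of three sequential spheres, keeping each twitcher straight.
#' Forces are the exact negative gradient, distributed over the triple so
#' that net force and net torque vanish.
#'
#' @param xi,xj,xk positions of the three spheres; length-2 vectors or
#'   matrices with one row per triple and columns (x, y).
#' @param params a [twitch_params()] object.
#' @return A list with `energy`, the interior angle `theta`, and force
#'   matrices `F_i`, `F_j`, `F_k`.
#' @export
angle_harmonic <- function(xi, xj, xk, params = twitch_params()) {
  as_m <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1)
  xi <- as_m(xi); xj <- as_m(xj); xk <- as_m(xk)
  stopifnot(ncol(xi) == 2, nrow(xi) == nrow(xj), nrow(xj) == nrow(xk))
  angle_ef_cpp(xi, xj, xk, params$angle_kH)
}

#' Pilus retraction force
#'
#' Constant-magnitude force `kP` pulling the head sphere of a retracting
#' twitcher toward its fixed pilus adhesion point, applied only while the
#' minimum-image head-anchor separation exceeds the cutoff `pilus_r0`.
#'
#' @param head_pos head sphere position (length-2).
#' @param anchor pilus adhesion point (length-2); must be present.
#' @param params a [twitch_params()] object.
#' @return Length-2 force vector acting on the head sphere.
#' @export
pilus_force <- function(head_pos, anchor, params = twitch_params()) {
  if (is.null(anchor) || any(is.na(anchor)))
    stop("pilus force requested without an anchor", call. = FALSE)
  L <- params$box_L
  d <- anchor - head_pos
  d <- d - L * round(d / L)  # minimum image
  r <- sqrt(sum(d^2))
  if (r <= params$pilus_r0) return(c(0, 0))
  params$pilus_kP * d / r
}

#' Total force field on all spheres
#'
#' Sum of WCA (all pairs within the cutoff, minimum image), FENE bonds,
#' harmonic angles, and the pilus force on retracting twitchers' heads.
#'
#' @param pos matrix `(4N, 2)` of wrapped sphere positions, four consecutive
#'   rows per twitcher (row 1 = tail, row 4 = head).
#' @param params a [twitch_params()] object with matching `n_twitchers`.
#' @param phase integer vector of per-twitcher phases (0 rest, 1 extension,
#'   2 retraction); defaults to all resting.
#' @param anchor matrix `(N, 2)` of pilus anchors (used for retracting
#'   twitchers only).
#' @param method `"cell"` (cell-list candidate pairs) or `"brute"`
#'   (all pairs); both give identical forces and the equivalence is part of
#'   the engine's contract.
#' @return Matrix `(4N, 2)` of forces.
#' @export
total_forces <- function(pos, params, phase = NULL, anchor = NULL,
                         method = c("cell", "brute")) {
  method <- match.arg(method)
  N <- params$n_twitchers
  if (nrow(pos) != 4 * N)
    stop("pos must have 4 * n_twitchers rows", call. = FALSE)
  if (is.null(phase)) phase <- integer(N)
  if (is.null(anchor)) anchor <- matrix(0, N, 2)
  total_forces_cpp(pos, as.integer(phase), anchor, unclass(params), method)
}

#' Equilibrium bond length of the combined WCA + FENE potential
#'
#' The separation at which WCA repulsion balances FENE attraction
#' (about `0.97 sigma` for the default constants); used to build initial
#' straight-rod configurations.
#'
#' @param params a [twitch_params()] object.
#' @return The equilibrium bond length.
#' @export
bond_equilibrium <- function(params = twitch_params()) {
  bond_equilibrium_cpp(unclass(params))
}
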