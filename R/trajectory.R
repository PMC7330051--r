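#' Construct a twitcher trajectory object
#'
#' Low-level constructor for the container used by all analysis functions.
#' Frames are sampled on a regular time grid; per-twitcher velocities are
#' displacements of the centre of mass over one `tau`, so `vel[f, , ]` refers
#' to the interval ending at `time[f]`.
#'
#' @param time numeric vector of frame times (starting at 0, step
#'   `sample_every * tau`).
#' @param com array `(F, N, 2)` of unwrapped centre-of-mass positions.
#' @param com_wrapped array `(F, N, 2)` of positions wrapped into the box.
#' @param vel array `(F, N, 2)` of per-`tau` velocities (`NA` in frame 1).
#' @param phase integer matrix `(F, N)`: 0 rest, 1 extension, 2 retraction.
#' @param phase_start integer matrix `(F, N)`: phase at the start of the
#'   velocity interval ending at each frame (used to attribute speeds to
#'   phases).
#' @param polar array `(F, N, 2)` of unit tail-to-head orientation vectors.
#' @param box_L box edge.
#' @param params optional [twitch_params()] object.
#' @param ... further fields stored on the object.
#' @return An object of class `twitch_traj`.
#' @export
twitch_traj <- function(time, com, com_wrapped = NULL, vel = NULL,
                        phase = NULL, phase_start = NULL, polar = NULL,
                        box_L, params = NULL, ...) {
  F <- length(time)
  stopifnot(length(dim(com)) == 3, dim(com)[1] == F, dim(com)[3] == 2)
  N <- dim(com)[2]
  if (is.null(com_wrapped)) com_wrapped <- com %% box_L
  if (is.null(vel)) {
    vel <- array(NA_real_, dim(com))
    if (F > 1) {
      dtf <- time[2] - time[1]
      vel[-1, , ] <- (com[-1, , , drop = FALSE] -
                      com[-F, , , drop = FALSE]) / dtf
    }
  }
  if (is.null(phase)) phase <- matrix(0L, F, N)
  if (is.null(phase_start)) phase_start <- phase
  structure(list(time = time, com = com, com_wrapped = com_wrapped,
                 vel = vel, phase = phase, phase_start = phase_start,
                 polar = polar, box_L = box_L, n_twitchers = N,
                 params = params, ...),
            class = "twitch_traj")
}

n_frames <- function(traj) length(traj$time)

#' @export
print.twitch_traj <- function(x, ...) {
  cat(sprintf("Twitcher trajectory: %d twitchers, %d frames, box %g\n",
              x$n_twitchers, n_frames(x), x$box_L))
  if (n_frames(x) > 1)
    cat(sprintf("  t = %g .. %g (sampling interval %g tau)\n",
                x$time[1], x$time[length(x$time)], x$time[2] - x$time[1]))
  invisible(x)
}

#' @export
print.twitch_sim <- function(x, ...) {
  phi <- if (!is.null(x$params)) coverage_fraction(x$n_twitchers, x$params)
         else NA_real_
  cat(sprintf(
    "Twitcher simulation: N = %d (phi = %.4g), box %g, %d frames\n",
    x$n_twitchers, phi, x$box_L, n_frames(x)))
  cat(sprintf("  duration %g tau, seed %d\n",
              x$time[length(x$time)], x$seed))
  cc <- x$event_counts
  cat(sprintf(
    "  events: %d rest exits, %d adhesions; %d arrive / %d snap / %d exhaust\n",
    cc[["rest_exit"]], cc[["anchor_placed"]], cc[["arrive"]], cc[["snap"]],
    cc[["exhaust"]]))
  invisible(x)
}

#' @export
summary.twitch_sim <- function(object, ...) {
  sp <- sqrt(object$vel[, , 1]^2 + object$vel[, , 2]^2)
  ph <- object$phase
  cat(sprintf("Mean speed v_m = %.4g sigma/tau\n", mean(sp, na.rm = TRUE)))
  occ <- tabulate(as.integer(ph) + 1L, nbins = 3L) / length(ph)
  cat(sprintf("Phase occupancy: rest %.3f, extension %.3f, retraction %.3f\n",
              occ[1], occ[2], occ[3]))
  invisible(object)
}

#' Plot twitcher centre-of-mass paths
#'
#' @param x a `twitch_traj`.
#' @param twitchers indices of twitchers to draw (default up to 10).
#' @param wrapped draw wrapped (in-box) or unwrapped paths.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.twitch_traj <- function(x, twitchers = NULL, wrapped = FALSE, ...) {
  if (is.null(twitchers)) twitchers <- seq_len(min(10, x$n_twitchers))
  a <- if (wrapped) x$com_wrapped else x$com
  graphics::matplot(a[, twitchers, 1, drop = FALSE],
                    a[, twitchers, 2, drop = FALSE],
                    type = "l", lty = 1, xlab = "x / sigma",
                    ylab = "y / sigma", asp = 1, ...)
  invisible(x)
}

#' Motility events of a simulation
#'
#' @param sim a `twitch_sim` with `record_events = TRUE`.
#' @return A data frame with columns `twitcher`, `kind` (factor:
#'   `rest_exit`, `anchor_placed`, `arrive`, `snap`, `exhaust`) and `time`.
#' @export
twitch_events <- function(sim) {
  ev <- sim$events
  if (is.null(ev) || length(ev$time) == 0)
    return(data.frame(twitcher = integer(), kind = factor(character(),
           levels = event_levels), time = numeric()))
  data.frame(twitcher = ev$twitcher,
             kind = factor(event_levels[ev$kind + 1L],
                           levels = event_levels),
             time = ev$time)
}

event_levels <- c("rest_exit", "anchor_placed", "arrive", "snap", "exhaust")
phase_levels <- c("R", "E", "T")
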