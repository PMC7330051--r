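#' Simulate an ensemble of twitching bacilliforms
#'
#' Integrates the underdamped Langevin dynamics of `N` four-bead twitchers in
#' a square periodic box while each twitcher follows the stochastic motility
#' cycle rest -> extension -> retraction. Identical `(params, seed)` give
#' bitwise-identical trajectories.
#'
#' The initial configuration is built by random sequential insertion of
#' non-overlapping rods for coverages up to 0.3, and by aligned lattice
#' placement with random polarity followed by a randomising warm-up
#' (default `1000 tau`, discarded) above that. All twitchers start at rest.
#'
#' @param params a [twitch_params()] object.
#' @param n_tau run length in units of `tau` (defaults to
#'   `total_steps / steps_per_tau` from `params`).
#' @param seed integer random seed (defaults to `params$seed`).
#' @param sample_every record one frame every `sample_every` tau. Per-`tau`
#'   velocities are recorded at each frame regardless of the stride.
#' @param keep_spheres record per-sphere positions (needed by
#'   [write_traj()]); defaults to `TRUE` for `N <= 20`.
#' @param record_events keep the full motility event log; defaults to `TRUE`
#'   for `N <= 20` (counts by kind are always kept).
#' @param record_energy record total (potential + kinetic) energy per frame.
#' @param init initial-configuration mode: `"auto"`, `"insertion"` or
#'   `"lattice"`.
#' @param warmup_tau warm-up duration in `tau` discarded before recording;
#'   default 0 for insertion starts and 1000 for lattice starts.
#' @return An object of classes `twitch_sim` and `twitch_traj`; see
#'   [twitch_traj()] for the frame fields. Additional fields: `events`
#'   (see [twitch_events()]), `event_counts`, `seed`, `report`, and, when
#'   `keep_spheres = TRUE`, `spheres` (wrapped and unwrapped per-sphere
#'   positions and per-twitcher anchors).
#' @examples
#' p <- twitch_params(n_twitchers = 1, box_L = 50, seed = 7)
#' sim <- simulate_twitchers(p, n_tau = 200)
#' sim
#' @export
simulate_twitchers <- function(params, n_tau = NULL, seed = params$seed,
                               sample_every = 1L,
                               keep_spheres = NULL, record_events = NULL,
                               record_energy = FALSE,
                               init = c("auto", "insertion", "lattice"),
                               warmup_tau = NULL) {
  stopifnot(inherits(params, "twitch_params"))
  init <- match.arg(init)
  N <- params$n_twitchers
  if (N < 1) stop("n_twitchers must be >= 1 to simulate", call. = FALSE)
  phi <- coverage_fraction(N, params)
  if (phi > 0.8)
    stop("requested coverage phi = ", signif(phi, 3), " exceeds 0.8",
         call. = FALSE)
  if (is.null(n_tau))
    n_tau <- as.integer(params$total_steps / params$steps_per_tau)
  n_tau <- as.integer(n_tau)
  sample_every <- as.integer(sample_every)
  stopifnot(n_tau >= 0, sample_every >= 1)
  if (is.null(keep_spheres)) keep_spheres <- N <= 20
  if (is.null(record_events)) record_events <- N <= 20
  lattice <- init == "lattice" || (init == "auto" && phi > 0.3)
  if (is.null(warmup_tau)) warmup_tau <- if (lattice) 1000L else 0L

  raw <- sim_run_cpp(unclass(params), n_tau, as.double(seed), sample_every,
                     keep_spheres, record_events, record_energy,
                     init, as.integer(warmup_tau))

  F <- raw$frames
  shape <- function(a, n) array(a, dim = c(F, n, 2))
  obj <- twitch_traj(
    time = raw$time,
    com = shape(raw$com, N),
    com_wrapped = shape(raw$com_wrapped, N),
    vel = shape(raw$vel, N),
    phase = matrix(raw$phase, F, N),
    phase_start = matrix(raw$phase_start, F, N),
    polar = shape(raw$polar, N),
    box_L = params$box_L,
    params = params,
    events = raw$events,
    event_counts = raw$event_counts,
    seed = as.integer(seed),
    report = list(seed = as.integer(seed), n_tau = n_tau,
                  total_steps = n_tau * params$steps_per_tau,
                  sample_every = sample_every, frames = F,
                  warmup_tau = warmup_tau,
                  init = if (lattice) "lattice" else "insertion",
                  bond_eq = raw$bond_eq,
                  event_counts = raw$event_counts))
  if (keep_spheres) {
    obj$spheres <- list(wrapped = array(raw$spheres_wrapped,
                                        dim = c(F, 4 * N, 2)),
                        unwrapped = array(raw$spheres_unwrapped,
                                          dim = c(F, 4 * N, 2)),
                        anchor = shape(raw$anchor, N))
  }
  if (record_energy) obj$energy <- raw$energy
  class(obj) <- c("twitch_sim", "twitch_traj")
  obj
}
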