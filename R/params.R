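#' Model parameters for a twitcher simulation
#'
#' Collects all physical and motility-cycle constants of the model in
#' simulation units: lengths in the sphere diameter `sigma`, masses in the
#' sphere mass `m`, energies in the Lennard-Jones well depth `epsilon`, and
#' times in `tau = sqrt(m sigma^2 / epsilon)`. Defaults are the standard
#' parameterisation of the model.
#'
#' @param sigma sphere diameter (length unit).
#' @param mass sphere mass (mass unit).
#' @param epsilon energy scale (energy unit).
#' @param temperature thermal energy `k_B T` of the Langevin noise. The model
#'   is run at a near-zero `2e-7` so the dynamics are dominated by the
#'   motility cycle, not thermal motion.
#' @param zeta friction coefficient of the Langevin drag.
#' @param dt integration time step.
#' @param steps_per_tau number of integration steps per unit time `tau`;
#'   `dt * steps_per_tau` must equal `tau = 1`.
#' @param total_steps default run length in integration steps.
#' @param box_L edge of the square periodic simulation box.
#' @param wca_cutoff cutoff of the WCA excluded-volume potential,
#'   `2^(1/6) sigma`.
#' @param fene_R0,fene_kF maximum extension and spring constant of the FENE
#'   bonds joining consecutive spheres.
#' @param angle_kH stiffness of the harmonic angle potential keeping the
#'   four-bead chain straight (`theta_0 = pi`).
#' @param angle_theta0 rest angle of the angle potential; only the straight
#'   rod (`pi`) is supported.
#' @param body_length nominal tip-to-tip body length of a twitcher.
#' @param pilus_kP magnitude of the constant pilus retraction force.
#' @param pilus_r0 cutoff distance of the pilus force.
#' @param pilus_L0 distance from the head at which the pilus anchor is placed.
#' @param arrive_LR head-anchor distance below which retraction ends by
#'   arrival.
#' @param snap_LS head-anchor distance above which the pilus snaps.
#' @param exhaust_tM maximum duration of a retraction phase (in `tau`).
#' @param rest_exit_prob probability per `tau` of leaving the rest phase.
#' @param extension_duration duration of the pilus extension phase (in `tau`).
#' @param cone_half_angle half-angle of the cone (about the body axis) within
#'   which the pilus anchor is placed.
#' @param n_twitchers number of twitchers `N`.
#' @param seed default random seed for [simulate_twitchers()].
#'
#' @return An object of class `twitch_params` (a validated named list).
#' @examples
#' p <- twitch_params(n_twitchers = 10, box_L = 50)
#' coverage_fraction(10, p)
#' @export
twitch_params <- function(sigma = 1, mass = 1, epsilon = 1,
                          temperature = 2e-7, zeta = 1, dt = 0.01,
                          steps_per_tau = 100L, total_steps = 1e8,
                          box_L = 100, wca_cutoff = 2^(1 / 6) * sigma,
                          fene_R0 = 1.5, fene_kF = 50,
                          angle_kH = 33, angle_theta0 = pi,
                          body_length = 4,
                          pilus_kP = 1, pilus_r0 = 0.2, pilus_L0 = 2.4,
                          arrive_LR = 0.2, snap_LS = 3, exhaust_tM = 70,
                          rest_exit_prob = 0.1, extension_duration = 10,
                          cone_half_angle = pi / 4,
                          n_twitchers = 1L, seed = 1L) {
  p <- list(sigma = sigma, mass = mass, epsilon = epsilon,
            temperature = temperature, zeta = zeta, dt = dt,
            steps_per_tau = as.integer(steps_per_tau),
            total_steps = total_steps, box_L = box_L,
            wca_cutoff = wca_cutoff, fene_R0 = fene_R0, fene_kF = fene_kF,
            angle_kH = angle_kH, angle_theta0 = angle_theta0,
            body_length = body_length, pilus_kP = pilus_kP,
            pilus_r0 = pilus_r0, pilus_L0 = pilus_L0, arrive_LR = arrive_LR,
            snap_LS = snap_LS, exhaust_tM = exhaust_tM,
            rest_exit_prob = rest_exit_prob,
            extension_duration = extension_duration,
            cone_half_angle = cone_half_angle,
            n_twitchers = as.integer(n_twitchers), seed = as.integer(seed))
  validate_twitch_params(p)
  structure(p, class = "twitch_params")
}

validate_twitch_params <- function(p) {
  lens <- c("sigma", "box_L", "wca_cutoff", "fene_R0", "body_length",
            "pilus_L0", "arrive_LR", "snap_LS")
  for (nm in lens)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive length", call. = FALSE)
  if (p$temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (p$rest_exit_prob <= 0 || p$rest_exit_prob > 1)
    stop("rest_exit_prob must be in (0, 1]", call. = FALSE)
  if (!(p$arrive_LR < p$pilus_L0 && p$pilus_L0 < p$snap_LS))
    stop("need arrive_LR < pilus_L0 < snap_LS", call. = FALSE)
  tau <- sqrt(p$mass * p$sigma^2 / p$epsilon)
  if (abs(p$dt * p$steps_per_tau - tau) > 1e-9)
    stop("dt * steps_per_tau must equal tau = sqrt(m sigma^2 / epsilon)",
         call. = FALSE)
  if (abs(p$angle_theta0 - pi) > 1e-12)
    stop("only the straight rod (angle_theta0 = pi) is supported",
         call. = FALSE)
  if (p$n_twitchers < 0) stop("n_twitchers must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.twitch_params <- function(x, ...) {
  cat("Twitcher model parameters (simulation units)\n")
  cat(sprintf("  N = %d twitchers, box %g x %g, coverage phi = %.4g\n",
              x$n_twitchers, x$box_L, x$box_L,
              coverage_fraction(x$n_twitchers, x)))
  cat(sprintf("  T = %g, zeta = %g, dt = %g (%d steps per tau)\n",
              x$temperature, x$zeta, x$dt, x$steps_per_tau))
  cat(sprintf(
    "  motility: rest exit %.2g per tau, extension %g tau, L0 = %g,\n",
    x$rest_exit_prob, x$extension_duration, x$pilus_L0))
  cat(sprintf("            arrive < %g, snap > %g, exhaust at %g tau\n",
              x$arrive_LR, x$snap_LS, x$exhaust_tM))
  invisible(x)
}

#' Twitcher footprint area
#'
#' Area of one twitcher, modelled as a rod of length `body_length` and width
#' `sigma` with circular end caps:
#' `(L_body - sigma) * sigma + pi * (sigma / 2)^2`. Under the default
#' geometry this is `3 + pi / 4 = 3.7854`.
#'
#' @param params a [twitch_params()] object.
#' @return The area in units of `sigma^2`.
#' @export
twitcher_area <- function(params = twitch_params()) {
  (params$body_length - params$sigma) * params$sigma +
    pi * (params$sigma / 2)^2
}

#' Surface coverage fraction
#'
#' Fraction of the box area covered by `N` twitchers,
#' `phi = N * A_twitch / box_L^2`. With the default geometry
#' `phi = 3.7854e-4 * N`.
#'
#' @param N number of twitchers.
#' @param params a [twitch_params()] object.
#' @return The coverage fraction.
#' @export
coverage_fraction <- function(N, params = twitch_params()) {
  stopifnot(all(N >= 0))
  N * twitcher_area(params) / params$box_L^2
}

#' Critical coverage fraction
#'
#' The coverage at which the mean area per twitcher equals the characteristic
#' rotational disc swept by one twitcher,
#' `phi* = A_twitch / (pi (L_body / 2)^2) ~ 0.3`. Above this coverage,
#' excluded-volume interactions become continuous rather than episodic and
#' collective dynamics emerge.
#'
#' @param params a [twitch_params()] object.
#' @return The critical coverage fraction.
#' @export
critical_coverage <- function(params = twitch_params()) {
  twitcher_area(params) / (pi * (params$body_length / 2)^2)
}

#' Number of twitchers for a target coverage
#'
#' @param phi target coverage fraction.
#' @param params a [twitch_params()] object.
#' @return Integer number of twitchers whose coverage is closest to `phi`.
#' @export
twitchers_for_coverage <- function(phi, params = twitch_params()) {
  stopifnot(phi >= 0)
  as.integer(round(phi * params$box_L^2 / twitcher_area(params)))
}
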