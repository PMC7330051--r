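#' Synthetic reference trajectories
#'
#' Random-walk trajectories with known statistical structure, used as
#' oracles for the analysis functions and as stand-ins for simulator
#' output. Types:
#' \describe{
#'   \item{`ballistic`}{straight-line motion at constant `speed`, random
#'     initial heading per walker;}
#'   \item{`brownian`}{2D Gaussian steps with diffusivity `D0`
#'     (per-component variance `2 D0 dt`);}
#'   \item{`persistent`}{constant-speed persistent random walk whose
#'     heading diffuses with rotational diffusivity `rot_diff`
#'     (direction correlation time `1 / rot_diff`, persistence length
#'     `speed / rot_diff`);}
#'   \item{`shell`}{fixed step length `speed * dt`, fresh uniform direction
#'     each step;}
#'   \item{`zero_gauss`}{50/50 mixture: each step is either exactly zero or
#'     a 2D Gaussian step (diffusivity `D0`);}
#'   \item{`uniform`}{positions redrawn independently and uniformly in the
#'     box each frame (an ideal-gas / Poisson occupancy reference).}
#' }
#' Uses R's RNG; call [set.seed()] for reproducibility.
#'
#' @param n_steps number of steps (frames = `n_steps + 1`).
#' @param n_walkers number of independent walkers.
#' @param type one of the types above.
#' @param speed speed for the ballistic/persistent/shell types.
#' @param D0 diffusivity for the Brownian and mixture types.
#' @param rot_diff rotational diffusivity of the persistent walk.
#' @param box_L periodic box edge used for the wrapped coordinates.
#' @param dt frame interval.
#' @param params optional [twitch_params()] attached to the trajectory.
#' @return A [twitch_traj()]; walkers start uniformly in the box.
#' @export
synthetic_walk <- function(n_steps, n_walkers = 1,
                           type = c("ballistic", "brownian", "persistent",
                                    "shell", "zero_gauss", "uniform"),
                           speed = 0.25, D0 = 0.1, rot_diff = 0.1,
                           box_L = 100, dt = 1, params = NULL) {
  type <- match.arg(type)
  F <- n_steps + 1L
  N <- as.integer(n_walkers)
  com <- array(0, c(F, N, 2))
  polar <- NULL
  if (N > 0) {
    x0 <- matrix(runif(2 * N, 0, box_L), N, 2)
    if (type == "uniform") {
      com[, , 1] <- matrix(runif(F * N, 0, box_L), F, N)
      com[, , 2] <- matrix(runif(F * N, 0, box_L), F, N)
    } else {
      steps_x <- matrix(0, n_steps, N)
      steps_y <- matrix(0, n_steps, N)
      if (type == "ballistic") {
        th <- runif(N, 0, 2 * pi)
        steps_x <- matrix(speed * dt * cos(th), n_steps, N, byrow = TRUE)
        steps_y <- matrix(speed * dt * sin(th), n_steps, N, byrow = TRUE)
      } else if (type == "brownian") {
        s <- sqrt(2 * D0 * dt)
        steps_x <- matrix(rnorm(n_steps * N, 0, s), n_steps, N)
        steps_y <- matrix(rnorm(n_steps * N, 0, s), n_steps, N)
      } else if (type == "persistent") {
        th0 <- runif(N, 0, 2 * pi)
        dth <- matrix(rnorm(n_steps * N, 0, sqrt(2 * rot_diff * dt)),
                      n_steps, N)
        th <- apply(dth, 2, cumsum) + matrix(th0, n_steps, N, byrow = TRUE)
        steps_x <- speed * dt * cos(th)
        steps_y <- speed * dt * sin(th)
      } else if (type == "shell") {
        th <- matrix(runif(n_steps * N, 0, 2 * pi), n_steps, N)
        steps_x <- speed * dt * cos(th)
        steps_y <- speed * dt * sin(th)
      } else if (type == "zero_gauss") {
        s <- sqrt(2 * D0 * dt)
        on <- matrix(runif(n_steps * N) < 0.5, n_steps, N)
        steps_x <- matrix(rnorm(n_steps * N, 0, s), n_steps, N) * on
        steps_y <- matrix(rnorm(n_steps * N, 0, s), n_steps, N) * on
      }
      colcum <- function(m) {
        cs <- apply(m, 2, cumsum)
        if (!is.matrix(cs)) cs <- matrix(cs, nrow = nrow(m))
        cs
      }
      com[, , 1] <- rbind(x0[, 1],
                          matrix(x0[, 1], n_steps, N, byrow = TRUE) +
                            colcum(steps_x))
      com[, , 2] <- rbind(x0[, 2],
                          matrix(x0[, 2], n_steps, N, byrow = TRUE) +
                            colcum(steps_y))
    }
  }
  tr <- twitch_traj(time = seq(0, by = dt, length.out = F), com = com,
                    com_wrapped = com %% box_L, box_L = box_L,
                    params = params)
  tr$synthetic <- type
  tr
}
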