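#' Mean squared displacement
#'
#' `MSD(t) = < |x(0) - x(t)|^2 >` of the twitcher centres of mass, averaged
#' over all time origins and all twitchers; the fourth moment
#' `< |x(0) - x(t)|^4 >` is accumulated alongside for the non-Gaussian
#' parameter.
#'
#' @param traj a [twitch_traj()].
#' @param lags lag times (in the trajectory's time units). Default: a
#'   log-spaced grid with about `points_per_decade` points per decade up to
#'   `max_lag`.
#' @param points_per_decade density of the default lag grid.
#' @param max_lag largest lag; default half the trajectory span.
#' @param origin_stride use every `origin_stride`-th frame as a time origin.
#' @return A data frame of class `msd_curve` with columns `t`, `msd`, `m4`
#'   and `n` (origin-pair count).
#' @export
msd <- function(traj, lags = NULL, points_per_decade = 20, max_lag = NULL,
                origin_stride = 1L) {
  F <- n_frames(traj)
  if (F < 2) stop("trajectory too short for an MSD", call. = FALSE)
  dtf <- traj$time[2] - traj$time[1]
  span <- traj$time[F] - traj$time[1]
  if (is.null(max_lag)) max_lag <- span / 2
  if (is.null(lags)) {
    k <- unique(pmax(1, round(10^(seq(0, log10(max_lag / dtf),
                                      by = 1 / points_per_decade)))))
    lags <- k * dtf
  }
  lag_f <- unique(as.integer(round(lags / dtf)))
  lag_f <- lag_f[lag_f >= 1]
  if (any(round(lags / dtf) > F - 1))
    stop("requested lag exceeds the trajectory span", call. = FALSE)
  r <- msd_cpp(traj$com, F, traj$n_twitchers, lag_f,
               as.integer(origin_stride))
  structure(data.frame(t = lag_f * dtf, msd = r$msd, m4 = r$m4, n = r$n),
            class = c("msd_curve", "data.frame"), d = 2L)
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$t, x$msd, log = "xy", xlab = "lag time t / tau",
                 ylab = expression(Delta * r^2), type = "b", pch = 20, ...)
  invisible(x)
}

#' MSD scaling exponent
#'
#' Least-squares slope `beta` of `log MSD` versus `log t` over a lag window;
#' `beta = 2` indicates propulsive and `beta = 1` diffusive motion.
#'
#' @param m an [msd()] curve.
#' @param window numeric `c(min, max)` lag range (inclusive).
#' @return The fitted exponent (scalar).
#' @export
fit_beta <- function(m, window) {
  sel <- m$t >= window[1] & m$t <= window[2] & is.finite(m$msd)
  if (sum(sel) < 4)
    stop("need at least 4 MSD points in the fit window", call. = FALSE)
  if (any(m$msd[sel] <= 0))
    stop("non-positive MSD values in the fit window", call. = FALSE)
  unname(coef(lm(log(m$msd[sel]) ~ log(m$t[sel])))[2])
}

#' Non-Gaussian parameter
#'
#' `alpha_2(t) = (d / (d + 2)) * <r^4> / <r^2>^2 - 1` of the displacement
#' distribution at each lag. Zero for Gaussian displacements, negative
#' (platykurtic, bounded below by `-2/(d+2)`) when large steps are rarer
#' than Gaussian, positive (leptokurtic) when they are more common.
#'
#' @param m an [msd()] curve.
#' @param d spatial dimension (2 for surface-bound twitchers).
#' @return A data frame with columns `t` and `alpha2` (lags with zero MSD
#'   are dropped).
#' @export
ngp <- function(m, d = 2) {
  keep <- is.finite(m$msd) & m$msd > 0
  data.frame(t = m$t[keep],
             alpha2 = d / (d + 2) * m$m4[keep] / m$msd[keep]^2 - 1)
}

#' Van Hove self-correlation function
#'
#' Distribution `G(dx, t)` of one-dimensional centre-of-mass displacements
#' at lag `t`, pooling both Cartesian components, all origins and all
#' twitchers. A Gaussian reference with the matched standard deviation is
#' returned alongside. With `collapse = TRUE` the abscissa is scaled by
#' `t^(-1/2)` and the density by `t^(1/2)` so purely diffusive curves at
#' different lags coincide.
#'
#' @param traj a [twitch_traj()].
#' @param t lag time.
#' @param bins number of histogram bins (or a vector of breaks on the
#'   displacement axis).
#' @param collapse apply the diffusive collapse scaling.
#' @param origin_stride origin subsampling.
#' @return A data frame of class `vanhove` with bin centres `x`, densities
#'   `G`, the matched `gauss` reference and counts `n`; attributes `t` and
#'   `sd`.
#' @export
van_hove <- function(traj, t, bins = 81, collapse = FALSE,
                     origin_stride = 1L) {
  F <- n_frames(traj)
  dtf <- traj$time[2] - traj$time[1]
  lag <- as.integer(round(t / dtf))
  if (lag < 1 || lag > F - 1)
    stop("lag outside the trajectory span", call. = FALSE)
  org <- seq(1, F - lag, by = origin_stride)
  dx <- c(traj$com[org + lag, , 1] - traj$com[org, , 1],
          traj$com[org + lag, , 2] - traj$com[org, , 2])
  if (length(dx) == 0) stop("no displacement samples", call. = FALSE)
  s <- stats::sd(dx)
  if (length(bins) == 1) {
    lim <- max(abs(dx)) * 1.02 + 1e-12
    bins <- seq(-lim, lim, length.out = bins + 1)
  }
  h <- graphics::hist(dx, breaks = bins, plot = FALSE)
  out <- data.frame(x = h$mids, G = h$density,
                    gauss = stats::dnorm(h$mids, 0, s), n = h$counts)
  if (collapse) {
    out$x <- out$x / sqrt(t)
    out$G <- out$G * sqrt(t)
    out$gauss <- out$gauss * sqrt(t)
  }
  structure(out, class = c("vanhove", "data.frame"), t = t, sd = s,
            collapse = collapse)
}

#' Short-time mean squared velocity
#'
#' `V^2 = MSD(tau) / tau^2`, the effective squared speed over the shortest
#' resolved interval.
#'
#' @param m an [msd()] curve containing the lag `tau`.
#' @param tau the unit time (1 by default).
#' @return `V^2` (scalar).
#' @export
msv <- function(m, tau = 1) {
  i <- which(abs(m$t - tau) < 1e-9)
  if (length(i) != 1)
    stop("MSD curve does not contain the lag tau = ", tau, call. = FALSE)
  m$msd[i] / tau^2
}

#' Long-time diffusion coefficient
#'
#' Fits `MSD(t) = const + 2 d D t` over lags beyond `t_min` and returns `D`.
#'
#' @param m an [msd()] curve spanning beyond `t_min`.
#' @param t_min lower edge of the diffusive fit range.
#' @param d spatial dimension.
#' @return The effective diffusion coefficient.
#' @export
diffusivity <- function(m, t_min = 1e4, d = 2) {
  sel <- m$t > t_min & is.finite(m$msd)
  if (sum(sel) < 2)
    stop("MSD does not span the diffusive fit range (t > ", t_min, ")",
         call. = FALSE)
  unname(coef(lm(m$msd[sel] ~ m$t[sel]))[2]) / (2 * d)
}

#' Relative diffusivity
#'
#' Dimensionless ratio `D = scriptD / (tau V^2)` comparing the long-time
#' diffusion coefficient with the short-time mean squared velocity.
#'
#' @param D long-time diffusion coefficient from [diffusivity()].
#' @param V2 short-time mean squared velocity from [msv()].
#' @param tau the unit time.
#' @return The relative diffusivity.
#' @export
relative_diffusivity <- function(D, V2, tau = 1) D / (tau * V2)

#' Individual auto-correlation of the direction of motion
#'
#' `rho(dr) = < v_hat(0) . v_hat(dr) >` along each twitcher's own
#' trajectory, where `dr` is by default the cumulative path length of the
#' centre of mass (sampled at `tau` resolution) since the origin; for each
#' origin the direction is compared at the first sample at which the path
#' reaches each bin edge. Zero-speed samples carry no direction and are
#' skipped.
#'
#' @param traj a [twitch_traj()].
#' @param bin_width abscissa bin width (in `sigma`).
#' @param r_max largest distance travelled.
#' @param origin_stride origin subsampling.
#' @param abscissa `"path"` (distance travelled, the default) or `"net"`
#'   (net displacement from the origin).
#' @return A data frame of class `corr_curve` with columns `r`, `value`,
#'   `n`.
#' @export
iac <- function(traj, bin_width = 1, r_max = 100, origin_stride = 1L,
                abscissa = c("path", "net")) {
  abscissa <- match.arg(abscissa)
  nb <- as.integer(ceiling(r_max / bin_width))
  r <- iac_cpp(traj$com, traj$vel, n_frames(traj), traj$n_twitchers,
               bin_width, nb, as.integer(origin_stride),
               abscissa == "path")
  structure(data.frame(r = (seq_len(nb)) * bin_width, value = r$value,
                       n = r$n),
            class = c("corr_curve", "data.frame"),
            statistic = "iac", abscissa = abscissa)
}

#' @export
plot.corr_curve <- function(x, ...) {
  graphics::plot(x$r, x$value, type = "l",
                 xlab = expression(Delta * r / sigma),
                 ylab = "correlation", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Exponential decorrelation length
#'
#' Fits `value ~ a * exp(-r / lambda)` by least squares on `log(value)`
#' over a tail range and returns `lambda = -1/slope`. Non-positive values
#' inside the range are dropped with a warning (the log is undefined there).
#'
#' @param curve a correlation curve (data frame with `r` and `value`).
#' @param range numeric `c(min, max)` abscissa range of the tail fit.
#' @return The decorrelation length, with the fit range and prefactor as
#'   attributes.
#' @export
fit_decorrelation_length <- function(curve, range = c(20, 80)) {
  sel <- curve$r >= range[1] & curve$r <= range[2] & is.finite(curve$value)
  if (any(curve$value[sel] <= 0)) {
    warning("non-positive correlation values in the fit range; shrinking")
    sel <- sel & curve$value > 0
  }
  if (sum(sel) < 2)
    stop("no usable points in the decorrelation fit range", call. = FALSE)
  ft <- lm(log(curve$value[sel]) ~ curve$r[sel])
  structure(-1 / unname(coef(ft)[2]),
            range = range, prefactor = exp(unname(coef(ft)[1])))
}
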