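#' Speed decomposition by motility phase
#'
#' Splits the ensemble- and time-averaged twitcher speed `v_m` into the
#' contribution of actively retracting twitchers (`v_a`) and of
#' resting/extending twitchers (`v_r`). Each per-`tau` interval is
#' attributed to the phase at the interval start, so the weighted identity
#' `v_m = f_a v_a + (1 - f_a) v_r` holds exactly, with `f_a` the active
#' time fraction.
#'
#' @param traj a [twitch_traj()].
#' @param discard_frac fraction of initial frames excluded (equilibration).
#' @return A list with `v_m`, `v_a`, `v_r`, `f_active` and the per-phase
#'   occupancy fractions.
#' @export
speed_decomposition <- function(traj, discard_frac = 0.1) {
  F <- n_frames(traj)
  keep <- seq.int(max(2L, floor(discard_frac * F) + 1L), F)
  sp <- sqrt(traj$vel[keep, , 1]^2 + traj$vel[keep, , 2]^2)
  ph <- traj$phase_start[keep, , drop = FALSE]
  act <- ph == 2L
  f_a <- mean(act)
  v_a <- if (any(act)) mean(sp[act]) else 0
  v_r <- if (any(!act)) mean(sp[!act]) else 0
  occ <- tabulate(as.integer(ph) + 1L, nbins = 3L) / length(ph)
  list(v_m = mean(sp), v_a = v_a, v_r = v_r, f_active = f_a,
       occupancy = setNames(occ, c("rest", "extension", "retraction")))
}

#' Pair auto-correlation of motion or orientation
#'
#' Instantaneous correlation between distinct twitchers as a function of
#' their minimum-image centre-of-mass separation:
#' \describe{
#'   \item{`which = "v"`}{direction of motion, `< v_hat_g . v_hat_h >`
#'     (zero-speed twitchers skipped);}
#'   \item{`which = "p"`}{polar tail-to-head orientation,
#'     `< p_hat_g . p_hat_h >`;}
#'   \item{`which = "n"`}{nematic director. The default `form = "cos2"` is
#'     the standard 2D headless correlator `< cos 2 theta >` with `theta`
#'     the angle between directors; `form = "dot"` and `form = "shifted"`
#'     (`3(n.n - 2/3)`, applied to canonicalised directors) are also
#'     available.}
#' }
#'
#' @param traj a [twitch_traj()].
#' @param which `"v"`, `"p"` or `"n"`.
#' @param bin_width separation bin width (default `0.2 sigma`).
#' @param r_max largest separation (default half the box edge).
#' @param frame_stride pool every `frame_stride`-th frame.
#' @param discard_frac fraction of initial frames excluded.
#' @param form nematic correlator form (see above).
#' @return A data frame of class `corr_curve` with `r` (bin centres),
#'   `value` and pair count `n` (0-count bins have `NA` value).
#' @export
pair_correlation <- function(traj, which = c("v", "p", "n"),
                             bin_width = 0.2, r_max = NULL,
                             frame_stride = 1L, discard_frac = 0.1,
                             form = c("cos2", "dot", "shifted")) {
  which <- match.arg(which)
  form <- match.arg(form)
  F <- n_frames(traj)
  N <- traj$n_twitchers
  if (is.null(r_max)) r_max <- traj$box_L / 2
  nb <- as.integer(ceiling(r_max / bin_width))
  if (which == "v") {
    u <- traj$vel
    sp <- sqrt(u[, , 1]^2 + u[, , 2]^2)
    ok <- is.finite(sp) & sp > 0
    u[, , 1] <- u[, , 1] / sp
    u[, , 2] <- u[, , 2] / sp
    u[!is.finite(u)] <- 0
    mode <- 0L
  } else {
    u <- traj$polar
    if (is.null(u)) stop("trajectory has no orientation data", call. = FALSE)
    ok <- matrix(TRUE, F, N)
    mode <- if (which == "p") 0L else switch(form, cos2 = 1L, dot = 0L,
                                             shifted = 2L)
    if (which == "n" && form != "cos2") {
      # canonicalise directors so the sign-indeterminate forms are defined
      flip <- u[, , 1] < 0 | (u[, , 1] == 0 & u[, , 2] < 0)
      u[, , 1][flip] <- -u[, , 1][flip]
      u[, , 2][flip] <- -u[, , 2][flip]
      if (form == "shifted") mode <- 2L
    }
  }
  frames <- seq.int(max(1L, floor(discard_frac * F) + 1L), F,
                    by = frame_stride)
  r <- pac_cpp(traj$com_wrapped, u, ok, F, N, mode, bin_width, nb,
               as.integer(frames), traj$box_L)
  structure(data.frame(r = (seq_len(nb) - 0.5) * bin_width,
                       value = r$value, n = r$n),
            class = c("corr_curve", "data.frame"),
            statistic = paste0("pac_", which), form = form)
}

#' Raft size from the nematic pair correlation
#'
#' Decorrelation length of the tail of the nematic pair correlation,
#' fitted after the smectic peak near one body length; the same exponential
#' fitting contract as [fit_decorrelation_length()].
#'
#' @param curve a [pair_correlation()] curve (typically `which = "n"`).
#' @param range tail fit range; defaults to `[5, 15] sigma`, beyond the
#'   smectic peak near `4 sigma`.
#' @return The effective raft size `lambda`.
#' @export
raft_length <- function(curve, range = c(5, 15)) {
  fit_decorrelation_length(curve, range)
}

#' Distribution of local coverage fractions
#'
#' Partitions the box into square sub-domains (edge `cell_edge`, default
#' `10 sigma`, giving 100 sub-domains for the default box) and histograms
#' the instantaneous local coverage `phi' = n_local A_twitch / cell_edge^2`
#' over sub-domains and frames. Each twitcher is assigned to the sub-domain
#' containing its wrapped centre of mass.
#'
#' @param traj a [twitch_traj()] with `params`.
#' @param cell_edge sub-domain edge; must divide the box edge.
#' @param discard_frac fraction of initial frames excluded.
#' @return A data frame of class `coverage_dist` with `phi_local` (bin
#'   value, one per possible occupancy), probability `P` and count `n`;
#'   attribute `phi` holds the global coverage.
#' @export
local_coverage_distribution <- function(traj, cell_edge = 10,
                                        discard_frac = 0.1) {
  L <- traj$box_L
  nwin <- round(L / cell_edge)
  if (abs(nwin * cell_edge - L) > 1e-9)
    stop("cell_edge must divide the box edge", call. = FALSE)
  A_tw <- twitcher_area(traj$params %||% twitch_params())
  F <- n_frames(traj)
  keep <- seq.int(max(1L, floor(discard_frac * F) + 1L), F)
  counts <- window_counts(traj, cell_edge, keep)
  occ <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  kmax <- max(counts)
  phi_local <- (0:kmax) * A_tw / cell_edge^2
  structure(data.frame(phi_local = phi_local, P = occ / sum(occ), n = occ),
            class = c("coverage_dist", "data.frame"),
            phi = coverage_fraction(traj$n_twitchers,
                                    traj$params %||% twitch_params()),
            cell_edge = cell_edge)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# occupancy of square windows of edge `l` for the kept frames
window_counts <- function(traj, l, keep) {
  L <- traj$box_L
  nwin <- round(L / l)
  cx <- traj$com_wrapped[keep, , 1, drop = FALSE]
  cy <- traj$com_wrapped[keep, , 2, drop = FALSE]
  ix <- pmin(floor(cx / l), nwin - 1)
  iy <- pmin(floor(cy / l), nwin - 1)
  Fk <- length(keep)
  cell <- ix + nwin * iy                   # (Fk, N) window index
  off <- (seq_len(Fk) - 1L) * nwin^2      # frame offset
  idx <- as.integer(cell + off) + 1L
  tabulate(idx, nbins = Fk * nwin^2)
}

#' Number-fluctuation scaling
#'
#' Occupancy fluctuations of square observation windows versus their mean
#' occupancy, for a set of window sizes: for each window edge `l`, the mean
#' `<N_l>` and standard deviation `dN_l` of the per-window twitcher count
#' over windows and frames. The exponent `mu` of `dN ~ <N>^mu` is fitted on
#' the largest-occupancy portion of the abscissa (top half of the log
#' range). `mu = 1/2` is the central-limit (thermal-like) value; `mu -> 1`
#' signals giant number fluctuations. Both axes are also reported in local
#' coverage units (`phi_mean`, `dphi`).
#'
#' @param traj a [twitch_traj()].
#' @param window_sizes window edges; each must divide the box edge. Default:
#'   the divisors of the box among `{4, 5, 10, 20, 25}` (at least 3 are
#'   required).
#' @param discard_frac fraction of initial frames excluded.
#' @param fit_fraction fraction (from the top) of the log-abscissa range
#'   used in the fit.
#' @return A list of class `gnf_scaling`: data frame `scaling` (per window
#'   size: `l`, `mean_occ`, `sd_occ`, `phi_mean`, `dphi`), exponent `mu`,
#'   and the fit range.
#' @export
number_fluctuations <- function(traj, window_sizes = NULL,
                                discard_frac = 0.1, fit_fraction = 0.5) {
  L <- traj$box_L
  if (is.null(window_sizes)) {
    cand <- c(4, 5, 10, 20, 25)
    window_sizes <- cand[abs(L / cand - round(L / cand)) < 1e-9 &
                         cand < L]
  }
  if (length(window_sizes) < 3)
    stop("need at least 3 window sizes", call. = FALSE)
  F <- n_frames(traj)
  keep <- seq.int(max(1L, floor(discard_frac * F) + 1L), F)
  A_tw <- twitcher_area(traj$params %||% twitch_params())
  rows <- lapply(window_sizes, function(l) {
    cnt <- window_counts(traj, l, keep)
    data.frame(l = l, mean_occ = mean(cnt), sd_occ = stats::sd(cnt),
               phi_mean = mean(cnt) * A_tw / l^2,
               dphi = stats::sd(cnt) * A_tw / l^2)
  })
  sc <- do.call(rbind, rows)
  sc <- sc[order(sc$mean_occ), ]
  usable <- sc$sd_occ > 0 & sc$mean_occ > 0
  if (!any(usable)) {
    mu <- NA_real_
    rng <- c(NA_real_, NA_real_)
  } else {
    lx <- log(sc$mean_occ[usable])
    cut <- max(lx) - fit_fraction * (max(lx) - min(lx))
    sel <- lx >= cut - 1e-12
    if (sum(sel) < 2) sel <- rep(TRUE, length(lx))
    mu <- unname(coef(lm(log(sc$sd_occ[usable][sel]) ~ lx[sel]))[2])
    rng <- range(exp(lx[sel]))
  }
  structure(list(scaling = sc, mu = mu, fit_range_occ = rng),
            class = "gnf_scaling")
}

#' @export
print.gnf_scaling <- function(x, ...) {
  cat(sprintf("Number-fluctuation scaling: mu = %.3f\n", x$mu))
  print(x$scaling, row.names = FALSE)
  invisible(x)
}
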