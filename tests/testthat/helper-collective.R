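# Reduced collective-dynamics runs shared by the acceptance checks:
# box 50, 7.5e4 tau, frames every 10 tau, lattice/insertion start per
# coverage. Built once per test run.

collective_run <- function(phi, seed) {
  nm <- sprintf("collective_%g", phi)
  fixture(nm, function() {
    N <- twitchers_for_coverage(phi, twitch_params(box_L = 50))
    p <- twitch_params(n_twitchers = N, box_L = 50, seed = seed)
    simulate_twitchers(p, n_tau = 75000, sample_every = 10,
                       keep_spheres = FALSE, record_events = FALSE)
  })
}

# local maxima of a coverage histogram (interior bins, plus the
# zero-occupancy boundary when it dominates its neighbour)
coverage_peaks <- function(cv) {
  P <- cv$P
  k <- which(diff(sign(diff(P))) < 0) + 1L
  if (length(P) > 1 && P[1] > P[2]) k <- c(1L, k)
  k <- k[P[k] > 0.01]  # ignore noise-level bumps
  cv$phi_local[k]
}

# abscissa of the first sign change, linearly interpolated
first_zero_crossing <- function(curve) {
  ok <- which(is.finite(curve$value))
  r <- curve$r[ok]; v <- curve$value[ok]
  i <- which(v[-length(v)] > 0 & v[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  r[i] + (r[i + 1] - r[i]) * v[i] / (v[i] - v[i + 1])
}
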