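test_that("MSD is exact for ballistic motion and simple displacements", {
  set.seed(1)
  tr <- synthetic_walk(200, 20, "ballistic", speed = 0.3)
  m <- msd(tr, lags = c(1, 2, 5, 10, 20, 50))
  expect_equal(m$msd, 0.3^2 * m$t^2, tolerance = 1e-12)
  expect_equal(fit_beta(msd(tr), c(1, 20)), 2, tolerance = 1e-9)
  # two-frame trajectory with displacement (3, 4)
  com <- array(c(0, 3, 0, 4), c(2, 1, 2))
  m2 <- msd(traj_from_com(com), lags = 1)
  expect_equal(m2$msd, 25)
  expect_error(msd(traj_from_com(com), lags = 5), "span")
})

test_that("MSD and diffusivity recover a known Brownian diffusivity", {
  set.seed(2)
  D0 <- 0.1
  tr <- synthetic_walk(3000, 60, "brownian", D0 = D0)
  m <- msd(tr)
  expect_equal(fit_beta(m, c(1, 100)), 1, tolerance = 0.05)
  D <- diffusivity(m, t_min = 100)
  expect_equal(D, D0, tolerance = 0.05)
  # MSD magnitude: 4 D0 t in 2D
  expect_equal(m$msd[m$t == 10], 4 * D0 * 10, tolerance = 0.1)
})

test_that("the fourth moment obeys the Cauchy-Schwarz bound", {
  set.seed(5)
  for (type in c("brownian", "shell", "zero_gauss")) {
    tr <- synthetic_walk(500, 30, type)
    m <- msd(tr)
    expect_true(all(m$m4 >= m$msd^2 - 1e-12))
    a <- ngp(m)
    expect_true(all(a$alpha2 >= -0.5 - 1e-9))  # -2/(d+2) moment bound
  }
})

test_that("the non-Gaussian parameter separates known step distributions", {
  set.seed(3)
  # Gaussian steps: alpha_2 = 0 at all lags
  g <- ngp(msd(synthetic_walk(2000, 100, "brownian"), lags = c(1, 2, 5)))
  expect_equal(g$alpha2, rep(0, 3), tolerance = 0.05)
  # fixed-length steps: alpha_2 = -1/2 at lag 1 (shell distribution)
  s <- ngp(msd(synthetic_walk(400, 400, "shell"), lags = 1))
  expect_equal(s$alpha2, -0.5, tolerance = 0.02)
  # 50/50 mixture of zero and Gaussian steps: alpha_2 = 1 at lag 1
  z <- ngp(msd(synthetic_walk(400, 400, "zero_gauss"), lags = 1))
  expect_equal(z$alpha2, 1, tolerance = 0.1)
})

test_that("van Hove distributions normalise and collapse diffusively", {
  set.seed(4)
  tr <- synthetic_walk(4000, 50, "brownian", D0 = 0.1)
  for (tt in c(10, 100)) {
    vh <- van_hove(tr, t = tt, bins = 61)
    w <- diff(vh$x[1:2])
    expect_equal(sum(vh$G) * w, 1, tolerance = 1e-6)
    # symmetric within sampling error (independent samples, not origins)
    n_indep <- 50 * (length(tr$time) / tt)
    expect_lt(abs(sum(vh$G * vh$x) * w), 4 * attr(vh, "sd") / sqrt(n_indep))
  }
  # diffusive collapse: Delta x / sqrt(t) has the same law at both lags
  F <- length(tr$time)
  dx1 <- c(tr$com[-(1:100), , 1] - tr$com[1:(F - 100), , 1]) / sqrt(100)
  dx2 <- c(tr$com[-(1:1000), , 1] - tr$com[1:(F - 1000), , 1]) / sqrt(1000)
  ks <- suppressWarnings(stats::ks.test(dx1[seq(1, length(dx1), 97)],
                                        dx2[seq(1, length(dx2), 97)]))
  expect_gt(ks$p.value, 1e-3)
  # two walkers moving along +x and -x: pooled components peak at
  # +-vt (x components) and 0 (y components)
  comb <- array(0, c(51, 2, 2))
  comb[, 1, 1] <- 0.5 * (0:50)
  comb[, 2, 1] <- -0.5 * (0:50)
  trb <- traj_from_com(comb)
  vh <- van_hove(trb, t = 20, bins = seq(-12, 12, by = 0.5))
  peaks <- vh$x[vh$G > 0]
  expect_true(any(abs(peaks - 10) < 0.5) && any(abs(peaks + 10) < 0.5) &&
              any(abs(peaks) < 0.5))
})

test_that("short-time MSV and relative diffusivity behave as defined", {
  set.seed(6)
  tr <- synthetic_walk(500, 20, "ballistic", speed = 0.4)
  expect_equal(msv(msd(tr, lags = 1)), 0.16, tolerance = 1e-12)
  expect_error(msv(msd(tr, lags = 2)), "tau")
  expect_equal(relative_diffusivity(0.05, 0.16), 0.05 / 0.16)
  expect_error(diffusivity(msd(tr), t_min = 1e4), "span")
})

test_that("IAC is 1 for straight motion and near 0 for random steps", {
  set.seed(7)
  tr <- synthetic_walk(300, 10, "ballistic", speed = 0.5)
  r <- iac(tr, bin_width = 5, r_max = 100)
  expect_equal(r$value[r$n > 0], rep(1, sum(r$n > 0)), tolerance = 1e-12)
  sh <- synthetic_walk(2000, 20, "shell", speed = 0.5)
  rs <- iac(sh, bin_width = 2, r_max = 40, origin_stride = 5)
  expect_lt(max(abs(rs$value[rs$r > 2 & rs$n > 100])), 0.05)
})

test_that("IAC recovers the persistence length of a persistent walk", {
  set.seed(8)
  v <- 0.5; Dr <- 0.05   # persistence length v / Dr = 10
  tr <- synthetic_walk(4000, 30, "persistent", speed = v, rot_diff = Dr)
  r <- iac(tr, bin_width = 1, r_max = 40, origin_stride = 7)
  lam <- fit_decorrelation_length(r, range = c(2, 25))
  expect_equal(as.numeric(lam), v / Dr, tolerance = 0.1)
})

test_that("exponential decorrelation lengths are fitted exactly", {
  x <- seq(1, 60)
  curve <- data.frame(r = x, value = exp(-x / 5))
  expect_equal(as.numeric(fit_decorrelation_length(curve, c(1, 60))), 5,
               tolerance = 1e-9)
  curve2 <- data.frame(r = x, value = 7.3 * exp(-x / 5))
  expect_equal(as.numeric(fit_decorrelation_length(curve2, c(1, 60))), 5,
               tolerance = 1e-9)  # prefactor invariance
  set.seed(9)
  noisy <- data.frame(r = seq(0.5, 25, by = 0.5),
                      value = exp(-seq(0.5, 25, by = 0.5) / 4) *
                        exp(rnorm(50, 0, 0.01)))
  expect_equal(as.numeric(fit_decorrelation_length(noisy, c(0.5, 25))), 4,
               tolerance = 0.05)
  neg <- data.frame(r = 1:10, value = c(rep(0.5, 8), -0.1, 0.2))
  expect_warning(fit_decorrelation_length(neg, c(1, 10)), "non-positive")
  expect_error(suppressWarnings(fit_decorrelation_length(neg, c(9, 9))),
               "no usable")
})
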