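test_that("speed decomposition satisfies its weighted identity", {
  s <- solitary_mid()
  d <- speed_decomposition(s)
  expect_equal(d$v_m, d$f_active * d$v_a + (1 - d$f_active) * d$v_r,
               tolerance = 1e-12)
  expect_true(all(unlist(d[c("v_m", "v_a", "v_r")]) >= 0))
  expect_equal(sum(d$occupancy), 1)
  # a frozen all-rest trajectory has zero speeds
  com <- array(5, c(10, 3, 2))
  fr <- traj_from_com(com, box_L = 20)
  dz <- speed_decomposition(fr, discard_frac = 0)
  expect_equal(dz$v_m, 0)
  expect_equal(dz$v_r, 0)
})

test_that("active twitchers move near the damped-chain speed kP / 4 zeta", {
  # head force 1 dragging four spheres of friction 1 each: com speed 0.25;
  # consistent with ~10 tau to traverse the 2.2 sigma retraction distance
  s <- solitary_mid()
  d <- speed_decomposition(s)
  expect_equal(d$v_a, 0.25, tolerance = 0.15)
  expect_lt(d$v_r, 0.05)
})

test_that("pair correlations handle aligned, anti-aligned and random", {
  # identical motion: g_v = 1 in every occupied bin
  set.seed(10)
  F <- 5; N <- 40
  com <- array(runif(F * N * 2, 0, 30), c(F, N, 2))
  tr <- traj_from_com(com, box_L = 30)
  tr$vel <- array(rep(c(0.3, 0.4), each = F * N), c(F, N, 2))
  g <- pair_correlation(tr, "v", bin_width = 1, discard_frac = 0)
  expect_equal(g$value[g$n > 0], rep(1, sum(g$n > 0)), tolerance = 1e-12)
  # two anti-parallel polar twitchers: g_p = -1, nematic mode = +1
  com2 <- array(c(10, 12, 10, 10), c(1, 2, 2))
  tr2 <- traj_from_com(com2, box_L = 20)
  tr2$polar <- array(c(1, -1, 0, 0), c(1, 2, 2))
  gp <- pair_correlation(tr2, "p", bin_width = 1, discard_frac = 0)
  expect_equal(gp$value[gp$n > 0], -1)
  gn <- pair_correlation(tr2, "n", bin_width = 1, discard_frac = 0)
  expect_equal(gn$value[gn$n > 0], 1)
  # directors invariant under sign flips, for every correlator form
  for (form in c("cos2", "dot", "shifted")) {
    tr3 <- tr2
    tr3$polar[1, 2, ] <- -tr3$polar[1, 2, ]
    a <- pair_correlation(tr2, "n", bin_width = 1, discard_frac = 0,
                          form = form)
    b <- pair_correlation(tr3, "n", bin_width = 1, discard_frac = 0,
                          form = form)
    expect_equal(a$value, b$value)
  }
  # isotropic random directors: nematic correlation ~ 0, bounded in [-1,1]
  set.seed(11)
  Fi <- 40; Ni <- 60
  tri <- traj_from_com(array(runif(Fi * Ni * 2, 0, 40), c(Fi, Ni, 2)),
                       box_L = 40)
  th <- matrix(runif(Fi * Ni, 0, 2 * pi), Fi, Ni)
  tri$polar <- array(c(cos(th), sin(th)), c(Fi, Ni, 2))
  gi <- pair_correlation(tri, "n", bin_width = 2, discard_frac = 0)
  ok <- gi$n > 500
  expect_lt(max(abs(gi$value[ok])), 0.1)
  expect_true(all(abs(gi$value[gi$n > 0]) <= 1 + 1e-12))
})

test_that("raft length extraction follows the exponential-fit contract", {
  x <- seq(0.1, 20, by = 0.2)
  curve <- data.frame(r = x, value = 0.4 * exp(-x / 3.2))
  expect_equal(as.numeric(raft_length(curve, range = c(4, 16))), 3.2,
               tolerance = 1e-9)
})

test_that("local coverage accounting is exact", {
  # every twitcher in one sub-domain: mass at 0 and at N A / l^2
  N <- 25
  com <- array(c(runif(N, 2, 8), runif(N, 2, 8)), c(1, N, 2))
  tr <- traj_from_com(com, box_L = 100, params = twitch_params())
  cv <- local_coverage_distribution(tr, discard_frac = 0)
  expect_equal(sum(cv$P), 1)
  occupied <- cv$phi_local[cv$P > 0]
  expect_equal(length(occupied), 2)
  expect_equal(occupied, c(0, N * twitcher_area() / 100))
  # mean local coverage equals the global coverage exactly
  set.seed(12)
  com2 <- array(runif(300 * 2 * 20, 0, 100), c(20, 300, 2))
  tr2 <- traj_from_com(com2, box_L = 100, params = twitch_params())
  cv2 <- local_coverage_distribution(tr2, discard_frac = 0)
  expect_equal(sum(cv2$phi_local * cv2$P),
               coverage_fraction(300), tolerance = 1e-12)
  # ideal-gas placement: unimodal with the mode near phi
  mode_phi <- cv2$phi_local[which.max(cv2$P)]
  expect_lt(abs(mode_phi - coverage_fraction(300)),
            1.5 * twitcher_area() / 100)  # within ~1 occupancy unit
})

test_that("number fluctuations scale as mu = 1/2 for uncorrelated gas", {
  set.seed(13)
  tr <- synthetic_walk(299, 500, "uniform", box_L = 100,
                       params = twitch_params())
  g <- number_fluctuations(tr, discard_frac = 0)
  expect_equal(g$mu, 0.5, tolerance = 0.05)
  expect_equal(g$scaling$phi_mean,
               rep(coverage_fraction(500), nrow(g$scaling)),
               tolerance = 1e-9)
})

test_that("perfectly correlated occupancy gives mu = 1", {
  # all walkers jump together between the two halves of the box: every
  # window's occupancy carries the same binary factor
  set.seed(14)
  F <- 400; N <- 400
  side <- sample(c(0, 50), F, replace = TRUE)
  com <- array(0, c(F, N, 2))
  com[, , 1] <- side + matrix(runif(F * N, 0, 50), F, N)
  com[, , 2] <- matrix(runif(F * N, 0, 100), F, N)
  tr <- traj_from_com(com, box_L = 100, params = twitch_params())
  # window sizes that divide the half-box so no window straddles the jump
  g <- number_fluctuations(tr, window_sizes = c(5, 10, 25, 50),
                           discard_frac = 0)
  expect_equal(g$mu, 1, tolerance = 0.07)
})

test_that("an empty system has zero fluctuations at every window size", {
  tr <- synthetic_walk(50, 0, "uniform", box_L = 100)
  g <- number_fluctuations(tr, discard_frac = 0)
  expect_true(all(g$scaling$sd_occ == 0))
  expect_true(is.na(g$mu))
  expect_error(number_fluctuations(tr, window_sizes = c(10, 20)),
               "3 window sizes")
})
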