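test_that("damped free particle matches the closed-form solution", {
  # m dv/dt = -zeta v + F from rest: v(t) = (F/zeta) (1 - exp(-zeta t / m))
  fp <- twitchr:::free_particle_cpp(1000L, 0.01, 1, 1, 0, c(0.5, 0), 1, 1L)
  vref <- 0.5 * (1 - exp(-fp$time))
  xref <- 0.5 * (fp$time - (1 - exp(-fp$time)))
  expect_lt(max(abs(fp$vx - vref)), 1e-4)
  expect_lt(max(abs(fp$x - xref)), 1e-4)
  expect_equal(fp$vy, rep(0, length(fp$vy)))
  # zero force, zero velocity, T = 0: nothing moves
  still <- twitchr:::free_particle_cpp(100L, 0.01, 1, 1, 0, c(0, 0), 1, 1L)
  expect_equal(still$x, rep(0, length(still$x)))
})

test_that("free diffusion satisfies the Einstein relation", {
  # ensemble of free particles at T = 0.5: MSD ~ 4 (kT/zeta) t in 2D
  kT <- 0.5
  t_end <- 20
  d2 <- vapply(1:400, function(s) {
    fp <- twitchr:::free_particle_cpp(as.integer(t_end / 0.01), 0.01, 1, 1,
                                      kT, c(0, 0), 1000 + s, 2000L)
    n <- length(fp$x)
    fp$x[n]^2 + fp$y[n]^2
  }, 0)
  expect_equal(mean(d2), 4 * kT * t_end, tolerance = 0.15)
})

test_that("engine noise is Gaussian with the fluctuation-dissipation scale", {
  z <- twitchr:::rng_normal_cpp(4e5, 31)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(var(z), 1, tolerance = 0.01)
  expect_equal(mean(z^4) / var(z)^2, 3, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(z[1:1e5], pnorm))
  expect_gt(ks$p.value, 1e-4)
  u <- twitchr:::rng_unif_cpp(1e5, 17)
  expect_true(all(u >= 0 & u < 1))
  expect_equal(mean(u), 0.5, tolerance = 0.01)
})

test_that("identical parameters and seed give identical trajectories", {
  p <- twitch_params(n_twitchers = 8, box_L = 30, seed = 5)
  a <- simulate_twitchers(p, n_tau = 150)
  b <- simulate_twitchers(p, n_tau = 150)
  expect_identical(a$com, b$com)
  expect_identical(a$phase, b$phase)
  expect_identical(a$event_counts, b$event_counts)
  c2 <- simulate_twitchers(p, n_tau = 150, seed = 6)
  expect_false(identical(a$com, c2$com))
})

test_that("a zero-length run returns the initial frame only", {
  p <- twitch_params(n_twitchers = 3, box_L = 30, seed = 2)
  s <- simulate_twitchers(p, n_tau = 0)
  expect_equal(length(s$time), 1)
  expect_equal(s$time, 0)
  expect_true(all(s$phase == 0L))  # everyone starts at rest
})

test_that("random insertion is overlap-free; lattice bonds sit at 0.97", {
  p <- twitch_params(n_twitchers = 120, box_L = 50, seed = 9)
  s <- simulate_twitchers(p, n_tau = 0, init = "insertion",
                          keep_spheres = TRUE)
  pos <- s$spheres$wrapped[1, , ]
  # minimum-image pair distances between spheres of different twitchers
  n <- nrow(pos)
  tw <- rep(seq_len(120), each = 4)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    dx <- pos[(i + 1):n, 1] - pos[i, 1]
    dy <- pos[(i + 1):n, 2] - pos[i, 2]
    dx <- dx - 50 * round(dx / 50); dy <- dy - 50 * round(dy / 50)
    d2 <- dx^2 + dy^2
    d2 <- d2[tw[(i + 1):n] != tw[i]]
    if (length(d2)) dmin <- min(dmin, min(d2))
  }
  expect_gt(sqrt(dmin), 0.9)
  # dense lattice start: all spheres in the box, bonds at equilibrium
  p2 <- twitch_params(n_twitchers = 500, box_L = 50, seed = 9)
  s2 <- simulate_twitchers(p2, n_tau = 0, init = "lattice", warmup_tau = 0,
                           keep_spheres = TRUE)
  pos2 <- s2$spheres$wrapped[1, , ]
  expect_true(all(pos2 >= 0 & pos2 < 50))
  bl <- sqrt(rowSums((s2$spheres$unwrapped[1, -seq(4, 2000, by = 4), ] -
                      s2$spheres$unwrapped[1, -seq(1, 2000, by = 4), ])^2))
  expect_equal(unique(round(bl, 6)), round(bond_equilibrium(), 6))
  expect_error(simulate_twitchers(twitch_params(n_twitchers = 2200)),
               "0.8")
})

test_that("energy of an isolated resting twitcher is conserved at T = 0", {
  p <- twitch_params(n_twitchers = 1, box_L = 30, seed = 4,
                     temperature = 0, rest_exit_prob = 1e-12)
  s <- simulate_twitchers(p, n_tau = 100, record_energy = TRUE)
  e <- s$energy
  drift <- abs(e[length(e)] - e[length(e) %/% 2]) /
    (s$time[length(e)] - s$time[length(e) %/% 2])
  expect_lt(drift, 1e-6)
})

test_that("an unobstructed retraction ends by arrival in about 10 tau", {
  p <- twitch_params(n_twitchers = 1, seed = 12, cone_half_angle = 0)
  s <- simulate_twitchers(p, n_tau = 600)
  cc <- s$event_counts
  expect_gt(cc[["arrive"]], 5)
  expect_equal(cc[["snap"]], 0)
  expect_equal(cc[["exhaust"]], 0)
  ev <- twitch_events(s)
  dur <- ev$time[ev$kind == "arrive"] -
    ev$time[ev$kind == "anchor_placed"][seq_len(cc[["arrive"]])]
  expect_true(all(dur > 8 & dur < 12))
})

test_that("recorded kinematics are independent of the sampling stride", {
  p <- twitch_params(n_twitchers = 5, box_L = 30, seed = 13)
  a <- simulate_twitchers(p, n_tau = 100, sample_every = 1)
  b <- simulate_twitchers(p, n_tau = 100, sample_every = 10)
  idx <- match(b$time, a$time)
  expect_identical(b$com, a$com[idx, , , drop = FALSE])
  # velocities are always per-tau displacements, whatever the stride
  expect_equal(b$vel[-1, , ], a$vel[idx[-1], , ], tolerance = 1e-14)
  expect_identical(b$phase, a$phase[idx, , drop = FALSE])
})
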