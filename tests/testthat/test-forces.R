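# direct evaluation of the pair potentials, used as the oracle
wca_ref <- function(r) ifelse(r < 2^(1 / 6), 4 * (r^-12 - r^-6) + 1, 0)
fene_ref <- function(r) -0.5 * 50 * 1.5^2 * log(1 - (r / 1.5)^2)

test_that("WCA energy matches direct evaluation and is cut at 2^(1/6)", {
  expect_equal(wca(2^(1 / 6))$energy, 0)
  expect_equal(wca(2^(1 / 6))$force, 0)
  expect_equal(wca(1)$energy, 1)
  expect_equal(wca(0.95)$energy, wca_ref(0.95), tolerance = 1e-12)
  expect_equal(round(wca(0.95)$energy, 3), 2.961)
  r <- seq(0.85, 1.3, by = 0.01)
  expect_equal(wca(r)$energy, wca_ref(r), tolerance = 1e-12)
  expect_error(wca(0), "positive")
  expect_error(wca(-1), "positive")
})

test_that("FENE energy matches direct evaluation and rejects overstretch", {
  expect_equal(fene(0)$energy, 0)
  expect_equal(fene(0.97)$energy, fene_ref(0.97), tolerance = 1e-12)
  expect_equal(round(fene(0.97)$energy, 2), 30.46)
  expect_error(fene(1.5), "overstretch")
  expect_error(fene(2), "overstretch")
})

test_that("angle potential is harmonic in the bend with zero at straight", {
  xi <- c(0, 0); xj <- c(1, 0)
  a <- angle_harmonic(xi, xj, c(2, 0))
  expect_equal(a$energy, 0)
  expect_equal(unname(c(a$F_i, a$F_j, a$F_k)), rep(0, 6))
  # theta = pi - 0.1: third sphere rotated off-axis by 0.1
  xk <- c(1 + cos(0.1), sin(0.1))
  b <- angle_harmonic(xi, xj, xk)
  expect_equal(b$energy, 0.5 * 33 * 0.1^2)
  expect_equal(round(b$energy, 3), 0.165)
  expect_equal(b$theta, pi - 0.1)
  # symmetric under bending up or down
  b2 <- angle_harmonic(xi, xj, c(1 + cos(0.1), -sin(0.1)))
  expect_equal(b2$energy, b$energy)
  expect_error(angle_harmonic(c(0, 0), c(0, 0), c(1, 0)), "degenerate")
})

test_that("analytic forces equal finite-difference gradients", {
  set.seed(42)
  h <- 1e-6
  # WCA and FENE: scalar central differences on random separations
  r_wca <- runif(100, 0.88, 1.12)
  expect_equal(wca(r_wca)$force,
               -(wca_ref(r_wca + h) - wca_ref(r_wca - h)) / (2 * h),
               tolerance = 1e-6)
  r_fene <- runif(100, 0.05, 1.4)
  expect_equal(fene(r_fene)$force,
               (fene_ref(r_fene + h) - fene_ref(r_fene - h)) / (2 * h),
               tolerance = 1e-6)
  # angle: full gradient over the six coordinates of random bent triples
  ang_ref <- function(x) {
    b1 <- x[3:4] - x[1:2]; b2 <- x[5:6] - x[3:4]
    phi <- atan2(b1[1] * b2[2] - b1[2] * b2[1], sum(b1 * b2))
    0.5 * 33 * phi^2
  }
  for (q in 1:100) {
    x <- c(0, 0, 1, 0, 2, 0) + rnorm(6, 0, 0.3)
    a <- angle_harmonic(x[1:2], x[3:4], x[5:6])
    Fa <- c(a$F_i[1, ], a$F_j[1, ], a$F_k[1, ])
    Fn <- vapply(1:6, function(k) {
      xp <- x; xm <- x; xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      -(ang_ref(xp) - ang_ref(xm)) / (2 * h)
    }, 0)
    expect_equal(Fa, Fn, tolerance = 1e-5)
    # net force and net torque of the triple vanish
    expect_lt(max(abs(a$F_i + a$F_j + a$F_k)), 1e-12)
    tq <- function(r, F) r[1] * F[2] - r[2] * F[1]
    expect_lt(abs(tq(x[1:2], a$F_i) + tq(x[3:4], a$F_j) +
                  tq(x[5:6], a$F_k)), 1e-9)
  }
})

test_that("pilus force is constant toward the anchor with an inner cutoff", {
  expect_equal(pilus_force(c(0, 0), c(2, 0)), c(1, 0))
  expect_equal(pilus_force(c(0, 0), c(0.05, 0.05)), c(0, 0))
  expect_equal(pilus_force(c(0, 0), c(0, -1.5)), c(0, -1))
  expect_error(pilus_force(c(0, 0), c(NA, 1)), "anchor")
  # minimum image: anchor just across the periodic boundary
  p <- twitch_params(box_L = 10)
  expect_equal(pilus_force(c(9.5, 5), c(0.5, 5), p), c(1, 0))
})

test_that("internal forces of a twitcher balance (momentum conservation)", {
  p1 <- twitch_params(n_twitchers = 1, box_L = 20)
  # straight rod at the bonded equilibrium: every sphere force vanishes
  rod <- straight_rod(10, 10)
  f0 <- total_forces(rod, p1)
  expect_lt(max(abs(f0)), 1e-9)
  # randomly bent rod: net internal force is zero
  set.seed(3)
  bent <- rod + matrix(rnorm(8, 0, 0.05), 4, 2)
  fb <- total_forces(bent, p1)
  expect_lt(max(abs(colSums(fb))), 1e-10)
  # with a retracting pilus the net force equals the pilus force
  anc <- matrix(c(14, 10), 1, 2)
  fp <- total_forces(bent, p1, phase = 2L, anchor = anc)
  hd <- bent[4, ]
  d <- anc[1, ] - hd
  expect_equal(colSums(fp), d / sqrt(sum(d^2)), tolerance = 1e-9)
})

test_that("combined WCA + FENE bond equilibrium is a force balance", {
  # for kF = 50, R0 = 1.5 the bracketing root sits near 0.935 sigma
  req <- bond_equilibrium()
  expect_gt(req, 0.92)
  expect_lt(req, 0.95)
  # root of the combined radial force
  net <- wca(req)$force - fene(req)$force
  expect_lt(abs(net), 1e-8)
})

test_that("cell-list forces equal brute-force all-pairs forces", {
  s <- small_ensemble()
  p <- s$params
  for (f in c(10, 35, 60)) {
    pos <- s$spheres$wrapped[f, , ]
    ph <- s$phase[f, ]
    anc <- s$spheres$anchor[f, , ]
    anc[is.na(anc)] <- 0
    fc <- total_forces(pos, p, ph, anc, method = "cell")
    fb <- total_forces(pos, p, ph, anc, method = "brute")
    expect_lt(max(abs(fc - fb)), 1e-12)
  }
})
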