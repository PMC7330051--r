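# Shared simulation fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# solitary twitcher, default parameters, with event log (moderate length)
solitary_mid <- function() fixture("solitary_mid", function() {
  simulate_twitchers(twitch_params(n_twitchers = 1, seed = 101),
                     n_tau = 2e4, keep_spheres = FALSE,
                     record_events = TRUE)
})

# long solitary run for displacement statistics (also used by acceptance)
solitary_long <- function() fixture("solitary_long", function() {
  simulate_twitchers(twitch_params(n_twitchers = 1, seed = 202),
                     n_tau = 2e5, keep_spheres = FALSE,
                     record_events = TRUE)
})

# small interacting ensemble with sphere data, for io / force tests
small_ensemble <- function() fixture("small_ensemble", function() {
  simulate_twitchers(twitch_params(n_twitchers = 12, box_L = 25, seed = 7),
                     n_tau = 60, keep_spheres = TRUE,
                     record_events = TRUE)
})

# build a minimal twitch_traj from a (F, N, 2) com array
traj_from_com <- function(com, box_L = 100, dt = 1, ...) {
  twitch_traj(time = seq(0, by = dt, length.out = dim(com)[1]),
              com = com, com_wrapped = com %% box_L, box_L = box_L, ...)
}

# straight four-sphere rod (tail first) centred at (cx, cy)
straight_rod <- function(cx, cy, angle = 0, spacing = bond_equilibrium()) {
  off <- (0:3 - 1.5) * spacing
  cbind(cx + off * cos(angle), cy + off * sin(angle))
}
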