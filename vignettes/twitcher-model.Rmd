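---
title: "A coarse-grained model of pili-driven twitching motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of pili-driven twitching motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twitchr)
```

## The model

`twitchr` simulates bacilliform cells that move over a surface by twitching:
cycles of type-IV pilus extension, anchoring, and retraction. The model is
deliberately minimal — it asks what part of collective pre-biofilm dynamics
follows from mechanics and the motility cycle alone, with no signalling,
secretion, growth or hydrodynamics.

Each cell ("twitcher") is a stiff chain of four spheres confined to a 2D
periodic box. In simulation units (sphere diameter `σ`, sphere mass `m`,
energy `ε`, time `τ = sqrt(mσ²/ε)`), every sphere obeys the underdamped
Langevin equation

$$ m\ddot{\vec x}_i = -\zeta \dot{\vec x}_i - \vec\nabla V + \vec\xi_i , $$

with friction `ζ = 1`, Gaussian noise at `k_BT = 2×10⁻⁷`, and time step
`Δt = 0.01τ`. The temperature is deliberately near zero: real surface-bound
bacteria are dominated by biological, not thermal, noise, so the only
important stochasticity enters through the motility cycle. The noise term
is nevertheless implemented with the full fluctuation–dissipation variance
and is exercised by the tests (a free particle reproduces the Einstein
relation).

The potential `V` has three parts, all standard bead–spring ingredients:

* **WCA excluded volume** between *all* sphere pairs (including bonded
  neighbours), `V = 4ε[(σ/r)^{12} − (σ/r)^6] + ε` for `r < 2^{1/6}σ`.
* **FENE bonds** along the chain, `V = −½k_F R_0² ln(1 − (r/R_0)²)` with
  `k_F = 50`, `R_0 = 1.5`. Combined with the WCA repulsion the bond
  equilibrium sits at `0.935σ` (the bracketing root of the combined radial
  force — note that the folklore value `0.97σ` belongs to the softer
  `k_F = 30` parameterisation).
* **Harmonic angle rigidity**, `V = k_H(θ − π)²/2` with `k_H = 33`, which
  keeps the body straight. Internally the bend is represented by the signed
  turning angle of the two bond vectors, which is smooth at `θ = π` and so
  avoids the `1/sin θ` singularity of the textbook formulation.

A body of four spheres at bond equilibrium spans about `3.8σ`; its nominal
footprint is a rod of length `L_body = 4` and width `σ` with circular caps,
`A_twitch = 3 + π/4 ≈ 3.7854`.

### The motility cycle

Each twitcher cycles through three phases:

1. **Rest.** No self-propulsion. At every `τ` boundary a resting twitcher
   leaves the phase with probability 0.1, giving geometrically distributed
   rests with mean `10τ`.
2. **Extension.** After exactly `10τ`, a single "dummy pilus" anchor is
   placed a distance `L_0 = 2.4` from the head sphere, at an angle drawn
   uniformly from `[−π/4, π/4]` about the instantaneous body axis. The
   anchor is fixed in the lab frame.
3. **Retraction.** The head is pulled toward the anchor with a constant
   force `k_P = 1` (zero inside the cutoff `r_0 = 0.2`). The printed form
   of the pilus potential, `V = −k_P(r − r_0)`, has a gradient pointing
   away from the anchor; the force is implemented as attractive, which is
   the only reading consistent with a retracting pilus pulling the head
   toward its adhesion point. Retraction ends when the head **arrives**
   (`r < L_R = 0.2`), the pilus **snaps** (`r > L_S = 3`), or the adhesion
   is **exhausted** (`t_M = 70τ`); the checks run every integration step in
   that order, and the twitcher then rests again with no memory of the
   previous pilus.

The head force `k_P = 1` dragging a total friction `4ζ` moves the centre of
mass at `≈ 0.25 σ/τ`, so an unobstructed retraction covers its `2.2σ` in
roughly `10τ` — always by arrival. This single number anchors most of the
solitary-twitcher phenomenology.

### Integrator and determinism

The engine uses a BAOAB splitting with the exact Ornstein–Uhlenbeck
treatment of the linear drag. Its contracts are behavioural rather than
nominal: a free particle under constant force matches the closed-form
solution of `m v̇ = −ζv + F` to better than `10⁻⁴` over `10τ`, free
diffusion satisfies the Einstein relation, and the energy of an isolated
resting twitcher at `T = 0` is conserved to `< 10⁻⁶ ε/τ`. Pair forces are
found through a cell-binned Verlet list with a `0.25σ` skin whose sole
contract is exact agreement (to `10⁻¹²`) with a brute-force all-pairs
evaluation; minimum-image offsets are baked into the candidate list at each
rebuild, and rebuilds are triggered by accumulated per-sphere displacement.
Randomness comes from a dedicated xoshiro256++ stream with a 128-layer
ziggurat normal sampler, seeded once per run; identical `(params, seed)`
give bitwise-identical trajectories. The sampler is itself tested
(moments, tails, Kolmogorov–Smirnov).

### Initial configurations

The initial state is not part of the model's definition, so the package
makes its construction explicit: for coverage `φ ≤ 0.3` rods are inserted
sequentially at random positions and orientations with a `0.95σ` minimum
sphere separation; denser systems start from an aligned lattice with random
polarity followed by a `1000τ` randomising warm-up that is discarded.
Steady-state statistics (speed decomposition, pair correlations,
coexistence, number fluctuations) additionally discard the first 10% of
recorded frames by default; displacement statistics use all post-warm-up
time origins.

## Estimators

All per-twitcher quantities are centre-of-mass quantities — the mean of the
four sphere positions. (The source description sums rather than averages
over spheres; the mean is used because measured displacement magnitudes
correspond to per-cell displacement, and the two differ only by the
constant factor 4.) Velocities are displacements over one `τ`; the
direction of motion `v̂` is undefined at zero speed and such samples are
excluded from correlation averages rather than coerced.

* **MSD / β** — `Δr²(t)` over all time origins and twitchers on a
  log-spaced lag grid; `β` is the least-squares slope of `log Δr²` vs
  `log t` over a stated window (defaults `[1, 10]τ` and `[10³τ, span/2]`).
* **Non-Gaussian parameter** — `α₂ = (d/(d+2))·Δr⁴/(Δr²)² − 1` with
  `d = 2`. It is bounded below by `−2/(d+2) = −1/2`, attained by
  fixed-length (shell) steps; Gaussian steps give 0 and a 50/50 zero/
  Gaussian mixture gives 1 — all three are test fixtures.
* **Van Hove** `G(Δx, t)` — 1D displacements pooled over both Cartesian
  axes, with a matched-σ Gaussian reference and an optional `t^{1/2}`
  collapse scaling.
* **Speed decomposition** — each `τ` interval is attributed to the phase
  at the interval start, so `v_m = f_a v_a + (1 − f_a) v_r` holds exactly.
* **IAC** — `ρ_v̂(Δr) = ⟨v̂(0)·v̂(Δr)⟩` along each twitcher's own path.
  `Δr` is the *cumulative path length* at `τ` resolution ("distance
  travelled" read literally); net displacement is available as an
  alternative abscissa (`abscissa = "net"`). For each origin the direction
  is compared at the first sample where the abscissa reaches each bin edge.
  Decorrelation lengths come from a least-squares fit of `log ρ` over a
  stated tail range.
* **PAC** — `g(Δr) = ⟨u_γ·u_η⟩` over distinct pairs binned by
  minimum-image centre-of-mass separation (bin width `0.2σ`). For the
  nematic director the default correlator is `⟨cos 2θ⟩`, the standard 2D
  headless form; the two printed variants (`dot` of canonicalised
  directors, and the shifted `3(n·n − 2/3)` form) are available behind the
  `form` argument but are either sign-convention-dependent or of 3D
  normalisation, which is why `cos 2θ` is the default. The proto-raft size
  is the exponential decay length of the nematic PAC tail fitted after the
  smectic peak near one body length (`Δr ≈ 4`).
* **Coexistence** — the box is partitioned into square sub-domains of edge
  `10σ` (100 of them for the full `100σ` box); `P(φ′; φ)` is the histogram
  of instantaneous local coverages with twitchers assigned by wrapped
  centre of mass. Its mean is exactly the global `φ`.
* **Number fluctuations** — for window edges `ℓ` dividing the box, the
  mean and standard deviation of window occupancy over windows and frames;
  `μ` is the log-log slope of `ΔN` vs `⟨N⟩` over the top half of the
  abscissa range. The construction follows the standard `ΔN`-vs-`⟨N⟩`
  reading because a per-area ("coverage units") abscissa is degenerate
  across window sizes: the mean local coverage is the same for every `ℓ`.
  Both axes are also reported in coverage units. `μ = 1/2` is the
  central-limit value (Poisson-placed points are the test oracle);
  rigidly co-moving occupancy gives `μ = 1`.

## Synthetic reference trajectories

`synthetic_walk()` generates ballistic, Brownian, persistent, shell,
zero/Gaussian-mixture and uniformly-redrawn ("ideal gas") trajectories with
known closed-form statistics. These are the oracles for the analysis suite:
parameter recovery (Brownian `D₀`, persistence length `v/D_r`, exponential
`λ`), exact limits (`β = 2`, `α₂ ∈ {0, −1/2, 1}`, `μ ∈ {1/2, 1}`).
They emulate the *statistical structure* of twitcher trajectories, not their
mechanics: there is no excluded volume, no phase structure and no periodic
interaction, so passing those tests validates the estimators, not the
simulator. The simulator itself is validated by the force-field oracles,
the integrator contracts and the motility-cycle distribution tests.

## Problem sizes and run lengths

The package's own test and reproduction runs use a solitary twitcher for
`2–5×10⁵τ` (displacement statistics converge over ~20 independent
persistence times), and reduced ensembles in a `50σ` box — `φ = 0.10`
(N = 66), `φ = 0.19` (N = 125) and `φ = 0.57` (N = 376) — for `7.5×10⁴τ` with
frames sampled every `10τ`. These reproduce the *qualitative* collective
phenomenology (coexistence, giant number fluctuations, the smectic peak);
quantitative curves at the full `100σ`/`10⁶τ`/N up to 2000 scale are
outside a desk-scale run and are expected to sharpen the same features.

## Known limitations and open points

* **Long-time diffusion onset.** Per retraction cycle the body reorients
  by a measured `0.58α` (a deterministic lever-arm response of the
  four-bead chain to the pilus pull), giving a direction persistence time
  of roughly `900τ`. The MSD therefore bends from `β ≈ 2` toward 1 only
  around `10³τ` and is fully diffusive beyond `~3×10⁴τ`: a log-log fit
  over `[10³, 10⁴]τ` yields `β ≈ 1.3–1.4`, and `α₂(10⁵τ)` is still
  slightly negative (`≈ −0.1`). Statements that the dynamics are diffusive
  "beyond `10³τ`" should be read as the *onset* of that crossover.
* The dummy pilus is a single effective appendage of fixed reach; real
  cells extend several pili of variable length with stochastic retraction,
  which would smear the rest/extension shoulder in the MSD.
* The model is strictly 2D, monodisperse, and non-growing; anchors have no
  excluded volume.
* Insertion-based initial states are only available up to `φ ≈ 0.3`;
  beyond that the lattice + warm-up start is used, and slowly coarsening
  structures (dense/dilute coexistence) may retain some memory of it on
  desk-scale run lengths.
* **Finite-size effects in the reduced collective runs.** In the `50σ`
  box at `φ = 0.57` the dense phase percolates, so while the
  local-coverage distribution shows a clear liquid-like peak near
  `φ′ ≈ 0.76–0.83` and giant number fluctuations (`μ ≈ 0.74`), the
  dilute side is a monotone shoulder rather than a distinct gas peak near
  `0.2`: interfacial sub-domains dominate the low-coverage statistics.
  The first- and second-half histograms coincide, so this is a steady
  property of the reduced system, not an equilibration artefact.
  Similarly, the polar pair correlation at `φ = 0.19` has the expected
  structure (aligned at contact, anti-correlated at collision range)
  but its zero crossing (`≈ 2.0σ`) and minimum (`≈ 2.5σ`) sit closer to
  contact than the `2.8σ` / `4.0σ` reported for the full-scale system.
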