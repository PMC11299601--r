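---
title: "Subgradient-projection phase retrieval: models, parameters and study designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgradient-projection phase retrieval: models, parameters and study designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptycrisp)
```

This vignette is the package's own account of the science it implements:
the observation model and its assumptions, the three reconstruction
engines and what their parameters do, what the synthetic-data generator
does and does not emulate, the numerical choices that required a
decision, and the designs of the validation studies the test suite and
`scripts/acceptance.R` run.

## The observation model

A thin specimen is described by a complex transmission function `O`
(modulus = absorption, argument = phase shift) sampled on a pixel grid,
and the illumination by a complex probe field `P` on a smaller window.
At scan position `r_n` the exit wave is the product `ψ_n = P_n ⊙ O_n`,
and the detector records the far-field (Fraunhofer) intensity
`I_n = |F ψ_n|²`. Assumptions baked into this model:

* **Multiplicative (projection) approximation** — the specimen is thin
  enough that propagation through it is a pointwise multiplication. No
  multi-slice treatment.
* **Far-field propagation only**, modeled by the discrete Fourier
  transform. We use the *unitary* normalization (`1/√(MN)` both ways) so
  Parseval's identity holds exactly: real-space and reciprocal-space
  energies and squared errors coincide, which in turn fixes the gradient
  and Lipschitz bookkeeping below with no stray factors.
* **Position split** — a scan position is decomposed into an integer
  part, applied by patch addressing on the object canvas, and a subpixel
  remainder in `[-0.5, 0.5)` applied to the probe as a linear phase ramp
  in the frequency domain (band-limited interpolation; exactly
  energy-preserving and exactly invertible). Rounding is to the nearest
  integer with ties resolved downward so the remainder interval is
  half-open.
* **Poisson counting noise**, drawn once at simulation time. Pixels with
  mean above `1e7` use the rounded normal limit `N(λ, λ)`: at such
  counts the relative skew of the Poisson law is below `1e-3`, and R's
  integer-based Poisson sampler cannot represent the largest doses.

The magnitude projection (`revised_exit_wave()`) replaces the modulus of
`F ψ` with `√I` while keeping its phase, with the convention
`sign(0) = 1` (a zero-modulus model pixel adopts the measured modulus at
zero phase). The projection is exact by construction: the intensity of
the revised wave reproduces the measurement to round-off, which the test
suite checks to `1e-8` relative on random fields.

## The engines

All three engines share the same sweep structure: one iteration visits
every scan position in a fresh random order, and for each sample forms
`ψ`, the projection `ψ'`, the residual `Δ = ψ' − ψ`, updates the object
patch and the probe from the *same pre-update fields*, writes the patch
back, and un-shifts the probe. The permutation stream is seeded
separately from the noise stream.

**ePIE** takes, for the object, the gradient step on
`g(O) = ‖ψ' − P ⊙ O‖²_F` with step size `η = α_o / |P|²_max`. Under the
Wirtinger convention used here the gradient is `conj(P) ⊙ (P ⊙ O − ψ')`
and `|P|²_max` is the Lipschitz constant of that gradient, so any
`α ∈ (0, 1]` makes the update non-increasing in the subproblem cost (a
property the tests verify on 1,000 random instances). The probe update
is symmetric with `α_p` and `|O|²_max`.

**rPIE** divides element-wise by `(1 − γ)|Q|² + γ|Q|²_max` instead of
the global maximum, boosting weakly illuminated pixels; `γ = 1` recovers
ePIE's object update at `α = 1`.

**CRISP** replaces the fixed step by the subgradient-projection
coefficient `G = (e − ξ)₊ / ‖conj(Q) ⊙ Δ‖²_F`, clipped at
`ν / |Q|²_max`. Three mechanisms matter:

* While the sample cost `e` exceeds the threshold `ξ`, the step keeps
  moving even where the gradient is small — the coefficient contains the
  reciprocal of the gradient norm, which is what lets the iteration
  escape shallow stagnation.
* The same reciprocal is a liability at points where the gradient
  vanishes but the cost does not: the implied step is unbounded. The
  clipping cap `ν/|Q|²_max` bounds it; with `ν = 1` and `λ = α` the
  clipped step can never exceed ePIE's, and when the cap is active the
  two updates are *identical* (verified bit-near over 50 iterations in
  the tests). The scale-adaptive setting `ν = (|P|_max, |O|_max)` makes
  the cap follow the field scales instead.
* `ξ` is retuned once per sweep to `c · mean(e)` with `c ∈ (0, 1)`, and
  initialized the same way from the initial fields. The bookkeeping is
  exact and the tests assert the identity `ξ[k+1] = c · mean(e[k])` at
  every iteration. Per-sample costs are stored at direction-computation
  time (the pre-update residual), which is also what enters the tuning
  rule.

Degenerate samples (zero update denominator at positive thresholded
cost) are skipped for that visit and counted; `λ` is accepted in
`(0, 2)` with a warning above 1, since the empirically stable range is
`(0, 1]`.

### Toy regimes

`run_toy_subgradient()` iterates the scalar form of the projection on a
2-D cost with analytic gradient. On the offset bowl `g(x) = ‖x‖² + E`:

* `E = 0, ξ = 0`: the coefficient is constant (`1/4` at `λ = 1`) and the
  iteration converges geometrically to the minimizer, like gradient
  descent.
* `E > 0, ξ = 0`: the coefficient `(‖x‖² + E)/(4‖x‖²)` blows up near the
  minimizer. The iterate map is not monotonically divergent — it is a
  chaotic radial map whose excursions are unbounded over time — so
  "divergence" is detected as the iterate norm exceeding a configured
  bound (default `1e3`, about 500 times the default start radius; from
  the default start the bound is first exceeded near iteration 1,200 of
  the deterministic trajectory). A cap on the coefficient (the clipping
  mechanism) removes the blow-up entirely.
* `E > 0, ξ > E`: the positive part clips to zero once `g(x) ≤ ξ` and
  the iteration parks inside the sublevel set, which is the fixed-point
  behavior the full engine inherits: a sweep in which every sample
  satisfies `e ≤ ξ` changes nothing.

## What the generator emulates — and what it does not

`make_particle_phantom()` draws random disks on a unit-transmission
background, with amplitudes in `(0.7, 0.95)` and phases in
`(-0.4, 0.2)` rad by default — the weak-absorption, phase-dominant
regime of thin specimens under hard X-rays. `make_siemens_star()` is the
standard resolution target. `make_probe()` is an idealized soft-edged
disk with optional quadratic (defocus) phase, normalized to unit energy;
it is *not* a wave-optical model of a zone-plate illumination train, and
detector effects (gaps, point spread, readout noise) are not simulated.
Passing tests on these phantoms therefore demonstrates algorithmic
correctness and the stated convergence properties under a well-specified
forward model; they do not by themselves demonstrate robustness to the
model mismatch real beamline data carry (position errors, partial
coherence, detector artifacts).

`simulate_dataset()` applies one global scale so the largest
zero-frequency intensity equals the dose `I0` (`1e10` high dose, `1e8`
low dose), then draws Poisson noise. The scale is carried by the stored
truth probe amplitude (`× √scale`), so a noise-free dataset is exactly
consistent with its stored truth and the object keeps `|O| ≤ 1`. Scaling
is global, not per pattern: one specimen, one incident flux.

Default initializers are an all-ones object and a unit-profile disk
probe at the nominal illumination diameter with its energy set to the
mean total counts per pattern — by Parseval the total intensity of a
pattern equals the exit-wave energy, so this matches the initial model
flux to the data, which matters when intensities are in raw counts.

## Study designs and problem sizes

The validation studies run at desk scale: a 64 × 64 object canvas, a
16 × 16 probe window, and a 5 × 5 scan — small enough that the whole
suite and the acceptance script each finish in about a minute on one
CPU, large enough that all the mechanisms above are exercised.

**Noise-free recovery** (`noise_free_recovery_study()`): particle
phantom, probe diameter 12 px (softness 0.3, defocus 0.3), exact raster
of step 2 (~83 % linear overlap), 300 iterations, high-dose step sizes,
`c = 0.1` for CRISP since on noise-free data the attainable cost is zero
and the threshold should sit well below the mean. All three engines
reach `R_F` ≈ 5–6 × 10⁻⁴, probe correlation 0.9998 and FRC > 0.95 on
every ring below half-Nyquist. Design notes: at 30–50 % overlap the
sequential engines are *not wrong but slow* — they sit at
`R_F ≈ 2–5 × 10⁻³` after 300 iterations and keep creeping down — and
scan jitter roughly doubles the residual at fixed iteration count, so
the recovery study uses the exact raster while jittered scans are
exercised by the functional tests. FRC and `τ` are evaluated on the
scan-covered bounding box trimmed by `(window − diameter)/2` per side:
the window border is grazed only by the probe's weak tail, converges
arbitrarily slowly for any engine, and says nothing about algorithm
quality.

**Dose ordering** (`dose_floor_rf()`): the `R_F` between a noisy dataset
and its generating truth is the floor below which no reconstruction of
that dataset can go; shot noise scales as `√I`, so the floor at
`I0 = 1e8` (≈ 1.4 × 10⁻³) sits a factor ≈ 10 above the floor at
`I0 = 1e10` (≈ 1.4 × 10⁻⁴).

**Update-order dispersion** (`order_dispersion_study()`): ten
reconstructions per engine differing only in the update-order seed, on a
Siemens-star dataset (jittered step-3 scan, Poisson noise at
`I0 = 1e8`, star-chart step sizes `λ_o = α_o = 0.8`,
`λ_p = α_p = 0.4`, `c = 0.01`, ePIE-like clipping, 150 iterations),
summarized by the variance of the 45 pairwise `τ` scores and pooled
over three replicate datasets. Two design points deserve emphasis:

* *Units.* Intensities are flux-normalized (mean total counts per
  pattern = 1) before reconstruction. The ePIE-like cap `ν = 1` is a
  dimensional quantity: in raw photon-count units `|P|²_max` is ~10⁶ and
  the cap undercuts `G` at every sample, making CRISP's trajectory
  coincide with ePIE's exactly; in flux-normalized units the per-sample
  costs and `ξ` are order-1 quantities (`update_xi` then produces
  thresholds of the magnitude a practitioner would recognize) and the
  cap is commensurate with the subgradient coefficient. ePIE and rPIE
  are invariant to this rescaling; CRISP with fixed `ν` is not, which is
  exactly why the scale-adaptive variant exists.
* *Pooling.* A variance estimated from 45 correlated pairs of 10 runs is
  itself noisy (±~3 % on the CRISP/ePIE ratio), while the two engines'
  per-dataset variances are strongly correlated; averaging each engine's
  variance over three replicate datasets before taking the ratio yields
  a stable directional comparison. The comparison is directional only —
  absolute `τ` values depend on the normalization chosen here and are
  not comparable across studies.

## Numerical choices and degenerate inputs

* Unitary FFT both ways; `back_propagate(propagate(ψ)) = ψ` to `1e-10`.
* `sign(0) = 1` in the magnitude projection.
* Ties in the position split round so the subpixel part lies in
  `[-0.5, 0.5)`.
* Alignment before image comparisons removes the global phase (argument
  of the inner product) and translation (modulus cross-correlation peak,
  parabolic subpixel refinement, applied as a Fourier ramp); without it
  FRC and `τ` are meaningless under the inherent ambiguities of the
  bilinear model.
* FRC rings are 1-frequency-pixel annuli indexed by integer radius;
  empty rings are dropped.
* `R_F` is pooled over all patterns and pixels (a single quotient of
  sums), not averaged per pattern.
* Zero denominators: ePIE/rPIE signal degenerate input when a field is
  identically zero; CRISP skips the sample for that visit (with a count)
  when the update direction is undefined while the cost exceeds `ξ`;
  `ξ` is nonnegative by construction and needs no floor.
* Sub-seeds for phantom, scan, noise and permutations are derived
  deterministically from one master seed and kept below 2³¹.

## Known limitations

Single probe mode, no position refinement, no multi-slice extension, no
detector model beyond Poisson counts, and a bespoke (documented) dataset
container rather than a community file standard. The dispersion
advantage of CRISP measured here is small (a few percent in pooled
`τ`-variance); the regime where it is reported to be large involves real
beamline data whose model mismatch this generator deliberately does not
emulate.
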