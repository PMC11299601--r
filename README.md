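# ptycrisp

Phase retrieval for X-ray ptychography in R: the sequential engines ePIE
and rPIE, and CRISP (clipped reliable iterative subgradient projection),
an algorithm whose per-sample step size adapts to the residual cost and
whose threshold parameter tunes itself.

## The problem

Ptychography scans a localized coherent beam (the *probe* `P`) across a
specimen (the *object* transmission function `O`) and records, at each of
`N` overlapping positions `r_n`, the far-field diffraction intensity

    I_n = | F( P_n ⊙ O_n ) |²  +  noise,

where `O_n` is the object patch at position `n`, `P_n` the shifted probe,
`⊙` the element-wise product and `F` the 2-D Fourier transform. The phase
of the diffracted field is lost; reconstruction ("phase retrieval")
recovers complex `O` and `P` jointly from the intensities.

The sequential engines visit the positions in random order and minimize,
per sample, the exit-wave cost

    e_n = ‖ ψ'_n − P_n ⊙ O_n ‖²_F ,

where `ψ'_n` (the *revised* exit wave) is the current exit wave with its
Fourier modulus replaced by `√I_n`. ePIE takes a fixed gradient step
`α/|P_n|²_max`; rPIE weights the denominator element-wise. CRISP instead
uses subgradient projection,

    O_n ← O_n + λ_o · min{ (e_n − ξ)₊ / ‖conj(P_n) ⊙ Δ_n‖²_F ,
                            ν_o / |P_n|²_max } · conj(P_n) ⊙ Δ_n ,

with `Δ_n = ψ'_n − ψ_n` (probe update analogous). The step keeps moving
while the cost exceeds the threshold `ξ`, which lets it escape shallow
stagnation; the `min` with `ν/|Q|²_max` clips the blow-up that otherwise
occurs where the gradient vanishes (with `ν = 1` and `λ = α` the step can
never exceed ePIE's); and `ξ` is retuned after every sweep to
`c · mean(e)`, so no manual threshold is needed.

The package also provides the forward model (subpixel probe shifts via
Fourier phase ramps, unitary propagation, Poisson noise with dose
scaling), synthetic phantoms/probes/scans, and the evaluation metrics
used to study these engines: the `R_F` factor, Fourier ring correlation
(FRC), the pairwise `τ` dispersion score and reciprocal-space probe
correlation.

## Worked example

```r
library(ptycrisp)

phantom <- make_particle_phantom(c(64, 64), seed = 7)
probe   <- make_probe(c(16, 16), diameter = 12, softness = 0.3, defocus = 0.3)
scan    <- make_scan(5, 5, step = 2, canvas = c(64, 64), window = c(16, 16))
sim     <- simulate_dataset(phantom, probe, scan, I0 = 1e10, noise = "clean")
init    <- initializers_for(sim)

res <- run_crisp(sim$dataset, sim$scan, init$object, init$probe,
                 crisp_params(lambda_o = 1, lambda_p = 0.4,
                              nu = "epie_like", c_tune = 0.1,
                              K = 300, seed = 1))
res
#> <recon_result: crisp, 300 iterations, final R_F = 0.0005906>
probe_correlation(res$probe, sim$truth$probe)
#> [1] 0.9998479
```

The final `R_F` of about 6e-4 means the reconstructed model reproduces
the measured diffraction moduli to a fraction of a percent, and the probe
correlation of 0.9998 means the illumination was recovered essentially
exactly (both up to the inherent global phase/translation ambiguities,
which the metrics remove). `run_pie()` runs the ePIE/rPIE baselines on
the same dataset; `frc()` and `tau_score()` compare object images after
`align_global()`.

A thin command-line wrapper (`inst/cli/ptycrisp`) exposes the same
pipeline as `simulate`, `reconstruct --algo {epie|rpie|crisp}` and
`evaluate` subcommands driven by JSON/YAML configs.

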