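# verdictmri

Voxelwise estimation of prostate tissue microstructure from diffusion MRI
with the VERDICT three-compartment model, for imaging scientists who want
parametric maps (cell radius and compartment volume fractions) from a
standard pulsed-gradient spin-echo acquisition — and for methodologists who
want the two fitting strategies side by side on reproducible synthetic data.

## The model and the two engines

The normalized PGSE signal of a voxel is modelled as

    S = f_IC * S_sphere(R, d_IC) + f_EES * S_ball(d_EES) + f_VASC * S_astrosticks(P)

with signal fractions `f_IC + f_EES + f_VASC = 1`: water restricted in
impermeable spheres of radius `R` (Gaussian phase distribution series, 100
roots), free isotropic diffusion `exp(-b d_EES)`, and pseudo-diffusion along
isotropically distributed sticks, `sqrt(pi) erf(sqrt(bP)) / (2 sqrt(bP))`.
Fixed diffusivities: `d_IC = d_EES = 2e-9 m²/s`, `P = 8e-9 m²/s`; the
b-value is `b = (Δ − δ/3)(γ δ |G|)²`.

Two interchangeable engines fit the model per voxel:

* **`fit_amico()`** — the linearized fit: a dictionary
  `Φ = [Φ_r | Φ_e | Φ_v]` of 19 precomputed compartment signals (17 sphere
  radii from 0.01 to 15.1 µm, one ball, one astrosticks), solved exactly by
  Tikhonov-regularized nonnegative least squares
  `argmin_{x≥0} ½‖Φx − y‖² + λ‖x‖²` with `λ = 0.001`, then
  `f_IC = Σ x_r`, `R = Σ R_j x_r_j / Σ x_r_j`, `f_EES = Σ x_e`,
  `f_VASC = x_v`. Runs at well under a millisecond per voxel.
* **`fit_nlls()`** — the original fit: constrained multi-start
  Levenberg–Marquardt over `(f_IC, R, f_EES)` with
  `f_VASC = 1 − f_IC − f_EES`, minimizing an offset-Gaussian chi-squared
  `Σ (y_k − √(S_k² + σ²))² / σ²`.

Both engines also come in a free-`d_EES` variant (5 ball diffusivities from
1.1 to 3.1e-9 m²/s), and both report the shared `f_obj` goodness-of-fit.
The package ships the five-shell prostate protocol (b = 90–3000 s/mm²,
20 measurements per voxel), a synthetic-data generator (the full
13,050-voxel ground-truth grid with Rician noise), evaluation metrics
(errors, precision ratios, Pearson r²/SSE, Bland–Altman RPC/CV), NIfTI
map output, and a CLI.

## Worked example

Simulate one tissue configuration (`f_IC = 0.45`, `f_EES = 0.35`,
`f_VASC = 0.20`, `R = 8 µm`) at the clinical noise level, and fit ten noisy
replicates with the linearized engine:

```r
library(verdictmri)

protocol <- verdict_protocol()            # 20-measurement prostate scheme
dict     <- verdict_dictionary(protocol)  # 20 x 19 signal dictionary

clean <- verdict_signal(protocol, f_ic = 0.45, f_ees = 0.35, f_vasc = 0.20,
                        radius = 8e-6)
reps  <- add_rician_noise(matrix(clean, 1)[rep(1, 10), ], snr = 20,
                          n_instances = 1, seed = 42)[[1]]

fit <- fit_amico(reps, dict, lambda = 0.001, sigma = 1/20)
head(tidy(fit, units = "um"), 3)
#> # A tibble: 3 × 7
#>   voxel  f_ic f_ees f_vasc       d_ees f_obj radius_um
#>   <int> <dbl> <dbl>  <dbl>       <dbl> <dbl>     <dbl>
#> 1     1 0.612 0.239  0.159 0.000000002  11.8      9.52
#> 2     2 0.601 0.145  0.231 0.000000002  17.4     10.3
#> 3     3 0.691 0.130  0.171 0.000000002  10.4     10.8
```

Each row is one noisy replicate: the intracellular fraction comes back near
its true 0.45 (biased up at this SNR, mean 0.54 over the ten replicates),
the radius near 8 µm (mean 9.4 µm), and `f_obj` is the offset-Gaussian
goodness-of-fit at `σ = 1/SNR`. `glance(fit)` gives the one-row summary;
`autoplot(fit)` histograms of all parameters. The non-linear engine is a
drop-in replacement (`fit_nlls(reps, protocol, sigma = 1/20)`), roughly a
hundred times slower per voxel.

Volume workflows mirror this: `normalize_volume()` divides a 4D NIfTI
acquisition by its TE-matched b = 0 volumes, `fit_volume()` fits every
masked voxel, and `write_parameter_maps()` writes one NIfTI map per
parameter (plus the tumour-conspicuity ratio `f_IC/d_EES`). The same
pipeline is scriptable from a shell via `inst/cli/verdict`
(`simulate`, `build-dict`, `fit`, `evaluate`, `compare`), each run leaving
a JSON manifest of seeds and options.

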