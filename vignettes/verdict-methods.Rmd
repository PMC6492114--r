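---
title: "Methods: the VERDICT model and its two fitting engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the VERDICT model and its two fitting engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(verdictmri)
```

## The tissue model

VERDICT (vascular, extracellular and restricted diffusion for cytometry in
tumours) describes the normalized diffusion-MRI signal of prostate tissue as
a sum of three non-exchanging water populations,

$$S = f_\mathrm{IC}\,S_\mathrm{sphere} + f_\mathrm{EES}\,S_\mathrm{ball}
    + f_\mathrm{VASC}\,S_\mathrm{astrosticks},$$

with nonnegative signal fractions summing to one.

* **Intracellular (sphere).** Water restricted inside impermeable spheres of
  radius $R$ with diffusivity $d_\mathrm{IC}$. The pulsed-gradient spin-echo
  (PGSE) attenuation is computed under the Gaussian phase distribution (GPD)
  approximation as a series over the positive roots $x_m$ of
  $(x^2-2)\sin x + 2x\cos x = 0$ (the derivative condition of the first-order
  spherical Bessel function, $x_1 \approx 2.0816$), truncated at 100 roots.
  Terms decay rapidly; at 100 roots the truncation error is far below the
  other numerical tolerances for radii up to 15.1 um on this protocol.
* **Extracellular-extravascular (ball).** Free isotropic diffusion,
  $S = e^{-b d_\mathrm{EES}}$.
* **Vascular (astrosticks).** Pseudo-diffusion along randomly oriented
  zero-radius sticks, averaged over the uniform sphere of orientations. The
  orientation integral reduces analytically to
  $\sqrt{\pi}\,\mathrm{erf}(\sqrt{bP}) / (2\sqrt{bP})$; a series expansion is
  used below $bP = 10^{-8}$ to avoid cancellation.

All quantities are SI internally (m, s, T/m, m^2/s, s/m^2); user-facing
tables convert $R$ to micrometres and $b$ to s/mm^2. Fixed parameters follow
the prostate model: $d_\mathrm{IC} = d_\mathrm{EES} = 2\times10^{-9}$ m^2/s
and $P = 8\times10^{-9}$ m^2/s. The PGSE b-value is
$b = (\Delta - \delta/3)(\gamma\delta|G|)^2$ with
$\gamma = 2.675153\times10^8$ rad s$^{-1}$T$^{-1}$ (the proton gyromagnetic
ratio; the protocol tables never state the constant, so the CODATA value is
used).

The built-in acquisition (`verdict_protocol()`) has five shells at nominal
b = 90, 500, 1500, 2000 and 3000 s/mm^2, each along three orthogonal
directions with a TE-matched b = 0 measurement, i.e. 20 normalized
measurements per voxel. The three directions are taken as the coordinate
axes; every compartment in scope is isotropic, so the choice does not affect
model signals. Normalization by the per-TE b = 0 image removes T1/T2
weighting, which is why b = 0 entries of every model signal are defined as
exactly 1.

## The linearized (dictionary) engine

The fit is recast as a nonnegative linear inverse problem over a dictionary
$\Phi = [\Phi_r\,|\,\Phi_e\,|\,\Phi_v]$ of precomputed atoms:

* original dictionary: 17 sphere atoms with radii linearly spaced (inclusive
  endpoints) from 0.01 to 15.1 um, one ball atom, one astrosticks atom
  (19 atoms for 20 measurements);
* free-$d_\mathrm{EES}$ dictionary: 13 sphere atoms over the same radius
  range plus 5 ball atoms at $d_\mathrm{EES} \in \{1.1, 1.6, 2.1, 2.6,
  3.1\}\times10^{-9}$ m^2/s and one astrosticks atom.

A dictionary with more atoms than measurements is refused: with the simple
quadratic regularizer the problem would be under-determined.

Per voxel we solve
$$\hat{x} = \arg\min_{x \ge 0} \tfrac12\lVert\Phi x - y\rVert_2^2
          + \lambda\lVert x\rVert_2^2,$$
with $\lambda = 0.001$ by default, exactly (the problem is convex) via
Lawson–Hanson active-set NNLS on the augmented system
$[\Phi;\,\sqrt{2\lambda}I]$, $[y;\,0]$. Parameters follow from the weights:
$f_\mathrm{IC}$ is the sum of sphere weights, $R$ their weight-averaged
radius, $f_\mathrm{EES}$ the sum of ball weights (with the weight-averaged
diffusivity when several ball atoms are present) and $f_\mathrm{VASC}$ the
astrosticks weight. Fractions are deliberately **not** renormalized to sum
to one; the five b = 0 rows softly enforce the sum instead. When the sphere
weights vanish, $R$ is reported as `NA` (a sentinel, never 0/0): a radius is
meaningless where $f_\mathrm{IC}$ is essentially zero.

**Column scaling.** By default the solver works in unit-$\ell_2$-norm atom
space and rescales the weights back to the volume-fraction scale afterwards
(`normalize_columns = TRUE`). This follows the established convention of
dictionary-based convex microstructure fitting, and it matters: the penalty
then acts uniformly across atoms, and the regularization bias on perfect
(noiseless) data is several times larger than with raw signal columns —
which is the documented behaviour of this class of fit (it is *less*
accurate at infinite SNR than with typical clinical noise, because the
regularizer is tuned for noisy data). Raw-column solving, under which the
objective above holds verbatim, remains available via
`normalize_columns = FALSE`, and the optimality (KKT) and convex-QP oracle
checks in the test suite exercise that exact objective.

## The non-linear engine

The original approach estimates $(f_\mathrm{IC}, R, f_\mathrm{EES})$ — plus
$d_\mathrm{EES}$ in the extended variant — by constrained Levenberg–
Marquardt, with $f_\mathrm{VASC} = 1 - f_\mathrm{IC} - f_\mathrm{EES}$.
Constraints are enforced exactly by a smooth reparameterization: a
trigonometric map of the probability simplex
($f_\mathrm{IC} = \cos^2\theta_1$, $f_\mathrm{EES} = \sin^2\theta_1
\cos^2\theta_2$, $f_\mathrm{VASC} = \sin^2\theta_1\sin^2\theta_2$) and
logistic maps of $R$ into $[0.01, 15.1]$ um and $d_\mathrm{EES}$ into
$[1.1, 3.1]\times10^{-9}$ m^2/s. Ten starting points are used by default: a
coarse grid over plausible fractions and radii, topped up with seeded
jitter; the best objective wins, and the whole procedure is deterministic
given the seed. A voxel where every start fails to produce a finite
objective is flagged (`converged = FALSE`), never an exception.

**The objective and its noise scale.** Both engines report the same
offset-Gaussian chi-squared goodness-of-fit,
$$f_\mathrm{obj} = \sum_k \big(y_k - \sqrt{S_k^2 + \sigma^2}\big)^2 /
\sigma^2,$$
which approximates the Rician mean of magnitude data at noise level
$\sigma$. At $\sigma = 0$ the plain residual sum of squares is reported
(same minimizer). For the direct API the default is $\sigma = 0$, so
noiseless self-consistency holds to solver precision. The simulation study
runner instead fixes the non-linear engine's $\sigma$ at $1/20$ for *all*
SNR conditions, emulating a processing pipeline whose noise floor is
calibrated once from the acquisition (the clinical b0 SNR of this protocol
is about 20) rather than re-tuned per experiment. This choice gives the
non-linear engine a small, realistic bias on clean data; the
SNR-matched alternative makes the noiseless fit exact and its
precision ratios degenerate. Both conventions are exposed
(`nlls_sigma`).

## The synthetic study

`verdict_parameter_grid()` reproduces the study's ground truth: 30 equally
spaced values of $f_\mathrm{IC}$ and $f_\mathrm{EES}$ on $[0, 1]$, keeping
pairs with $f_\mathrm{IC} > 0$ and $f_\mathrm{IC} + f_\mathrm{EES} \le 1$
(435 pairs — pairs with zero intracellular fraction are excluded entirely,
the unique reading under which $435 \times 30 = 13{,}050$ voxels holds), each
crossed with 30 radii equally spaced from 0.02 to 15 um. Rician noise
replaces each measurement $S$ by $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$
with independent zero-mean Gaussians of standard deviation $1/\mathrm{SNR}$,
the SNR being defined on the normalized b = 0 signal (equal to 1). Noise is
applied to all 20 entries including the b = 0 rows, and the noisy data are
not re-normalized; the alternative (dividing by the noisy per-TE b0) was
examined and degrades the fraction estimates without matching the reported
behaviour better. Ten instances per finite SNR reproduce the study
conditions; every replicate's seed is recorded.

What the generator emulates: the parameter ranges, the protocol, and
magnitude (Rician) noise at b0-referenced SNR. What it does not: partial
volume with non-prostate tissue, T2 heterogeneity within a voxel, exchange
between compartments, motion/registration residuals, anisotropy of the EES,
or spatially varying noise. Passing recovery tests on this grid therefore
demonstrates correctness of the estimator, not robustness to everything a
scanner does.

## Evaluation conventions

Errors are estimate minus truth per voxel; radius errors are reported in um
and computed only where the true $f_\mathrm{IC}$ is positive, with undefined
radius estimates dropped from radius summaries rather than coerced to zero.
Summary statistics (mean and SD of absolute errors, and of signed errors)
are pooled over voxels and noise instances. The precision ratio of a
parameter is SD(errors at SNR 20) / SD(errors at infinite SNR); absolute
errors are the default, signed-error ratios are reported alongside. Pearson
$r^2$ with the sum of squared differences, Bland–Altman repeatability
(bias, RPC $= 1.96\,\mathrm{SD}$ of scan–rescan differences, and CV
$= \mathrm{SD}/(\sqrt2\,\bar m)$, both as % of the grand mean of all
measurements — the denominator convention is ours, the source being silent),
and a Welch test on objective-function errors complete the metric set.
Engine comparisons on goodness of fit use the achieved `f_obj` values
directly — the objective is itself the misfit measure — rather than
deviations from the objective evaluated at the true parameters (both are
available in the study output).

A reproduction caveat worth stating plainly: the printed precision ratios of
the reference implementations (1.75 and 0.95 for the dictionary engine's
$f_\mathrm{IC}$ and $R$; 2.39 for the non-linear $f_\mathrm{IC}$) embed the
noiseless-data error structure of those specific solver stacks, which their
authors attribute partly to numerical instability on perfect data. An exact
active-set solver and a tightly converged LM produce smaller noiseless error
spread, hence systematically larger ratios (about 2.8, 1.25 and 4 under the
study conditions here), while reproducing the qualitative structure — the
$f_\mathrm{IC}$ ratio is the largest, the $R$ ratio the smallest, and the
non-linear engine degrades more with noise than the linear one.

## Numerical choices

* Sphere eigenvalue roots: bracketed bisection (`uniroot`, tolerance
  1e-14) on a sign-change scan; the first 100 roots are cached per session.
* Series accumulated in increasing-root order in double precision; the
  exponential pair $e^{-d\alpha^2\Delta\pm\delta}$ is evaluated directly to
  avoid 0/0 underflow at large roots.
* NNLS: active-set iterations capped at 300 (never reached on these
  problems); equality subproblems solved by QR. KKT residuals are held to
  1e-8.
* LM: `nls.lm` with `ftol = ptol = 1e-10`, 100-iteration cap per start.
* Monte-Carlo sphere oracle: walkers start uniform in the sphere, take
  Gaussian steps with radial mirror reflection, and accumulate phase by the
  midpoint rule; the default step gives an RMS displacement of $R/20$ per
  step. The oracle validates the GPD series where the Gaussian-phase
  assumption holds (moderate attenuation: small radii on any shell, large
  radii on the weaker shells, e.g. 0.2% at $R = 8$ um / b = 500 and 0.6% at
  $R = 15$ um / b = 500). At strong attenuation the GPD itself deviates from
  the random-walk ground truth (about 1.5% at $R = 8$ um / b = 2000,
  over 10% at $R = 15$ um / b = 3000) — a property of the approximation
  shared by every implementation of this model family, not an
  implementation error, and the reason the oracle comparisons are made in
  the validity regime.
* Degenerate cases: $R$ is `NA` when no sphere weight survives; a pure-ball
  voxel flags `radius_identifiable = FALSE` in the non-linear engine
  ($f_\mathrm{IC} < 10^{-3}$).

## Problem sizes

The test suite runs the full 13,050-voxel grid for the dictionary engine
(10 noise instances at SNR 20 plus the noiseless pass) and a uniform
500-voxel subsample with 3 instances for the non-linear engine; the
SNR-trend check uses 150 voxels with 2 instances at each finite SNR. These
sizes were chosen so the whole suite completes comfortably on a single CPU
while keeping the Monte-Carlo and sampling error of each asserted quantity
well below its tolerance. `scripts/acceptance.R` re-runs the same
computations from scratch.

## Limitations

The model assumes impermeable spheres, a single isotropic EES diffusivity
per voxel, and no exchange; the dictionary fixes $d_\mathrm{IC}$ and $P$.
The regularization weight is a global constant, not adapted to local SNR.
Registration, ROI drawing and any clinical interpretation are out of scope:
the volume interface consumes already-registered NIfTI data.
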