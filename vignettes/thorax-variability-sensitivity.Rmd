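---
title: "Methods: population thorax variability and rib fracture risk sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population thorax variability and rib fracture risk sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoraxvar)
```

## The problem

The risk that a vehicle occupant sustains rib fractures in a crash varies
strongly between individuals, even under identical loading, because thorax
geometry and tissue material properties vary across the population. When a
finite-element human body model (HBM) is used as an occupant substitute, it
represents a single fixed individual; to understand which sources of human
variability matter most for predicted rib fracture risk, the model must be
parametrized and the output variance decomposed over those parameters.

`thoraxvar` implements that pipeline: a 15-parameter scaling model of thorax
geometry and materials, a probabilistic model of the risk of two or more
fractured ribs (NFR2+) from per-rib peak strains, and a variance-based
global sensitivity analysis computed from a small Gauss-quadrature design
via the multiplicative dimensional reduction method (M-DRM). Because crash
simulation itself is expensive and proprietary, the package includes a
documented surrogate thorax model (beam bending of elliptical-annulus rib
sections) so that every stage can be exercised, tested and reproduced on a
desktop. The surrogate is a stand-in, not a fidelity claim; an adapter
(`tabulated_strain_model()`) accepts externally computed strain tables in
its place.

## The 15-parameter variability model

Each parameter is driven by a unitless scaling coordinate $s \in [-2, 2]$,
interpreted as a number of population standard deviations for geometry and
rib material parameters, as a percentile-interpolation coordinate for costal
cartilage, and as a position in a bounded range of experimental behaviours
for the soft tissues.

**Geometry.**

* Six ribcage shape coordinates scale the scores of the leading principal
  components of a statistical shape model of rib centroidal curves
  (`generate_ribcage()`): $C_i(s) = \mu + P_i^T \sigma_i s$.
* Cortical bone thickness is scaled multiplicatively and identically at all
  nodes of all 24 ribs, $T(s) = \exp(\log T_{nom} + \sigma_\mu s)$ with
  $\sigma_\mu = 0.22$, the SD of log-normal location parameters fitted to
  individual thickness maps.
* Rib cross-sectional width and height receive additive offsets of 1.36 and
  1.96 mm per unit $s$, so $s = \pm 2$ produces the $\pm 2.7$ mm and
  $\pm 3.9$ mm offsets that correspond to $\pm 2$ SD of the minimum and
  maximum cross-sectional area moments of inertia. The source expressions
  are also quoted with coefficients 2.72 and 3.92 applied per unit $s$,
  which is internally inconsistent with the $\pm 2$-SD statements and with
  the quoted width SD of 1.35 mm; we adopt the per-SD reading and expose
  the alternative through the `width_per_sd` / `height_per_sd` arguments.

**Materials** (units exactly as in the underlying material models):

* Cortical bone (bi-linear): $E = 14.7 + 2.0 s$ GPa,
  $\sigma_Y = 100.7 + 12.9 s$ MPa, $P = 1.94 + 0.5 s$ GPa.
* Trabecular bone (bi-linear, MPa): $E = 25.7 + 46.7\,g(s)$,
  $\sigma_Y = 0.42 + 0.65\,g(s)$, $P = 5.66 + 11.9\,g(s)$. The published
  scaling term is typeset ambiguously ("0.95\*s4"); we use
  $g(s) = 0.95 s / 4$, which keeps all three parameters positive over the
  scaling range (at $s = -2$, $P \approx 0.0075$ MPa) and matches the
  stated intent of covering 95% of the parameter range. The reading is
  overridable through the `g` argument.
* Costal cartilage: $E_{eff} = 21.4 + 1.15 s^2 + 9.05 s$ MPa, a quadratic
  that interpolates the 5th-95th percentiles of the log-normal modulus
  distribution with mean 21.4 and SD 12.0 MPa. The package tests verify the
  endpoints against a moment-matched log-normal to 0.5%.
* Adipose and muscle tissue (Ogden with Prony series for adipose): the
  tabulated expressions for $\nu$, $\mu$, $\alpha$ and $G_{1..3}$. One
  source table prints the muscle $\mu$ extremes in transposed columns; the
  parametric expression $\mu = 108 + 22.5 s$ Pa is authoritative here.

**Distributions.** Geometry and rib-material coordinates are standard
normal truncated to $[-2, 2]$ and renormalized. Soft-tissue coordinates are
uniform: their ranges represent differences between experimental setups
rather than a population, so every behaviour receives equal weight. The
cartilage coordinate's density is a centred normal with
$\mathrm{SD} = 2 / \Phi^{-1}(0.95) \approx 1.216$, truncated to $[-2, 2]$:
this is the unique centred normal for which $s = \pm 2$ falls at the
5th/95th percentiles, preserving the percentile correspondence of the
interpolation. All densities integrate to 1 over the range (checked by
quadrature to 1e-8).

## Shape model and thickness fitting

`fit_shape_pca()` performs mean-centred PCA on whole-ribcage coordinate
vectors (24 curves, fixed point count per curve, left and right stacked so
the modes are whole-ribcage modes). Score SDs use the $n-1$ convention, and
each component is oriented so its largest-magnitude loading is positive —
PCA signs are arbitrary, and a deterministic convention is needed for the
scaling coordinate to have reproducible meaning. Curve resampling is
arc-length uniform with 20 points per rib by default; the original point
density is not documented in the source data, and any count that resolves
the curve shape gives equivalent mode structure.

`fit_thickness_lognormal()` uses closed-form log-moment estimators (the
exact MLE for a log-normal) rather than iterative optimisation, for
determinism. `population_mu_sd()` is the sample SD of fitted log-means
across individuals; on synthetic data generated at the study scale (33
individuals) it recovers the generating value 0.22 within three standard
errors.

## Risk model

Per-rib fracture probability uses a log-normal probit in strain with a
linear age adjustment,
$p = \Phi\big((\ln \varepsilon - (b_0 + b_{age}\,a)) / \sigma\big)$,
with occupant age fixed at 45 years by default. The published coefficient
values for this family of risk functions are not printed in the source we
follow, so the defaults ($b_0 = -3.687$, $b_{age} = -0.005$,
$\sigma = 0.25$: median fracture strain about 2% at age 45) are documented
placeholders; `risk_function()` accepts published coefficients and
round-trips through JSON. Strains below 1e-12 map to probability zero.

NFR2+ aggregates per-rib probabilities assuming independent fractures: the
fracture count is then Poisson-binomial and
$\mathrm{NFR2+} = 1 - P_0 - P_1$, computed by the stable two-state
recursion over ribs (exact at probabilities 0 and 1). Independence is the
standard assumption of the probabilistic rib-fracture framework; the
combination rule is kept behind `nfr2plus()` so alternatives can be
substituted. A $2^n$ enumeration oracle (`nfr2plus_bruteforce()`) verifies
the closed form on a thousand random vectors in the test suite.

## Sensitivity analysis

The output variance is decomposed as
$V_Y = \sum_i V_i + \sum_{i<j} V_{ij} + \dots$, with Sobol indices
$S_i = V_i / V_Y$, $S_{ij} = V_{ij} / V_Y$, and totals $S_{Ti}$. M-DRM
approximates the model around the cut-point $C$ (all $s = 0$) by a
normalized product of univariate cuts,
$h(x) \approx h_0^{1-n} \prod_i h_i(x_i)$, so that all indices follow from
one-dimensional integrals. With $\nu_i = E[h_i]$, $\tau_i = E[h_i^2]$ and
$r_i = \tau_i / \nu_i^2$:

$$S_i = \frac{r_i - 1}{\prod_k r_k - 1}, \qquad
S_{ij} = \frac{(r_i - 1)(r_j - 1)}{\prod_k r_k - 1}, \qquad
S_{Ti} = 1 - \frac{\prod_{k \ne i} r_k - 1}{\prod_k r_k - 1}.$$

Expectations are computed with Gauss-Legendre nodes on $[-2, 2]$ weighted
by each parameter's (truncated, renormalized) density — this honours the
non-uniform distributions while keeping the quadrature abscissae common
across parameters. A Gauss-Hermite rule would be the natural alternative
for untruncated normals; since all coordinates here are truncated to a
common finite range, the density-weighted Legendre rule is used throughout.
A full study costs $n \cdot N_{GP} + 1 = 76$ model evaluations per load
case at the default five-point rule, versus $3^{15} \approx 14.3$ million
for a three-level full factorial (`factorial_cost()`).

Degenerate situations are handled explicitly: a constant model (zero
variance) returns all-zero indices with a flag; a vanishing one-dimensional
mean $\nu_i$ (output changing sign around the cut-point) is an error, since
the ratios $r_i$ are then undefined; node outputs within 1e-6 of the risk
bounds trigger a saturation warning. Ratios are clamped to $r_i \ge 1$
against round-off (Jensen), and the variance is evaluated in the
numerically stable form $h_0^2(\prod_k \tau_k/h_0^2 - \prod_k \nu_k^2/h_0^2)$.
Rankings sort by descending $S_{Ti}$, then descending $S_i$, then name.

**Known limitation — and why the oracle matters.** M-DRM is exact for
multiplicative models (the package tests assert agreement with analytic
Sobol indices to 1e-10) and accurate for near-multiplicative ones, such as
a dominated additive model with an offset. It is structurally unable to
represent pure, non-multiplicative interactions: for the Ishigami function
the term $b x_3^4 \sin x_1$ enters the univariate cut $h_3$ as a
multiplicative factor whenever $\sin c_1 \ne 0$, so part of the pure
$x_1 \times x_3$ interaction variance is attributed to the first-order
index of $x_3$ regardless of the cut-point or the number of quadrature
points (the ratio $r_3$ is invariant to the cut-point scale). The
Monte Carlo oracle (`sobol_oracle()`, Saltelli/Jansen estimators with
standard errors) quantifies exactly this model error in the test suite:
agreement is within Monte Carlo error for the multiplicative and additive
battery functions and deviates by up to ~0.4 in total index for Ishigami.
Conclusions drawn from M-DRM on a response with strong non-multiplicative
interactions should therefore be treated as indicative and spot-checked
against Monte Carlo estimates when the model is cheap enough.

## The surrogate thorax

`peak_rib_strain()` maps a parameter vector and a load case to 24 per-rib
peak strains through beam bending:
$\varepsilon_r = M_r c_r / (E I_r) \cdot A_{soft} \cdot A_{cart}$, with the
bending moment distributed over ribs by the load case (frontal: ribs 2-8
bilaterally, peaking at ribs 4-6; near-side: struck-side ribs 3-9, peaking
laterally), perturbed multiplicatively by the shape coordinates and
renormalized so the total transmitted load is conserved. Sections are
elliptical annuli built from per-level nominal dimensions (minor axis
7.6-9.2 mm, major axis 12-16 mm, cortical shell 0.5-0.6 mm — chosen once as
anthropometrically plausible values) after applying the geometry scalings;
in-plane bending uses the minimum area moment with extreme-fiber distance
$W/2$ (the width-dominated axis), which is what makes thickness, width and
cortical stiffness the dominant parameters and height subordinate. The
soft-tissue and cartilage/trabecular factors are deliberately weak
(≤ ~5% strain modulation across the range) so these parameters rank low, as
configuration data in `surrogate_config()`.

`calibrate_load()` sets the moment scale by monotone root finding so that
the cut-point NFR2+ equals a target (0.51 by default, within 1e-4),
mirroring how crash severity is chosen so the baseline model predicts close
to 50% risk. Baseline risk is therefore a calibration anchor, never a
prediction of the surrogate. Within the top three parameters the
surrogate's index ordering is a near-tie between width and thickness; the
reproducible claim is the membership of the top-three set in both load
cases, stable at both three- and five-point quadrature.

`conserve_mass()` carries the bookkeeping factor $1/(1+v)$ that keeps
soft-tissue mass constant under volume-changing geometry morphs.

## Synthetic data: what it emulates, and what it does not

`generate_population()` produces ribcage populations as a smooth template
(semi-elliptical arcs with level-dependent span, depth, pump-handle droop
and slight twist; arc length growing from rib 1 to rib 7) plus six known
orthonormal shape modes with normal scores (SDs 12, 8, 6, 4, 3, 2.5 mm) and
iid residual noise of 0.04 mm per coordinate — calibrated so that PCA at
the study sample size (n = 89) recovers the generating mode subspace within
5 degrees and the first six components explain over 90% of variance.
Metadata is sampled over windows (age 16-80 y, height 1.60-1.95 m, weight
60-95 kg) that straddle the average-male inclusion criteria (age > 18,
height 1.72-1.82 m, weight 72-82 kg) so filtering is exercised.
`generate_thickness_maps()` draws per-subject log-normal maps whose
log-means scatter with SD 0.22 (33 subjects, 2000 nodes by default).
Ground truth is always returned (and serializable as `*.truth.json`
sidecars) so recovery tests never depend on the pipeline under test.

These generators reproduce the statistical structure the pipeline assumes —
low-rank shape variation, log-normal thickness, metadata windows — not
anatomy: passing recovery tests demonstrates that the estimators are
correct at the study's sample sizes, not that real CT-derived populations
satisfy the low-rank-plus-noise model. Likewise the deterministic test
battery (`make_test_functions()`) carries analytic Sobol indices
(multiplicative, additive, Ishigami, constant) recomputed from the standard
closed forms.

## Reproducibility and problem sizes

The main pipeline is deterministic: only the Monte Carlo oracle and the
synthetic generators take seeds, and both restore the global RNG state. The
test suite runs the full two-case study (152 surrogate evaluations plus
calibration) in well under a minute; the oracle comparisons use 65,536 base
samples; recovery tests use the study sample sizes n = 89 and 33. Reports
(`run_study(out_dir = ...)`) contain only deterministic content, so
identical configurations produce byte-identical bundles; the run log
records the resolved scaling conventions (per-SD width/height coefficients,
trabecular scaling term) to keep those choices auditable per run.
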