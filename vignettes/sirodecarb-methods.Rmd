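---
title: "Models and methods in sirodecarb"
author: "sirodecarb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sirodecarb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirodecarb)
```

# Scope

`sirodecarb` analyses the three assay types used to characterize sirohaem
decarboxylase (AhbA/B), the enzyme of the alternative haem biosynthesis
pathway that removes the two acetate carboxyls of sirohaem:

1. **progress curves** — concentrations of sirohaem (S1),
   monodecarboxysirohaem (S2) and didecarboxysirohaem (S3) versus time from
   stopped anaerobic assays, fitted as whole curves to a two-step kinetic
   model;
2. **redox titrations** — absorbance of the enzyme-bound haem Q-band versus
   applied potential, fitted to a one-electron Nernst model;
3. **pyridine haemochrome spectra and HPLC traces** — reduced-minus-oxidized
   difference spectra for haem typing, and chromatogram peak assignment by
   retention time.

Every analysis stage has a matching synthetic-data generator, so the whole
pipeline can be exercised and validated without experimental data.

# The kinetic model

The cascade S1 → S2 → S3 is catalysed by a single active site. Each step is
Michaelis–Menten in its own substrate, with the other substrate competing
through its own Michaelis constant and the product inhibiting through the
tight-binding constant $K_i$:

$$v_1 = \frac{V_{max1}\,(E/E_{ref})\; S_1}
            {K_{m1}\left(1 + S_2/K_{m2} + S_3^{free}/K_i\right) + S_1},
\qquad
v_2 = \frac{V_{max2}\,(E/E_{ref})\; S_2}
            {K_{m2}\left(1 + S_1/K_{m1} + S_3^{free}/K_i\right) + S_2},$$

closed by the stoichiometry
$\dot S_1 = -v_1,\ \dot S_2 = v_1 - v_2,\ \dot S_3 = v_2$, which conserves
the total tetrapyrrole concentration exactly.

**Tight binding and the free-product term.** Because $K_i$ (≈ 1.8 µM) is of
the same order as the enzyme concentration (2.3 µM), a substantial fraction
of the product is enzyme-bound, and the inhibition term must use the *free*
product concentration. We take it from the binary binding (Morrison)
quadratic,

$$[ES_3] = \tfrac12\left((E_0 + S_3 + K_i) -
 \sqrt{(E_0 + S_3 + K_i)^2 - 4E_0S_3}\right),
\qquad S_3^{free} = S_3 - [ES_3].$$

This choice is not cosmetic. If total $S_3$ is used instead, mass
conservation ($S_3 = T - S_1 - S_2$ at fixed total $T$) makes each rate's
denominator affine in $(S_1, S_2)$ with a free common scale, and an *exact*
one-parameter family of parameter sets then reproduces any single-total
progress curve perfectly: the five constants are structurally
unidentifiable from exactly the experiment the model is meant to analyse.
With the free-product correction the quadratic breaks that collapse, and we
verified numerically that refits from widely perturbed starting guesses
converge back to the generating constants to machine precision.

**Parameters.** `Km1`, `Km2` (µM) are the Michaelis constants of the two
steps, `Vmax1`, `Vmax2` (µM min⁻¹) the limiting rates *at the reference
enzyme concentration* `Eref` (default 2.3 µM, the standard assay); rates
scale linearly in enzyme concentration. `Ki` (µM) is the product
dissociation constant. `ddAhbABParams()` returns the published set for the
*D. desulfuricans* enzyme (11.74, 44.63, 9.94, 33.22, 1.77).

**Integration.** Trajectories are computed with the adaptive, stiff-capable
`lsoda` at relative tolerance $10^{-8}$ and absolute tolerance
$10^{-10}$ µM. States are clipped at zero inside the right-hand side, and
sub-tolerance negative outputs are clipped in the returned object.
Conservation of the total holds to well below $10^{-6}$ µM over the
standard 0–120 min grid; a fixed-step fourth-order Runge–Kutta oracle at
step $10^{-4}$ min agrees with the adaptive trajectory to relative
$10^{-6}$.

# Progress-curve fitting

`fitTimeCourse()` estimates all five constants simultaneously by
Levenberg–Marquardt least squares on the simulated trajectories of all
three species. Design choices:

- **Log-parameter space.** Optimization is over $\log$ parameters, which
  enforces positivity without active bounds; standard errors are mapped
  back by the delta method.
- **Objective.** Unweighted residuals pooled over species and times by
  default; `weighting = "per_species"` rescales each species by the
  reciprocal of its observed standard deviation.
- **Replicates.** Averaged point-wise before fitting (`replicates =
  "mean"`, matching how such assays are usually reported); `"joint"`
  stacks all replicates instead.
- **Initial conditions.** Taken from the first row of the (averaged) data,
  not fitted.
- **Multistart.** Five starts — the supplied guess plus four log-uniform
  perturbations within ±50%, drawn from a fixed seed — with the best final
  objective winning and ties broken by first found. The reported residual
  sum of squares therefore never exceeds the objective at the supplied
  guess.
- **Diagnostics.** Non-convergence is flagged, never silent; a
  rank-deficient normal matrix triggers a warning naming the dominant flat
  parameter combination. `estimateUncertainty()` offers linearized errors
  (finite-difference Jacobian, residual-variance scaling) and
  residual-resampling bootstrap errors, both deterministic given their
  seed.

**Practical identifiability.** A single progress curve at one total
substrate concentration is a weak design for a five-parameter model: the
normal matrix of the fit is extremely ill-conditioned (the fitter warns
about the dominant flat direction), so while noiseless data refit exactly,
realistic noise lets estimates slide along a nearly flat valley in which Michaelis
constants and limiting rates rise and fall together. The package's
Monte-Carlo tests document this honestly: at 5% multiplicative noise the
median parameter errors are several-fold larger than the nominal
uncertainties quoted for this assay format. Users planning quantitative
work should fit several progress curves at different starting
concentrations jointly, which breaks the valley; the fitting interface
accepts any time grid and initial condition to support that.

# Nernst analysis

The titration is modelled as a two-state mixture at a single wavelength,

$$A(E) = A_{ox} + \frac{A_{red} - A_{ox}}
 {1 + \exp\!\left(\frac{nF}{RT}(E - E_m)\right)},$$

with potentials in mV versus NHE. The electron count is fixed (default
$n = 1$, the Fe³⁺/Fe²⁺ couple) and the temperature defaults to 298.15 K
(not recorded for the original titration; at 25 °C the curve moves one
decade of the redox ratio per ≈ 59.16 mV). $E_m$, $A_{ox}$ and $A_{red}$
are fitted by Levenberg–Marquardt from data-derived starts (plateau means
and the half-transition crossing). No direction is assumed — the reduced
form may absorb more or less than the oxidized. Constant absorbance, or a
fitted amplitude below $10^{-3}$ of the data span, raises a no-transition
error instead of returning a meaningless midpoint. The fit is exactly
translation-equivariant in potential and scale-equivariant in absorbance,
and agrees with a 0.1 mV grid-search oracle in which the two asymptotes
are profiled out linearly.

# Haemochrome difference spectra and haem typing

`differenceSpectrum()` subtracts oxidized from reduced point-wise and
refuses mismatched wavelength grids — no silent interpolation, because
resampling artefacts would bias apex positions. `findAlphaPeak()` takes
the discrete maximum in the 540–575 nm window and refines it by parabolic
interpolation through the maximum and its neighbours; on noiseless
Gaussian bands the apex is recovered to well under one fifth of the grid
spacing. A flat or monotone window raises a no-peak error. The β band
(≈ 527 nm) can be reported by passing `window = c(522, 535)` but plays no
part in classification.

`classifyHaem()` maps the α apex to a haem type: ≥ 555 nm → `haem_b`,
≤ 551 nm → `haem_c`, otherwise `intermediate`. The boundaries were chosen
so that the three reference cases of this enzyme family (556 nm b-type,
554 nm shifted/protein-bound, ≈ 550 nm c-type) classify accordingly, and
they are exposed as arguments. Classification is refused outside
540–575 nm.

# HPLC peak assignment

`assignHplcPeaks()` detects strict local maxima rising more than five
baseline median-absolute-deviations above the baseline median (baseline =
first two minutes of the trace; no noise model is available for these
detectors, so a robust data-derived threshold is used). Peaks are matched
to the reference retention times 16.0 (SH), 19.5 (MDSH) and 25.0 min
(DDSH) within a 1.0 min tolerance — a design choice reflecting typical
run-to-run drift, configurable per call — and integrated by the
trapezoidal rule between flanking minima. `fractionsFromChromatogram()`
converts assigned areas into concentrations that sum exactly to a stated
total, producing kinetic-model inputs from chromatographic data.

# Synthetic data

The generators emulate the statistical structure the analyses assume:

- `genTimeCourse()` — model trajectories for the standard assay (23 µM
  sirohaem, 2.3 µM enzyme, 16 points over 0–120 min, geometrically spaced
  after $t=0$ to resolve the early transient of the intermediate), with
  replicate structure (default 3) and multiplicative Gaussian noise
  (default 5% CV, a typical HPLC-MS quantification spread);
- `genTitration()` — Nernst curves over −300…+100 mV in 10 mV steps with
  additive absorbance noise;
- `genHaemochromePair()` — a flat-baseline oxidized spectrum and a reduced
  spectrum with Gaussian α and β bands (band width given as the Gaussian
  standard deviation, default 6 nm) on a 520–620 nm grid;
- `genChromatogram()` — sums of Gaussian peaks at the reference retention
  times with areas proportional to requested species fractions.

Every generator is a pure function of its arguments including the noise
seed, and each noiseless generator inverts exactly through its analysis
stage (simulate ↔ fit, Nernst ↔ `fitNernst`, Gaussian band ↔ peak finder,
fractions ↔ area fractions). What the generators do *not* emulate:
instrument drift and baseline curvature, chromatographic tailing,
wavelength-dependent noise, partial oxidation during sampling, and any
coupling between the haem redox state and catalytic rate. Passing tests
therefore validate the computational pipeline, not the field behaviour of
any particular instrument.

# Problem sizes used by the test-suite

Unit and property tests run at the sizes above; the Monte-Carlo recovery
studies use 100 repetitions for the kinetics (3 replicates each) and 100
seeds for the titration; bootstrap checks use 20 resamples at 1% noise.
These sizes give stable medians and keep the default test run fast.

# Known limitations

- Practical identifiability of the five kinetic constants from a
  single-total progress curve is poor (see above); multi-concentration
  designs are recommended.
- The "monodecarboxysirohaem" pool is treated as one kinetic species; the
  order of loss of the C12 and C18 acetates is not modelled.
- No mechanistic model of the decarboxylation chemistry, no
  rate–potential coupling, no mediator/electrode model for the titration,
  no multi-couple deconvolution, and no extinction-coefficient
  quantification of haem from haemochrome amplitudes.
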