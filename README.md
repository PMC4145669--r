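# sirodecarb

Kinetic, redox and spectroscopic analysis of sirohaem decarboxylase
(AhbA/B) assay data.

Sirohaem decarboxylase removes the two acetate side-chain carboxyls of
sirohaem — via monodecarboxysirohaem to didecarboxysirohaem — as the first
committed step of the alternative haem biosynthesis pathway used by
sulphate-reducing bacteria and archaea. Characterizing the enzyme raises
three recurring data-analysis problems, all covered here:

- **Progress-curve kinetics.** The three tetrapyrroles have practically
  identical UV-Vis spectra, so assays are stopped anaerobically and
  quantified chromatographically; the resulting full time courses are
  fitted as whole curves. The model is a single-active-site two-step
  cascade with competitive substrate inhibition and tight-binding product
  inhibition:

  v1 = Vmax1 (E/Eref) S1 / (Km1 (1 + S2/Km2 + S3f/Ki) + S1)
  v2 = Vmax2 (E/Eref) S2 / (Km2 (1 + S1/Km1 + S3f/Ki) + S2)

  with dS1/dt = −v1, dS2/dt = v1 − v2, dS3/dt = v2, and S3f the *free*
  product concentration from the Morrison binding quadratic (Ki is
  comparable to the enzyme concentration, so enzyme-bound product must
  not be counted as free inhibitor). All five constants are estimated
  simultaneously by Levenberg–Marquardt least squares in log-parameter
  space, with multistart, linearized and bootstrap standard errors, and
  explicit convergence/identifiability diagnostics.

- **Redox titrations.** Absorbance of the enzyme-bound haem Q-band versus
  applied potential is fitted to the one-electron Nernst sigmoid
  A(E) = Aox + (Ared − Aox) / (1 + exp(nF/RT (E − Em))) to estimate the
  midpoint potential Em (mV vs NHE).

- **Haem typing and HPLC assignment.** Reduced-minus-oxidized pyridine
  haemochrome difference spectra are computed on matched wavelength
  grids, the α-band apex located by parabolic interpolation
  (b-type ≈ 556 nm, c-type ≈ 550 nm, intermediate between), and HPLC
  chromatogram peaks are assigned to sirohaem (~16 min),
  monodecarboxysirohaem (~19.5 min) and didecarboxysirohaem (~25 min) by
  retention time.

Synthetic-data generators emulate each assay (replicated noisy time
courses, sigmoidal titrations, Gaussian band spectra, Gaussian
chromatogram peaks), so the full pipeline is testable end to end without
experimental data.

## Worked example

```r
library(sirodecarb)

truth <- ddAhbABParams()      # published constants for D. desulfuricans AhbA/B
tc <- simulateTimeCourse(truth, c(23, 0, 0))   # standard 23 uM assay
head(round(as.data.frame(tc), 3), 4)
#>   time_min  S1_uM S2_uM S3_uM
#> 1    0.000 23.000 0.000 0.000
#> 2    0.500 12.752 7.796 2.452
#> 3    0.740 10.136 8.731 4.133
#> 4    1.094  7.628 9.006 6.366

set.seed(1)                   # refit from a +/-50% perturbed guess
g <- paramVector(truth) * runif(5, 0.5, 1.5)
fitTimeCourse(tc, RateParameters(g[1], g[2], g[3], g[4], g[5]), seed = 1)
#> KineticFit: converged (48 observations, RSS = 3.54479e-21 uM^2)
#>   Km1    =      11.74 +/- 3.944e-09
#>   Vmax1  =      44.63 +/- 4.869e-09
#>   Km2    =       9.94 +/- 4.078e-09
#>   Vmax2  =      33.22 +/- 6.098e-09
#>   Ki     =       1.77 +/- 4.34e-10
```

The sirohaem trace falls monotonically, the intermediate passes through a
single maximum near 1 min, the product rises to the conserved 23 µM total,
and the refit recovers the generating constants exactly (noiseless data,
hence the vanishing standard errors).

```r
em <- fitNernst(genTitration(Em = -98, Aox = 0.12, Ared = 0.31,
                             noise = noiseModel("additive_gaussian", 0.004,
                                                seed = 3)))
em
#> NernstFit (n = 1, T = 298.15 K): Em = -99.28 mV vs NHE +/- 1.20
#>   Aox = 0.1215 AU, Ared = 0.3094 AU

pair <- genHaemochromePair(556)                  # synthetic b-type haemochrome
apex <- findAlphaPeak(differenceSpectrum(pair$reduced, pair$oxidized))
classifyHaem(round(as.numeric(apex), 2))
#> [1] "haem_b"
```

A thin command-line wrapper over the same stages ships at
`inst/cli/sirodecarb.R` (subcommands `simulate`, `fit`, `titrate`,
`haemochrome`, `hplc-assign`, `synth`).

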