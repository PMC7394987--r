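# bbbleak

Quantifying subtle blood–brain barrier (BBB) leakage from dual temporal
resolution dynamic contrast-enhanced (DCE) MRI.

In healthy and normally aging brains the BBB leaks contrast agent at rates
of only 10⁻⁷–10⁻⁶ min⁻¹ — far below the single-voxel noise floor of DCE
MRI. This package implements the full analysis chain that makes such rates
measurable, for imaging scientists who want a tested, reproducible
reference implementation:

- **Signal → concentration**: saturation-recovery signal model
  (S = S₀(1 − e^(−TD·R₁))) inverted against a pre-contrast T1 (T10) map,
  with the linear relaxivity relationship C = (R₁ − R₁₀)/r₁; blood signal
  converted through a monotone in-vitro calibration curve and hematocrit.
- **Vascular input function**: extracted from ≥ 20 superior sagittal sinus
  voxels of each dynamic sequence, merged across the fast (3.2 s × 29
  volumes) and slow (30.5 s × 30 volumes) sequences.
- **Patlak model**: voxel-wise linear least squares of
  Ct(t) = Kᵢ·∫₀ᵗ Cp dτ + vp·Cp(t), giving leakage-rate (Kᵢ, min⁻¹) and
  plasma-volume (vp) maps. Negative Kᵢ values are retained by design.
- **Histogram noise correction**: per-ROI mirror subtraction —
  corrected(b) = max(0, raw(b) − raw(mirror(b))) — and whole-ROI corrected
  mean leakage rates for white matter, gray matter, and primary /
  secondary / tertiary cortical regions.
- **Cohort statistics**: signed cube-root transform, standardized multiple
  regression of regional leakage on age and sex (β = b·SD(x)/SD(y)), with
  confounder models and brain-integrity interaction models with the
  non-significant-interaction pruning rule.
- **Synthetic module**: a phantom subject generator (box-region digital
  phantom, dual-time acquisition, Rician noise) and a cohort generator
  with programmed standardized age effects, so every stage is testable by
  parameter recovery without any acquired data.

## Worked example

Simulate a noiseless phantom subject, run the pipeline stages, and compare
against the known ground truth:

```r
library(bbbleak)

sub <- simulateSubject(phantomSpec(noiseSd = 0))
fastVif <- extractVif(sub$fast, sub$sinusMask, sub$calibration)
slowVif <- extractVif(sub$slow, sub$sinusMask, sub$calibration)
vif  <- mergeVif(fastVif, slowVif)
vif
#> VascularInputFunction: 57 points, t = 0.0..943.6 s, peak Cp 5.86 mM (96 voxels)

conc <- tissueConcentration(sub$fast, sub$slow, sub$t10, sub$brainMask)
map  <- fitPatlakMap(conc, vif, sub$brainMask)
#> fitted 8736 voxels (0 flagged) over 50 usable time points

summarizeRois(map, sub$masks)[, c("roi", "mean_ki", "median", "bin_width")]
#>            roi      mean_ki   median    bin_width
#> 1 white_matter 1.111500e-06 1.14e-06 5.700000e-08
#> 2  gray_matter 6.740697e-07 6.80e-07 6.270416e-08
#> 3      primary 4.290000e-07 4.40e-07 2.200000e-08
#> 4    secondary 3.315000e-07 3.40e-07 1.700000e-08
#> 5     tertiary 8.970000e-07 9.20e-07 4.600000e-08
```

The raw medians reproduce the phantom's programmed regional leakage rates
exactly (white matter 11.4 × 10⁻⁷ min⁻¹, tertiary 9.2 × 10⁻⁷, ...), and
each noise-corrected mean sits within one histogram bin width of the
regional ground truth — the half-bin discretization is the only error
left at zero noise (voxel-wise Kᵢ recovery is at machine-precision level;
the test suite asserts < 10⁻⁹ min⁻¹).

Cohort-level: simulate a 57-subject cohort with programmed standardized
age effects and refit the age model:

```r
tab <- simulateCohort(cohortSpec(seed = 1L))
fitAgeModel(tab, "white_matter")
#> RegressionResult for ROI 'white_matter' (n = 57, 0 dropped)
#>  term         b   beta      p
#>   age  0.000119  0.266 0.0455
#>   sex -0.001497 -0.194 0.1425
```

One 57-subject draw from a world with a true standardized age effect of
0.306 here yields an estimate of 0.266, significant at p < .05 — with the
sampling spread one expects at this n (see the methods vignette,
`vignettes/bbb-leakage-mapping.Rmd`, for the power analysis).

`runPipeline()` chains all stages and writes NIfTI maps, CSV summaries,
regression tables, the resolved configuration and a run manifest; a thin
command-line wrapper lives at `inst/cli/bbbleak.R`
(`Rscript bbbleak.R simulate|cohort|run|stats --config conf.json --seed N
--out DIR`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end against the installed package at the
given seed — simulating the default phantom subject, converting signal to
concentration, fitting the voxel-wise Patlak model, summarizing the
noise-corrected regional leakage rates, simulating the default 57-subject
cohort and fitting the standardized age regressions — printing the
regional summary and regression table, and writing the JSON report to
`--out`.
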