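#' Construct an acquisition protocol
#'
#' Defaults reproduce the dual-time protocol the simulator emulates: a fast
#' sequence with a 3.2 s dynamic scan interval and 29 volumes, a slow
#' sequence with a 30.5 s interval and 30 volumes, TR/TE/TD = 5.3/2.5/120 ms.
#' The flip angle is metadata only: the adopted signal model is pure
#' saturation recovery, \eqn{S = S_0 (1 - e^{-TD \cdot R_1})}.
#'
#' @param trMs,teMs,tdMs repetition/echo/saturation-delay times (ms).
#' @param flipDeg flip angle (degrees, metadata).
#' @param fastIntervalS,nFast fast-sequence interval (s) and volume count.
#' @param slowIntervalS,nSlow slow-sequence interval (s) and volume count.
#' @param nPrecontrastFast,nPrecontrastSlow pre-contrast volume counts.
#' @param r1Relaxivity contrast-agent longitudinal relaxivity
#'   (L mmol^-1 s^-1); default 5.0, typical for gadobutrol at 3 T.
#' @return An [AcquisitionProtocol-class] object.
#' @examples
#' p <- acquisitionProtocol()
#' protocolTimes(p)$fast[1:4]
#' @export
acquisitionProtocol <- function(trMs = 5.3, teMs = 2.5, tdMs = 120,
                                flipDeg = 30,
                                fastIntervalS = 3.2, nFast = 29L,
                                slowIntervalS = 30.5, nSlow = 30L,
                                nPrecontrastFast = 5L, nPrecontrastSlow = 2L,
                                r1Relaxivity = 5.0) {
  new("AcquisitionProtocol", trMs = trMs, teMs = teMs, tdMs = tdMs,
      flipDeg = flipDeg, fastIntervalS = fastIntervalS,
      nFast = as.integer(nFast), slowIntervalS = slowIntervalS,
      nSlow = as.integer(nSlow),
      nPrecontrastFast = as.integer(nPrecontrastFast),
      nPrecontrastSlow = as.integer(nPrecontrastSlow),
      r1Relaxivity = r1Relaxivity)
}

#' Acquisition time stamps of both sequences
#'
#' The fast sequence starts the common clock at t = 0. The slow sequence
#' contributes its pre-contrast volumes before the fast block (negative
#' times) and resumes after the fast block ends, one interval apart --
#' mirroring an acquisition in which both sequences are sampled before
#' injection and the slow sequence covers the leakage phase.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @return list with numeric vectors `fast` and `slow` (seconds).
#' @export
protocolTimes <- function(protocol) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  fast <- (seq_len(protocol@nFast) - 1L) * protocol@fastIntervalS
  nPost <- protocol@nSlow - protocol@nPrecontrastSlow
  slow <- c(-rev(seq_len(protocol@nPrecontrastSlow)) * protocol@slowIntervalS,
            max(fast) + seq_len(nPost) * protocol@slowIntervalS)
  list(fast = fast, slow = slow)
}

## Table-level defaults for the five tissue regions (min^-1): population
## medians and quartiles of the leakage rate used by the generators.
.defaultKiMedian <- c(white_matter = 11.4e-7, gray_matter = 9.5e-7,
                      primary = 4.4e-7, secondary = 3.4e-7,
                      tertiary = 9.2e-7)
.defaultKiP25 <- c(white_matter = 5.1e-7, gray_matter = 3.9e-7,
                   primary = 1.0e-7, secondary = 0.4e-7, tertiary = 1.1e-7)
.defaultKiP75 <- c(white_matter = 20.4e-7, gray_matter = 17.3e-7,
                   primary = 10.8e-7, secondary = 7.1e-7, tertiary = 25.1e-7)
.defaultAgeBeta <- c(white_matter = 0.306, gray_matter = 0.286,
                     primary = 0.145, secondary = 0.098, tertiary = 0.307)

#' Construct a phantom specification
#'
#' Ground-truth leakage rates default to the population medians of the five
#' regions (white matter 11.4e-7 min^-1, gray matter 9.5e-7, primary 4.4e-7,
#' secondary 3.4e-7, tertiary 9.2e-7). T10 defaults are literature-typical
#' 3 T values (white matter 1100 ms, cortex 1800 ms, blood 1650 ms). The
#' default grid (32 x 32 x 16) keeps every region above 500 voxels while
#' staying seconds-scale to simulate and fit.
#'
#' @param dim grid size (3 integers).
#' @param voxelSizeMm voxel size (mm).
#' @param ki,vp,t10Ms named per-region ground truth (regions
#'   `white_matter, gray_matter, primary, secondary, tertiary`).
#' @param bloodT10Ms sinus blood T1 (ms).
#' @param noiseSd noise SD relative to baseline signal (default 0.02,
#'   i.e. baseline SNR 50).
#' @param noiseModel `"rician"` (default) or `"gaussian"`.
#' @param aifPeakMm peak plasma concentration (mM). The injected dose fixes
#'   the total agent, not the peak; 6 mM is a typical first-pass plasma peak
#'   for 0.1 mmol/kg.
#' @param bolusArrivalS bolus arrival (s); default 20 s, after the fast
#'   pre-contrast volumes, so the peak falls inside the fast window.
#' @param aifRiseS arrival-to-peak time (s).
#' @param aifDecayRates biexponential washout rates (s^-1).
#' @param hct hematocrit for the blood/plasma conversion (default 0.45).
#' @param seed random seed.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(dim = c(32L, 32L, 16L), voxelSizeMm = c(2, 2, 2),
                        ki = .defaultKiMedian,
                        vp = c(white_matter = 0.008, gray_matter = 0.02,
                               primary = 0.02, secondary = 0.02,
                               tertiary = 0.02),
                        t10Ms = c(white_matter = 1100, gray_matter = 1800,
                                  primary = 1800, secondary = 1800,
                                  tertiary = 1800),
                        bloodT10Ms = 1650,
                        noiseSd = 0.02, noiseModel = "rician",
                        aifPeakMm = 6, bolusArrivalS = 20, aifRiseS = 8,
                        aifDecayRates = c(0.05, 8e-4), hct = 0.45,
                        seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), voxelSizeMm = voxelSizeMm,
      ki = ki, vp = vp, t10Ms = t10Ms, bloodT10Ms = bloodT10Ms,
      noiseSd = noiseSd, noiseModel = noiseModel, aifPeakMm = aifPeakMm,
      bolusArrivalS = bolusArrivalS, aifRiseS = aifRiseS,
      aifDecayRates = aifDecayRates, hct = hct, seed = as.integer(seed))
}

#' Construct a cohort specification
#'
#' Defaults state the cohort the generator emulates: n = 57 subjects, age
#' normal (65.8, SD 10.2) truncated to 47--91 years, 52.6% male, systolic
#' blood pressure 141.3 (17.2) mmHg, BMI 27.7 (4.5), 17.5% diabetes, 14%
#' smokers. Leakage rates per region are cube-root-normal anchored at the
#' published medians/quartiles, with a programmed standardized age effect
#' per region (white matter 0.306, gray matter 0.286, primary 0.145,
#' secondary 0.098, tertiary 0.307).
#'
#' @param nSubjects sample size (default 57).
#' @param ageMean,ageSd,ageRange age distribution.
#' @param pMale probability of male sex.
#' @param ageBeta named standardized age effect per region, each in (-1, 1).
#' @param kiMedian,kiP25,kiP75 named leakage quantiles (min^-1).
#' @param noiseScale residual SD multiplier (1 = unit total variance).
#' @param mediator,mediatorBeta,interactionBeta optional mediation /
#'   interaction structure, see [CohortSpec-class].
#' @param covAgeLoading correlations of the standardized integrity measures
#'   with age (defaults: WMH +0.5, cortical thickness -0.5, hippocampal
#'   volume -0.3).
#' @param sbpMean,sbpSd,bmiMean,bmiSd,pDiabetes,pSmoker covariate parameters.
#' @param wmhMeanlog,wmhSdlog,ctMean,ctSd,hcMean,hcSd integrity-measure
#'   location/scale (WMH cm^3 log-normal; cortical thickness mm;
#'   hippocampal volume cm^3).
#' @param seed random seed.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nSubjects = 57L,
                       ageMean = 65.8, ageSd = 10.2, ageRange = c(47, 91),
                       pMale = 0.526,
                       ageBeta = .defaultAgeBeta,
                       kiMedian = .defaultKiMedian,
                       kiP25 = .defaultKiP25, kiP75 = .defaultKiP75,
                       noiseScale = 1,
                       mediator = NA_character_, mediatorBeta = 0,
                       interactionBeta = 0,
                       covAgeLoading = c(wmhVolume = 0.5,
                                         corticalThickness = -0.5,
                                         hippocampalVolume = -0.3),
                       sbpMean = 141.3, sbpSd = 17.2,
                       bmiMean = 27.7, bmiSd = 4.5,
                       pDiabetes = 0.175, pSmoker = 0.14,
                       wmhMeanlog = log(2.5), wmhSdlog = 1.0,
                       ctMean = 2.45, ctSd = 0.12,
                       hcMean = 6.5, hcSd = 0.7,
                       seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects), ageMean = ageMean,
      ageSd = ageSd, ageRange = ageRange, pMale = pMale, ageBeta = ageBeta,
      kiMedian = kiMedian, kiP25 = kiP25, kiP75 = kiP75,
      noiseScale = noiseScale, mediator = mediator,
      mediatorBeta = mediatorBeta, interactionBeta = interactionBeta,
      covAgeLoading = covAgeLoading, sbpMean = sbpMean, sbpSd = sbpSd,
      bmiMean = bmiMean, bmiSd = bmiSd, pDiabetes = pDiabetes,
      pSmoker = pSmoker, wmhMeanlog = wmhMeanlog, wmhSdlog = wmhSdlog,
      ctMean = ctMean, ctSd = ctSd, hcMean = hcMean, hcSd = hcSd,
      seed = as.integer(seed))
}

#' Construct a dynamic series
#' @param data 4D numeric array (x, y, z, t).
#' @param times time stamps (s), strictly increasing.
#' @param role `"fast"` or `"slow"`.
#' @param nPrecontrast number of pre-contrast volumes.
#' @return A [DynamicSeries-class].
#' @export
dynamicSeries <- function(data, times, role, nPrecontrast) {
  new("DynamicSeries", data = data, times = as.numeric(times), role = role,
      nPrecontrast = as.integer(nPrecontrast))
}

#' Construct a vascular input function
#' @param times time stamps (s).
#' @param cp plasma concentration (mM).
#' @param nVoxels contributing sinus voxel count.
#' @return A [VascularInputFunction-class].
#' @export
vascularInputFunction <- function(times, cp, nVoxels) {
  new("VascularInputFunction", times = as.numeric(times),
      cp = as.numeric(cp), nVoxels = as.integer(nVoxels))
}

#' Construct an ROI mask set
#'
#' @param masks named list of logical 3D arrays (`white_matter`,
#'   `gray_matter`, `primary`, `secondary`, `tertiary`), or a 3D integer
#'   label array as produced by [phantomLabels()].
#' @return An [ROIMaskSet-class].
#' @export
roiMaskSet <- function(masks) {
  if (is.array(masks) && !is.list(masks)) {
    lab <- masks
    masks <- list(
      white_matter = lab == 2L,
      gray_matter = lab %in% c(3L, 4L, 5L, 6L),
      primary = lab == 4L, secondary = lab == 5L, tertiary = lab == 6L)
    masks <- lapply(masks, function(m) array(m, dim = dim(lab)))
  }
  new("ROIMaskSet", masks = masks)
}

#' @describeIn roiMaskSet Access one region mask.
#' @param x an `ROIMaskSet`.
#' @param roi region name.
#' @export
roiMask <- function(x, roi) {
  stopifnot(is(x, "ROIMaskSet"))
  if (!roi %in% names(x@masks)) stop("unknown ROI: ", roi)
  x@masks[[roi]]
}

#' @describeIn roiMaskSet Region names in the set.
#' @export
roiNames <- function(x) names(x@masks)

## ---- accessors ------------------------------------------------------------

#' Accessors for leakage maps and series
#'
#' `kiMap`, `vpMap`, `residSdMap`, `flaggedMap` return the component 3D
#' arrays of a [LeakageMap-class]; `seriesTimes` and `seriesData` the time
#' stamps and array of a dynamic or concentration series; `vifTimes` /
#' `vifCp` the samples of a [VascularInputFunction-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
kiMap <- function(x) { stopifnot(is(x, "LeakageMap")); x@ki }

#' @rdname accessors
#' @export
vpMap <- function(x) { stopifnot(is(x, "LeakageMap")); x@vp }

#' @rdname accessors
#' @export
residSdMap <- function(x) { stopifnot(is(x, "LeakageMap")); x@residSd }

#' @rdname accessors
#' @export
flaggedMap <- function(x) { stopifnot(is(x, "LeakageMap")); x@flagged }

#' @rdname accessors
#' @export
seriesTimes <- function(x) {
  stopifnot(is(x, "DynamicSeries") || is(x, "ConcentrationSeries"))
  x@times
}

#' @rdname accessors
#' @export
seriesData <- function(x) {
  stopifnot(is(x, "DynamicSeries") || is(x, "ConcentrationSeries"))
  x@data
}

#' @rdname accessors
#' @export
vifTimes <- function(x) { stopifnot(is(x, "VascularInputFunction")); x@times }

#' @rdname accessors
#' @export
vifCp <- function(x) { stopifnot(is(x, "VascularInputFunction")); x@cp }

#' Histogram accessors
#'
#' Bin edges, centers, raw and corrected counts, and the whole-ROI
#' denominator of a [KiHistogram-class].
#' @param x a `KiHistogram`.
#' @name histogram-accessors
NULL

#' @rdname histogram-accessors
#' @export
histEdges <- function(x) { stopifnot(is(x, "KiHistogram")); x@edges }

#' @rdname histogram-accessors
#' @export
histCenters <- function(x) {
  stopifnot(is(x, "KiHistogram"))
  e <- x@edges
  (e[-1L] + e[-length(e)]) / 2
}

#' @rdname histogram-accessors
#' @export
histCounts <- function(x) { stopifnot(is(x, "KiHistogram")); x@counts }

#' @rdname histogram-accessors
#' @export
histCorrected <- function(x) { stopifnot(is(x, "KiHistogram")); x@corrected }

#' @rdname histogram-accessors
#' @export
histTotal <- function(x) { stopifnot(is(x, "KiHistogram")); x@nTotal }

#' Regression result accessors
#'
#' `resultCoefficients` returns the tidy coefficient table (term, b, beta,
#' p); `resultStages` the per-stage tables of an interaction model;
#' `interactionPruned` whether the interaction term was removed.
#' @param x a [RegressionResult-class].
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
resultCoefficients <- function(x) {
  stopifnot(is(x, "RegressionResult")); x@coefficients
}

#' @rdname result-accessors
#' @export
resultStages <- function(x) { stopifnot(is(x, "RegressionResult")); x@stages }

#' @rdname result-accessors
#' @export
interactionPruned <- function(x) {
  stopifnot(is(x, "RegressionResult")); x@interactionPruned
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol: dual-time DCE\n")
  cat(sprintf("  fast: %g s x %d volumes (%d pre-contrast)\n",
              object@fastIntervalS, object@nFast, object@nPrecontrastFast))
  cat(sprintf("  slow: %g s x %d volumes (%d pre-contrast)\n",
              object@slowIntervalS, object@nSlow, object@nPrecontrastSlow))
  cat(sprintf("  TR/TE/TD: %g/%g/%g ms, flip %g deg, r1 %g L/mmol/s\n",
              object@trMs, object@teMs, object@tdMs, object@flipDeg,
              object@r1Relaxivity))
})

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DynamicSeries (%s): %d x %d x %d voxels, %d volumes, t = %.1f..%.1f s\n",
    object@role, d[1L], d[2L], d[3L], d[4L], min(object@times),
    max(object@times)))
})

setMethod("show", "ConcentrationSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ConcentrationSeries: %d x %d x %d voxels, %d time points (%d fast, %d slow)\n",
    d[1L], d[2L], d[3L], d[4L], sum(object@provenance == "fast"),
    sum(object@provenance == "slow")))
})

setMethod("show", "VascularInputFunction", function(object) {
  cat(sprintf(
    "VascularInputFunction: %d points, t = %.1f..%.1f s, peak Cp %.3g mM (%d voxels)\n",
    length(object@times), min(object@times), max(object@times),
    max(object@cp), object@nVoxels))
})

setMethod("show", "LeakageMap", function(object) {
  d <- dim(object@ki)
  ok <- !object@flagged
  cat(sprintf("LeakageMap: %d x %d x %d grid, %d fitted voxels (%d flagged)\n",
              d[1L], d[2L], d[3L], sum(ok), sum(object@flagged)))
  if (any(ok))
    cat(sprintf("  Ki median %.3g min^-1, vp median %.3g\n",
                median(object@ki[ok]), median(object@vp[ok])))
})

setMethod("show", "KiHistogram", function(object) {
  cat(sprintf("KiHistogram: %d bins, width %.3g min^-1, %d voxels (%d flagged)%s\n",
              length(object@counts), diff(object@edges[1:2]), object@nTotal,
              object@nFlagged,
              if (length(object@corrected)) ", noise-corrected" else ""))
})

setMethod("show", "ROIMaskSet", function(object) {
  cat("ROIMaskSet:\n")
  for (nm in names(object@masks))
    cat(sprintf("  %-13s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult for ROI '%s' (n = %d, %d dropped)\n",
              object@roi, object@n, object@nDropped))
  if (!is.na(object@interactionPruned))
    cat(sprintf("  interaction term %s\n",
                if (object@interactionPruned) "pruned (p >= .05)"
                else "retained"))
  print(object@coefficients, row.names = FALSE, digits = 3)
})
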