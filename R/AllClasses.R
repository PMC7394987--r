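## Central S4 containers. All times are stored in seconds, Ki in min^-1,
## concentrations in mM, T1/TD in ms unless a slot name says otherwise.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Acquisition protocol for dual-time DCE-MRI
#'
#' Parameters of the dual temporal resolution dynamic acquisition: a fast
#' sequence (short dynamic scan interval, samples the bolus) and a slow
#' sequence (long interval, samples the leakage phase), both saturation-
#' recovery prepared. Defaults reproduce the protocol the simulator emulates:
#' fast 3.2 s x 29 volumes, slow 30.5 s x 30 volumes, TR/TE/TD 5.3/2.5/120 ms.
#'
#' @slot trMs,teMs,tdMs repetition, echo and saturation-delay time (ms). Only
#'   `tdMs` enters the signal model; TR/TE/flip are carried as metadata.
#' @slot flipDeg excitation flip angle (degrees), metadata only.
#' @slot fastIntervalS,nFast dynamic scan interval (s) and volume count of the
#'   fast sequence.
#' @slot slowIntervalS,nSlow interval (s) and volume count of the slow
#'   sequence.
#' @slot nPrecontrastFast,nPrecontrastSlow pre-contrast volume counts.
#' @slot r1Relaxivity longitudinal relaxivity of the contrast agent
#'   (L mmol^-1 s^-1).
#' @seealso [acquisitionProtocol()]
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(
    trMs = "numeric", teMs = "numeric", tdMs = "numeric", flipDeg = "numeric",
    fastIntervalS = "numeric", nFast = "integer",
    slowIntervalS = "numeric", nSlow = "integer",
    nPrecontrastFast = "integer", nPrecontrastSlow = "integer",
    r1Relaxivity = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  pos <- c(trMs = object@trMs, teMs = object@teMs, tdMs = object@tdMs,
           fastIntervalS = object@fastIntervalS,
           slowIntervalS = object@slowIntervalS,
           r1Relaxivity = object@r1Relaxivity)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("slots must be strictly positive: ",
                         paste(bad, collapse = ", ")))
  if (object@nPrecontrastFast < 1L || object@nFast < object@nPrecontrastFast)
    msg <- c(msg, "need n_fast >= n_precontrast_fast >= 1")
  if (object@nPrecontrastSlow < 1L || object@nSlow < object@nPrecontrastSlow)
    msg <- c(msg, "need n_slow >= n_precontrast_slow >= 1")
  if (length(msg)) msg else TRUE
})

#' Phantom specification for the synthetic subject generator
#'
#' Describes a small 3D digital phantom with box-shaped regions (background,
#' sagittal sinus, white matter, and gray matter containing disjoint primary /
#' secondary / tertiary cortical boxes), the ground-truth kinetics per region,
#' the relaxation times, and the noise model.
#'
#' @slot dim integer grid size (3 values, voxels).
#' @slot voxelSizeMm voxel edge lengths (mm, 3 values), metadata for the
#'   NIfTI affine.
#' @slot ki named ground-truth leakage rate per tissue region (min^-1).
#' @slot vp named ground-truth plasma volume fraction per tissue region.
#' @slot t10Ms named pre-contrast T1 per tissue region (ms).
#' @slot bloodT10Ms pre-contrast T1 of sinus blood (ms).
#' @slot noiseSd noise standard deviation relative to the voxel baseline
#'   signal (0 = noiseless).
#' @slot noiseModel `"rician"` (magnitude MRI default) or `"gaussian"`.
#' @slot aifPeakMm peak plasma concentration of the input function (mM).
#' @slot bolusArrivalS bolus arrival time (s, on the fast-sequence clock).
#' @slot aifRiseS time from arrival to peak (s).
#' @slot aifDecayRates biexponential washout rates (s^-1, fast then slow).
#' @slot hct hematocrit used for the blood-to-plasma conversion.
#' @slot seed integer random seed.
#' @seealso [phantomSpec()], [simulateSubject()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    dim = "integer", voxelSizeMm = "numeric",
    ki = "numeric", vp = "numeric", t10Ms = "numeric",
    bloodT10Ms = "numeric",
    noiseSd = "numeric", noiseModel = "character",
    aifPeakMm = "numeric", bolusArrivalS = "numeric", aifRiseS = "numeric",
    aifDecayRates = "numeric", hct = "numeric",
    seed = "integer"
  )
)

.tissueRegions <- c("white_matter", "gray_matter", "primary", "secondary",
                    "tertiary")

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 8L))
    msg <- c(msg, "dim must be 3 integers >= 8")
  for (sl in c("ki", "vp", "t10Ms")) {
    v <- slot(object, sl)
    if (!all(.tissueRegions %in% names(v)))
      msg <- c(msg, paste0(sl, " must be named for all regions: ",
                           paste(.tissueRegions, collapse = ", ")))
  }
  if (any(object@vp < 0 | object@vp >= 1))
    msg <- c(msg, "vp must lie in [0, 1)")
  if (any(object@t10Ms <= 0) || object@bloodT10Ms <= 0)
    msg <- c(msg, "T10 values must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@noiseModel %in% c("rician", "gaussian"))
    msg <- c(msg, "noiseModel must be 'rician' or 'gaussian'")
  if (object@aifPeakMm <= 0) msg <- c(msg, "aifPeakMm must be > 0")
  if (any(object@aifDecayRates <= 0) || length(object@aifDecayRates) != 2L)
    msg <- c(msg, "aifDecayRates must be two positive rates")
  if (object@hct <= 0 || object@hct >= 1) msg <- c(msg, "hct must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Cohort specification for the synthetic cohort generator
#'
#' States the generative world of the phantom cohort: sample size, the age
#' distribution, the per-region leakage-rate distribution on the cube-root
#' scale (medians and quartiles set the location/scale), the programmed
#' standardized age effect per region, and the covariate generators with
#' their own age loadings.
#'
#' @slot nSubjects number of subjects (>= 3).
#' @slot ageMean,ageSd,ageRange age distribution: normal truncated to range.
#' @slot pMale probability of male sex.
#' @slot ageBeta named programmed standardized age effect per region, each in
#'   (-1, 1), on the cube-root Ki scale.
#' @slot kiMedian,kiP25,kiP75 named per-region leakage quantiles (min^-1)
#'   that anchor the cube-root-normal Ki distribution.
#' @slot noiseScale multiplier on the residual (non-age) Ki standard
#'   deviation; 1 keeps unit total variance on the standardized scale.
#' @slot mediator optional covariate name (`"wmhVolume"`,
#'   `"corticalThickness"`, `"hippocampalVolume"`) through which the age
#'   effect is routed; `NA` for a direct age effect.
#' @slot mediatorBeta loading of the mediator on (cube-root) Ki when
#'   `mediator` is set; the direct age path is then removed, so the marginal
#'   age effect is `mediatorBeta * ageLoading(mediator)`.
#' @slot interactionBeta coefficient of the centered age x mediator
#'   interaction on the standardized outcome scale (0 = none).
#' @slot covAgeLoading named correlations of the standardized integrity
#'   measures with standardized age (wmhVolume, corticalThickness,
#'   hippocampalVolume).
#' @slot sbpMean,sbpSd,bmiMean,bmiSd,pDiabetes,pSmoker covariate parameters.
#' @slot wmhMeanlog,wmhSdlog log-normal WMH volume (cm^3) parameters.
#' @slot ctMean,ctSd,hcMean,hcSd cortical thickness (mm) and hippocampal
#'   volume (cm^3) location/scale.
#' @slot seed integer random seed.
#' @seealso [cohortSpec()], [simulateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    ageMean = "numeric", ageSd = "numeric", ageRange = "numeric",
    pMale = "numeric",
    ageBeta = "numeric",
    kiMedian = "numeric", kiP25 = "numeric", kiP75 = "numeric",
    noiseScale = "numeric",
    mediator = "character", mediatorBeta = "numeric",
    interactionBeta = "numeric",
    covAgeLoading = "numeric",
    sbpMean = "numeric", sbpSd = "numeric",
    bmiMean = "numeric", bmiSd = "numeric",
    pDiabetes = "numeric", pSmoker = "numeric",
    wmhMeanlog = "numeric", wmhSdlog = "numeric",
    ctMean = "numeric", ctSd = "numeric",
    hcMean = "numeric", hcSd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 3L) msg <- c(msg, "nSubjects must be >= 3")
  if (any(abs(object@ageBeta) >= 1))
    msg <- c(msg, "programmed standardized age effects must lie in (-1, 1)")
  for (sl in c("ageBeta", "kiMedian", "kiP25", "kiP75")) {
    if (!all(.tissueRegions %in% names(slot(object, sl))))
      msg <- c(msg, paste0(sl, " must be named for all regions"))
  }
  if (diff(object@ageRange) <= 0) msg <- c(msg, "ageRange must be increasing")
  if (!is.na(object@mediator) &&
      !object@mediator %in% c("wmhVolume", "corticalThickness",
                              "hippocampalVolume"))
    msg <- c(msg, "mediator must be an integrity measure column or NA")
  if (length(msg)) msg else TRUE
})

#' 4D dynamic signal series
#'
#' One dynamic sequence: a 4D signal array (x, y, z, t) in arbitrary scanner
#' units, its time stamps (seconds, on the common subject clock), the
#' sequence role, and how many leading volumes were acquired pre-contrast.
#'
#' @slot data 4D numeric array.
#' @slot times volume time stamps (s), strictly increasing.
#' @slot role `"fast"` or `"slow"`.
#' @slot nPrecontrast number of pre-contrast volumes (>= 1).
#' @exportClass DynamicSeries
setClass("DynamicSeries",
  representation(data = "array", times = "numeric", role = "character",
                 nPrecontrast = "integer")
)

setValidity("DynamicSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, t)")
  else if (dim(object@data)[4L] != length(object@times))
    msg <- c(msg, "4th dimension must match length(times)")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "time stamps must be strictly increasing")
  if (!object@role %in% c("fast", "slow"))
    msg <- c(msg, "role must be 'fast' or 'slow'")
  if (object@nPrecontrast < 1L ||
      object@nPrecontrast >= length(object@times))
    msg <- c(msg, "nPrecontrast must be >= 1 and < number of volumes")
  if (length(msg)) msg else TRUE
})

#' In-vitro signal calibration curve for blood
#'
#' Paired samples of signal-enhancement ratio (relative to the zero-
#' concentration baseline) and blood gadolinium concentration, spanning the
#' in-vitro range and including the zero point. The curve must be strictly
#' monotone; it is evaluated through a monotone (Hyman) spline in both
#' directions.
#'
#' @slot concMm blood concentration samples (mM), starting at 0.
#' @slot ratio signal enhancement ratio at each concentration, starting at 1.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(concMm = "numeric", ratio = "numeric")
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@concMm) != length(object@ratio) ||
      length(object@concMm) < 3L)
    msg <- c(msg, "need >= 3 paired (concentration, ratio) samples")
  if (object@concMm[1L] != 0)
    msg <- c(msg, "curve must include the zero-concentration point first")
  if (any(diff(object@concMm) <= 0) || any(diff(object@ratio) <= 0))
    msg <- c(msg, "curve must be strictly monotone increasing")
  if (length(msg)) msg else TRUE
})

#' Vascular input function
#'
#' Plasma gadolinium concentration against time, measured from sinus voxels.
#'
#' @slot times time stamps (s).
#' @slot cp plasma concentration (mM).
#' @slot nVoxels number of contributing sinus voxels (>= 20 by convention).
#' @exportClass VascularInputFunction
setClass("VascularInputFunction",
  representation(times = "numeric", cp = "numeric", nVoxels = "integer")
)

setValidity("VascularInputFunction", function(object) {
  msg <- character()
  if (length(object@times) != length(object@cp))
    msg <- c(msg, "times and cp must have equal length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!all(is.finite(object@cp)))
    msg <- c(msg, "cp must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' 4D tissue concentration series
#'
#' Voxel-wise gadolinium concentration (mM) with merged time stamps and a
#' per-time-point provenance flag recording which sequence contributed the
#' sample. Negative concentrations are retained by contract: they encode
#' noise and are required downstream by the symmetric histogram noise
#' correction.
#'
#' @slot data 4D numeric array (mM); NA outside the brain mask.
#' @slot times time stamps (s), strictly increasing.
#' @slot provenance `"fast"`/`"slow"` per time point.
#' @exportClass ConcentrationSeries
setClass("ConcentrationSeries",
  representation(data = "array", times = "numeric", provenance = "character")
)

setValidity("ConcentrationSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array")
  else if (dim(object@data)[4L] != length(object@times))
    msg <- c(msg, "4th dimension must match length(times)")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "merged time stamps must be strictly increasing")
  if (length(object@provenance) != length(object@times) ||
      !all(object@provenance %in% c("fast", "slow")))
    msg <- c(msg, "provenance must flag each time point fast/slow")
  if (length(msg)) msg else TRUE
})

#' Patlak design (regressors shared by all voxels)
#'
#' Plasma concentration resampled to the tissue sampling times, its running
#' integral in mM.min, and the usable-time-point mask (post-bolus points).
#'
#' @slot times tissue sampling times (s).
#' @slot cp plasma concentration at those times (mM).
#' @slot cpIntegral running trapezoid integral of cp (mM.min).
#' @slot usable logical mask of time points entering the fit.
#' @slot bolusArrivalS detected bolus arrival time (s).
#' @exportClass PatlakDesign
setClass("PatlakDesign",
  representation(times = "numeric", cp = "numeric", cpIntegral = "numeric",
                 usable = "logical", bolusArrivalS = "numeric")
)

setValidity("PatlakDesign", function(object) {
  n <- length(object@times)
  msg <- character()
  if (length(object@cp) != n || length(object@cpIntegral) != n ||
      length(object@usable) != n)
    msg <- c(msg, "cp, cpIntegral and usable must match times in length")
  if (all(object@cp >= 0) && any(diff(object@cpIntegral) < -1e-12))
    msg <- c(msg, "integral must be non-decreasing for non-negative cp")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise leakage map
#'
#' The fitted Patlak parameters per voxel: leakage rate Ki (min^-1, negative
#' values permitted and meaningful as noise), plasma volume fraction vp,
#' residual standard deviation, and a flag map of unfittable voxels (outside
#' the mask, non-finite input, or rank-deficient design).
#'
#' @slot ki,vp,residSd 3D numeric arrays; NA where flagged/outside mask.
#' @slot flagged 3D logical array: voxels excluded from downstream summaries.
#' @slot df residual degrees of freedom of the per-voxel fit.
#' @exportClass LeakageMap
setClass("LeakageMap",
  representation(ki = "array", vp = "array", residSd = "array",
                 flagged = "array", df = "integer")
)

setValidity("LeakageMap", function(object) {
  msg <- character()
  d <- dim(object@ki)
  if (length(d) != 3L) msg <- c(msg, "ki must be a 3D array")
  for (sl in c("vp", "residSd", "flagged"))
    if (!identical(dim(slot(object, sl)), d))
      msg <- c(msg, paste0(sl, " must share the grid of ki"))
  ok <- !object@flagged & !is.na(object@flagged)
  if (any(!is.finite(object@ki[ok])))
    msg <- c(msg, "ki must be finite in unflagged voxels")
  if (length(msg)) msg else TRUE
})

#' Ki histogram with mirror-subtraction noise correction
#'
#' Histogram of voxel-wise Ki over one region of interest, with uniform bins
#' symmetric about zero: for every positive bin (a, b] there is a mirror bin
#' (-b, -a]. The corrected counts (once [noiseCorrect()] has run) estimate
#' the leaking-voxel content of each positive bin.
#'
#' @slot edges bin edges (min^-1), uniform and symmetric about zero.
#' @slot counts raw counts per bin.
#' @slot corrected corrected counts per bin (length 0 before correction).
#' @slot nTotal total ROI voxel count entering the histogram (the
#'   whole-ROI denominator for the corrected mean).
#' @slot nFlagged voxels excluded because they were flagged in the map.
#' @exportClass KiHistogram
setClass("KiHistogram",
  representation(edges = "numeric", counts = "numeric",
                 corrected = "numeric", nTotal = "integer",
                 nFlagged = "integer")
)

setValidity("KiHistogram", function(object) {
  msg <- character()
  e <- object@edges
  if (length(e) < 3L) msg <- c(msg, "need at least 2 bins")
  w <- diff(e)
  if (any(abs(w - w[1L]) > 1e-9 * abs(w[1L])))
    msg <- c(msg, "bin width must be uniform")
  if (max(abs(e + rev(e))) > 1e-9 * max(abs(e)))
    msg <- c(msg, "edges must be symmetric about zero")
  if (length(object@counts) != length(e) - 1L)
    msg <- c(msg, "counts must have one entry per bin")
  if (length(object@corrected) &&
      length(object@corrected) != length(object@counts))
    msg <- c(msg, "corrected must match counts in length")
  if (length(object@corrected) && any(object@corrected < 0))
    msg <- c(msg, "corrected counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ROI mask set
#'
#' Binary masks for the five regions the leakage summaries use: total white
#' matter, total gray matter, and the primary (pre/postcentral), secondary
#' (supramarginal/superior temporal) and tertiary (orbitofrontal/cingulate)
#' cortical classes. The cortical classes must be pairwise disjoint subsets
#' of gray matter.
#'
#' @slot masks named list of 3D logical arrays, names
#'   `white_matter, gray_matter, primary, secondary, tertiary`.
#' @exportClass ROIMaskSet
setClass("ROIMaskSet", representation(masks = "list"))

setValidity("ROIMaskSet", function(object) {
  msg <- character()
  m <- object@masks
  if (!all(.tissueRegions %in% names(m)))
    return(paste0("masks must be named: ",
                  paste(.tissueRegions, collapse = ", ")))
  d <- dim(m[[1L]])
  for (nm in .tissueRegions) {
    if (!is.logical(m[[nm]]) || !identical(dim(m[[nm]]), d))
      msg <- c(msg, paste0(nm, " must be a logical array on the common grid"))
    else if (!any(m[[nm]]))
      msg <- c(msg, paste0(nm, " must be non-empty"))
  }
  if (!length(msg)) {
    cls <- c("primary", "secondary", "tertiary")
    for (i in seq_along(cls)) {
      if (any(m[[cls[i]]] & !m[["gray_matter"]]))
        msg <- c(msg, paste0(cls[i], " must be a subset of gray_matter"))
      for (j in seq_len(i - 1L))
        if (any(m[[cls[i]]] & m[[cls[j]]]))
          msg <- c(msg, paste0(cls[i], " and ", cls[j], " must be disjoint"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated subject
#'
#' @slot ki,vp 3D ground-truth parameter maps.
#' @slot labels 3D integer region-label array (see [phantomLabels()]).
#' @slot cpTimes,cp the noiseless plasma curve on the merged time grid.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(ki = "array", vp = "array", labels = "array",
                 cpTimes = "numeric", cp = "numeric")
)

#' Cohort regression result
#'
#' Standardized multiple-regression output for one region of interest:
#' per-predictor standardized coefficients beta = b * SD(x)/SD(y), raw
#' coefficients, and two-sided t-test p-values, together with the analysis
#' sample size. For the brain-integrity interaction models, `stages` keeps
#' the full (interaction) model alongside the reduced model, and
#' `interactionPruned` records whether the non-significant interaction term
#' was removed before reading the main effects.
#'
#' @slot roi outcome region label.
#' @slot coefficients data.frame with columns `term`, `b`, `beta`, `p`.
#' @slot n rows used after complete-case filtering.
#' @slot nDropped rows dropped as incomplete.
#' @slot interactionPruned logical (NA for models without interaction).
#' @slot stages named list of per-stage coefficient tables
#'   (`full`, `reduced`).
#' @exportClass RegressionResult
setClass("RegressionResult",
  representation(roi = "character", coefficients = "data.frame",
                 n = "integer", nDropped = "integer",
                 interactionPruned = "logical", stages = "list")
)

setValidity("RegressionResult", function(object) {
  msg <- character()
  cf <- object@coefficients
  if (!all(c("term", "b", "beta", "p") %in% names(cf)))
    msg <- c(msg, "coefficients must have term, b, beta, p")
  else if (any(cf$p < 0 | cf$p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
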