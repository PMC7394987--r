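#' Parametric population input function
#'
#' A parsimonious single-peaked stand-in for a measured sinus concentration
#' curve: zero before bolus arrival, a gamma-variate rise that attains
#' exactly `peakConcentration` at `bolusArrival + riseTime`, and a
#' biexponential washout thereafter (continuous at the peak).
#'
#' @param times sampling times (s), non-decreasing.
#' @param bolusArrival bolus arrival time (s).
#' @param peakConcentration peak plasma concentration (mM), > 0.
#' @param decayRates two positive washout rates (s^-1), fast then slow.
#' @param riseTime arrival-to-peak time (s).
#' @param alpha gamma-variate shape of the rise.
#' @param washoutWeight weight of the fast washout component in (0, 1).
#' @return plasma concentration at `times` (mM), non-negative.
#' @examples
#' t <- seq(0, 600, by = 3.2)
#' cp <- populationAif(t, bolusArrival = 20, peakConcentration = 6,
#'                     decayRates = c(0.05, 8e-4))
#' max(cp)  # 6 at t = 28 if sampled there
#' @export
populationAif <- function(times, bolusArrival, peakConcentration,
                          decayRates, riseTime = 8, alpha = 3,
                          washoutWeight = 0.6) {
  dt <- diff(times)
  if (any(dt < 0)) {
    i <- which(dt < 0)[1L] + 1L
    stop("times must be non-decreasing; first offending index: ", i)
  }
  stopifnot(peakConcentration > 0, all(decayRates > 0),
            length(decayRates) == 2L, riseTime > 0,
            washoutWeight > 0, washoutWeight < 1)
  tp <- times - bolusArrival
  out <- numeric(length(times))
  rise <- tp > 0 & tp <= riseTime
  x <- tp[rise] / riseTime
  out[rise] <- peakConcentration * x^alpha * exp(alpha * (1 - x))
  wash <- tp > riseTime
  tw <- tp[wash] - riseTime
  out[wash] <- peakConcentration *
    (washoutWeight * exp(-decayRates[1L] * tw) +
       (1 - washoutWeight) * exp(-decayRates[2L] * tw))
  out
}

#' Forward Patlak model
#'
#' Tissue concentration under irreversible uptake,
#' \eqn{C_t(t) = K_i \int_0^t C_p d\tau + v_p C_p(t)}, with the running
#' integral computed by the trapezoid rule on the supplied sampling grid --
#' the same quadrature the fitting stage uses, so a noiseless round trip
#' through [fitPatlakVoxel()] recovers `(ki, vp)` to machine precision.
#'
#' @param ki leakage rate (min^-1).
#' @param vp plasma volume fraction.
#' @param cp plasma concentration (mM) at `times`.
#' @param times sampling times, non-decreasing.
#' @param timeUnit unit of `times` (`"s"` default or `"min"`); `ki` is in
#'   min^-1 regardless.
#' @return tissue concentration (mM) at `times`.
#' @export
forwardPatlak <- function(ki, vp, cp, times, timeUnit = c("s", "min")) {
  timeUnit <- match.arg(timeUnit)
  if (length(cp) != length(times))
    stop("cp and times must have the same length (", length(cp), " vs ",
         length(times), ")")
  if (any(diff(times) < 0)) stop("times must be non-decreasing")
  toMin <- if (timeUnit == "s") 1 / 60 else 1
  ki * cumtrapz(times, cp) * toMin + vp * cp
}

#' Saturation-recovery signal from concentration
#'
#' Exact inverse of the tissue signal-to-concentration conversion: with
#' pre-contrast relaxation rate \eqn{R_{10} = 1000 / T_{10}[ms]} and the
#' linear relaxivity relationship \eqn{R_1 = R_{10} + r_1 C}, the
#' saturation-recovery signal is \eqn{S = S_0 (1 - e^{-TD \cdot R_1})}.
#'
#' @param conc concentration (mM); may be negative as long as R1 stays
#'   positive.
#' @param t10Ms pre-contrast T1 (ms), > 0.
#' @param protocol an [AcquisitionProtocol-class] (supplies TD and
#'   relaxivity).
#' @param s0 equilibrium signal scale (arbitrary units).
#' @return signal in the units of `s0`.
#' @export
concentrationToSignal <- function(conc, t10Ms, protocol, s0 = 1000) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  if (any(t10Ms <= 0)) stop("non-physical T10 (must be > 0)")
  r10 <- 1000 / t10Ms
  r1 <- r10 + protocol@r1Relaxivity * conc
  if (any(r1 <= 0))
    stop("concentration drives R1 non-positive; outside model validity")
  s0 * (1 - exp(-(protocol@tdMs / 1000) * r1))
}

#' Region label array of the box phantom
#'
#' Integer labels: 0 background, 1 sagittal sinus, 2 white matter,
#' 3 gray matter (unclassified), 4 primary, 5 secondary, 6 tertiary
#' cortical regions. The cortical classes are disjoint boxes inside the
#' gray-matter block; on the default 32 x 32 x 16 grid every tissue region
#' exceeds 500 voxels and the sinus exceeds 100.
#'
#' @param dim grid size (3 integers >= 8).
#' @return 3D integer array.
#' @export
phantomLabels <- function(dim = c(32L, 32L, 16L)) {
  nx <- dim[1L]; ny <- dim[2L]; nz <- dim[3L]
  lab <- array(0L, dim = dim)
  zr <- 3:(nz - 2L)
  lab[1:2, 1:max(8L, ny %/% 4L), (nz %/% 3L):(2L * nz %/% 3L)] <- 1L
  lab[4:(nx %/% 2L), 3:(ny - 2L), zr] <- 2L
  gx <- (nx %/% 2L + 2L):(nx - 2L)
  ys <- 3:(ny - 2L)
  qs <- floor(seq(1L, length(ys) + 1L, length.out = 5L))
  bands <- lapply(1:4, function(k) ys[qs[k]:(qs[k + 1L] - 1L)])
  lab[gx, bands[[1L]], zr] <- 3L
  lab[gx, bands[[2L]], zr] <- 4L
  lab[gx, bands[[3L]], zr] <- 5L
  lab[gx, bands[[4L]], zr] <- 6L
  lab
}

## Region curves for one subject: noiseless signal time courses per tissue
## region on a given time grid, from ground-truth kinetics.
.regionCt <- function(spec, region, cp, x) {
  spec@ki[[region]] * x + spec@vp[[region]] * cp
}

#' Simulate a phantom subject
#'
#' Generates the dual-time acquisition of one digital phantom: the fast and
#' slow [DynamicSeries-class] (saturation-recovery signal, sinus voxels
#' carrying the blood curve through the calibration map, tissue voxels the
#' forward Patlak curves), the T10 map, the region masks, the calibration
#' curve, and the full ground truth. With `noiseSd = 0` the entire pipeline
#' (convert, fit, summarize) recovers the ground-truth Ki exactly (to
#' numerical precision); with noise, Rician (default) or Gaussian noise of
#' SD `noiseSd` x baseline signal is added per voxel and volume.
#' Identical seeds give bit-identical output.
#'
#' @param spec a [PhantomSpec-class].
#' @param protocol an [AcquisitionProtocol-class].
#' @param seed random seed; defaults to the seed in `spec`.
#' @return a list with elements `fast`, `slow` (DynamicSeries), `t10`
#'   (3D array, ms), `masks` ([ROIMaskSet-class]), `sinusMask`, `brainMask`
#'   (3D logical), `calibration` ([CalibrationCurve-class]), `groundTruth`
#'   ([GroundTruth-class]), `protocol`, and `spec`.
#' @export
simulateSubject <- function(spec = phantomSpec(),
                            protocol = acquisitionProtocol(),
                            seed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"), is(protocol, "AcquisitionProtocol"))
  set.seed(seed)
  tt <- protocolTimes(protocol)
  tMerged <- c(tt$fast, tt$slow[tt$slow > max(tt$fast)])

  aif <- function(t) populationAif(
    t, bolusArrival = spec@bolusArrivalS,
    peakConcentration = spec@aifPeakMm, decayRates = spec@aifDecayRates,
    riseTime = spec@aifRiseS)

  ## Plasma curve and its running integral on the merged grid the fitter
  ## will use; tissue curves on each sequence grid are read off this grid
  ## (slow pre-contrast volumes sit before the bolus: zero concentration).
  cpM <- aif(tMerged)
  xM <- cumtrapz(tMerged, cpM) / 60                     # mM.min
  idxFast <- seq_along(tt$fast)
  slowPost <- tt$slow > max(tt$fast)
  idxSlowM <- length(tt$fast) + seq_len(sum(slowPost))

  lab <- phantomLabels(spec@dim)
  calib <- bloodCalibration(protocol, bloodT10Ms = spec@bloodT10Ms)
  s0 <- 1000
  tdS <- protocol@tdMs / 1000

  regionSignal <- function(region, tIdx, cp, x) {
    ct <- .regionCt(spec, region, cp, x)
    concentrationToSignal(ct, spec@t10Ms[[region]], protocol, s0)
  }
  sinusSignal <- function(cp) {
    cb <- cp * (1 - spec@hct)
    sb <- s0 * (1 - exp(-tdS * 1000 / spec@bloodT10Ms))
    sb * calibrationRatio(calib, cb)
  }

  mkSeries <- function(role) {
    if (role == "fast") {
      tSeq <- tt$fast; cp <- cpM[idxFast]; x <- xM[idxFast]
      nPre <- protocol@nPrecontrastFast
    } else {
      tSeq <- tt$slow
      cp <- numeric(length(tSeq)); x <- numeric(length(tSeq))
      cp[slowPost] <- cpM[idxSlowM]; x[slowPost] <- xM[idxSlowM]
      nPre <- protocol@nPrecontrastSlow
    }
    nt <- length(tSeq)
    dat <- array(0, dim = c(spec@dim, nt))
    curves <- list()
    for (r in .tissueRegions) curves[[r]] <- regionSignal(r, NULL, cp, x)
    curves[["sinus"]] <- sinusSignal(cp)
    baseline <- array(50, dim = spec@dim)   # air/background floor
    codes <- c(sinus = 1L, white_matter = 2L, gray_matter = 3L,
               primary = 4L, secondary = 5L, tertiary = 6L)
    for (k in seq_len(nt)) {
      vol <- array(50, dim = spec@dim)
      for (r in names(codes)) {
        nm <- if (r == "gray_matter") "gray_matter" else r
        cur <- if (r == "sinus") curves[["sinus"]] else curves[[nm]]
        vol[lab == codes[[r]]] <- cur[k]
      }
      dat[, , , k] <- vol
    }
    for (r in names(codes)) {
      cur <- if (r == "sinus") curves[["sinus"]] else curves[[r]]
      baseline[lab == codes[[r]]] <- cur[1L]
    }
    if (spec@noiseSd > 0) {
      sig <- as.vector(baseline) * spec@noiseSd
      nvox <- prod(spec@dim)
      for (k in seq_len(nt)) {
        v <- as.vector(dat[, , , k])
        if (spec@noiseModel == "rician") {
          v <- sqrt((v + rnorm(nvox, 0, sig))^2 + rnorm(nvox, 0, sig)^2)
        } else {
          v <- v + rnorm(nvox, 0, sig)
        }
        dat[, , , k] <- array(v, dim = spec@dim)
      }
    }
    dynamicSeries(dat, tSeq, role, nPre)
  }

  fast <- mkSeries("fast")
  slow <- mkSeries("slow")

  t10 <- array(1000, dim = spec@dim)
  t10[lab == 1L] <- spec@bloodT10Ms
  codes <- c(white_matter = 2L, gray_matter = 3L, primary = 4L,
             secondary = 5L, tertiary = 6L)
  kiTrue <- array(0, dim = spec@dim)
  vpTrue <- array(0, dim = spec@dim)
  for (r in names(codes)) {
    sel <- lab == codes[[r]]
    t10[sel] <- spec@t10Ms[[r]]
    kiTrue[sel] <- spec@ki[[r]]
    vpTrue[sel] <- spec@vp[[r]]
  }

  list(fast = fast, slow = slow, t10 = t10,
       masks = roiMaskSet(lab),
       sinusMask = array(lab == 1L, dim = spec@dim),
       brainMask = array(lab %in% codes, dim = spec@dim),
       calibration = calib,
       groundTruth = new("GroundTruth", ki = kiTrue, vp = vpTrue,
                         labels = lab, cpTimes = tMerged, cp = cpM),
       protocol = protocol, spec = spec)
}

#' Simulate a phantom cohort table
#'
#' Generates a per-subject cohort table with per-region mean leakage rates
#' carrying a programmed standardized age effect. On the cube-root scale the
#' regional Ki is normal with location/scale anchored at the published
#' medians and quartiles; the standardized outcome is
#' \deqn{y^* = b_a z_{age} + b_m z_{med} + b_i (z_{age} z_{med} - r) + s\,\epsilon}
#' with \eqn{s} chosen to keep unit total variance, so the programmed
#' standardized age effect is exact in the population. Covariates (systolic
#' blood pressure, BMI, diabetes, smoking, WMH volume, cortical thickness,
#' hippocampal volume) are generated with their stated distributions and age
#' loadings. Identical seeds give identical tables.
#'
#' @param spec a [CohortSpec-class].
#' @return a `data.frame` (the cohort table) with columns `id, age, sex,
#'   sbp, bmi, diabetes, smoker, wmhVolume, corticalThickness,
#'   hippocampalVolume` and `ki_<region>` for the five regions, plus an
#'   attribute `groundTruth` holding the generating `CohortSpec` and the latent standardized
#'   outcomes.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(spec@seed)
  n <- spec@nSubjects
  age <- rtruncnorm(n, spec@ageMean, spec@ageSd, spec@ageRange[1L],
                    spec@ageRange[2L])
  ## standardize on the realized sample: truncation shrinks the age SD, and
  ## the programmed effect is defined on the standardized analysis scale
  zAge <- (age - mean(age)) / sd(age)
  sex <- rbinom(n, 1L, spec@pMale)

  mkMeasure <- function(r) r * zAge + sqrt(1 - r^2) * rnorm(n)
  zW <- mkMeasure(spec@covAgeLoading[["wmhVolume"]])
  zC <- mkMeasure(spec@covAgeLoading[["corticalThickness"]])
  zH <- mkMeasure(spec@covAgeLoading[["hippocampalVolume"]])
  zMed <- switch(ifelse(is.na(spec@mediator), "none", spec@mediator),
                 wmhVolume = zW, corticalThickness = zC,
                 hippocampalVolume = zH, none = NULL)

  sbp <- spec@sbpMean + 0.4 * spec@sbpSd * zAge +
    spec@sbpSd * sqrt(1 - 0.16) * rnorm(n)
  bmi <- spec@bmiMean + spec@bmiSd * rnorm(n)
  diabetes <- rbinom(n, 1L, spec@pDiabetes)
  smoker <- rbinom(n, 1L, spec@pSmoker)
  wmh <- exp(spec@wmhMeanlog + spec@wmhSdlog * zW)
  ct <- spec@ctMean + spec@ctSd * zC
  hc <- spec@hcMean + spec@hcSd * zH

  tab <- data.frame(id = sprintf("sub-%03d", seq_len(n)), age = age,
                    sex = sex, sbp = sbp, bmi = bmi, diabetes = diabetes,
                    smoker = smoker, wmhVolume = wmh,
                    corticalThickness = ct, hippocampalVolume = hc)

  rMed <- if (is.null(zMed)) 0 else
    spec@covAgeLoading[[spec@mediator]]
  latent <- list()
  z <- qnorm(0.75)
  for (r in .tissueRegions) {
    bA <- if (is.null(zMed)) spec@ageBeta[[r]] else 0
    bM <- if (is.null(zMed)) 0 else spec@mediatorBeta
    bI <- spec@interactionBeta
    zm <- if (is.null(zMed)) numeric(n) else zMed
    varExplained <- bA^2 + bM^2 + 2 * bA * bM * rMed + bI^2 * (1 + rMed^2)
    s <- spec@noiseScale * sqrt(max(0.02, 1 - varExplained))
    y <- bA * zAge + bM * zm + bI * (zAge * zm - rMed) + s * rnorm(n)
    muT <- signedCbrt(spec@kiMedian[[r]])
    sdT <- (signedCbrt(spec@kiP75[[r]]) - signedCbrt(spec@kiP25[[r]])) /
      (2 * z)
    tki <- muT + sdT * y
    tab[[paste0("ki_", r)]] <- sign(tki) * tki^2 * abs(tki)  # cube, signed
    latent[[r]] <- y
  }
  attr(tab, "groundTruth") <- list(spec = spec, zAge = zAge,
                                   latent = latent)
  tab
}
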