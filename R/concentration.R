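#' Saturation-recovery signal to relaxation rate
#'
#' Inverts the saturation-recovery signal equation for the longitudinal
#' relaxation rate: with baseline rate `r10` (s^-1) and saturation delay
#' `tdMs`, \deqn{R_1 = -\ln\!\big(1 - (S/S_{base})(1 - e^{-TD R_{10}})\big)/TD.}
#' Signal at baseline maps to exactly `r10`. Noise can push the signal above
#' the saturation ceiling, where the log argument becomes non-positive: such
#' samples are clamped to a configurable ceiling fraction and flagged, never
#' silently turned into non-finite values.
#'
#' @param signal signal values (any shape).
#' @param baselineSignal matching pre-contrast baseline signal, > 0.
#' @param r10 baseline relaxation rate (s^-1).
#' @param tdMs saturation delay (ms), > 0.
#' @param ceilingFrac samples are clamped so that the recovery argument
#'   stays above `1 - ceilingFrac` (default 0.999, i.e. R1 is capped at
#'   -ln(0.001)/TD).
#' @return numeric R1 (s^-1) with attribute `clamped`: logical vector
#'   marking clamped samples.
#' @export
signalToR1 <- function(signal, baselineSignal, r10, tdMs,
                       ceilingFrac = 0.999) {
  if (any(baselineSignal <= 0)) stop("baselineSignal must be > 0")
  if (any(tdMs <= 0)) stop("tdMs must be > 0")
  stopifnot(ceilingFrac > 0, ceilingFrac < 1)
  tdS <- tdMs / 1000
  e <- 1 - exp(-tdS * r10)
  arg <- 1 - (signal / baselineSignal) * e
  clamped <- arg <= (1 - ceilingFrac)
  clamped[is.na(clamped)] <- FALSE
  arg <- pmax(arg, 1 - ceilingFrac)
  r1 <- -log(arg) / tdS
  attr(r1, "clamped") <- clamped
  r1
}

#' Relaxation rate to concentration
#'
#' The linear relaxivity relationship \eqn{C = (R_1 - R_{10}) / r_1}.
#' Sign-preserving: negative concentrations are retained, they encode noise
#' and are required by the downstream symmetric noise correction.
#'
#' @param r1 relaxation rate values (s^-1).
#' @param r10 baseline relaxation rate (s^-1).
#' @param relaxivity contrast-agent relaxivity (L mmol^-1 s^-1), > 0.
#' @return concentration (mM).
#' @export
r1ToConcentration <- function(r1, r10, relaxivity) {
  if (any(relaxivity <= 0)) stop("relaxivity must be > 0")
  (r1 - r10) / relaxivity
}

#' Extract the vascular input function from sinus voxels
#'
#' Averages the dynamic signal over the sinus mask, forms the enhancement
#' ratio relative to the pre-contrast mean, maps the ratio to blood
#' concentration through the monotone calibration curve, and converts blood
#' to plasma concentration with the hematocrit,
#' \eqn{C_p = C_b / (1 - Hct)}.
#'
#' @param series a [DynamicSeries-class] (fast or slow).
#' @param sinusMask 3D logical mask of sinus voxels.
#' @param calibration a [CalibrationCurve-class].
#' @param minVoxels minimum sinus voxel count (default 20).
#' @param hct hematocrit (default 0.45).
#' @param allowExtrapolation passed to [calibrationConcentration()].
#' @return a [VascularInputFunction-class] at the series time stamps.
#' @export
extractVif <- function(series, sinusMask, calibration, minVoxels = 20L,
                       hct = 0.45, allowExtrapolation = FALSE) {
  stopifnot(is(series, "DynamicSeries"), is(calibration, "CalibrationCurve"))
  d <- dim(series@data)
  if (!identical(dim(sinusMask), d[1:3]))
    stop("sinus mask grid ", paste(dim(sinusMask), collapse = "x"),
         " does not match series grid ", paste(d[1:3], collapse = "x"))
  nVox <- sum(sinusMask)
  if (nVox < minVoxels)
    stop("sinus mask too small: ", nVox, " < ", minVoxels, " voxels")
  nt <- d[4L]
  flat <- matrix(series@data, nrow = prod(d[1:3]), ncol = nt)
  s <- colMeans(flat[as.vector(sinusMask), , drop = FALSE])
  sBase <- mean(s[seq_len(series@nPrecontrast)])
  ratio <- s / sBase
  cb <- calibrationConcentration(calibration, ratio,
                                 allowExtrapolation = allowExtrapolation)
  vascularInputFunction(series@times, cb / (1 - hct), nVox)
}

#' Merge fast and slow vascular input functions
#'
#' Keeps every fast sample and the slow samples after the fast window,
#' mirroring [mergeDualTime()]; the reported voxel count is the smaller of
#' the two contributions.
#'
#' @param fastVif,slowVif [VascularInputFunction-class] objects.
#' @return a merged [VascularInputFunction-class].
#' @export
mergeVif <- function(fastVif, slowVif) {
  stopifnot(is(fastVif, "VascularInputFunction"),
            is(slowVif, "VascularInputFunction"))
  keep <- slowVif@times > max(fastVif@times)
  vascularInputFunction(c(fastVif@times, slowVif@times[keep]),
                        c(fastVif@cp, slowVif@cp[keep]),
                        min(fastVif@nVoxels, slowVif@nVoxels))
}

## Convert one dynamic series to a ConcentrationSeries (single role).
.convertSeries <- function(series, t10, relaxivity, brainMask, tdMs,
                           ceilingFrac = 0.999) {
  d <- dim(series@data)
  if (!identical(dim(t10), d[1:3]) || !identical(dim(brainMask), d[1:3]))
    stop("T10 map / mask grid does not match series grid (",
         paste(d[1:3], collapse = "x"), ")")
  nt <- d[4L]
  nvox <- prod(d[1:3])
  flat <- matrix(series@data, nrow = nvox, ncol = nt)
  inMask <- as.vector(brainMask)
  conc <- matrix(NA_real_, nrow = nvox, ncol = nt)
  nClamped <- 0L
  if (any(inMask)) {
    sub <- flat[inMask, , drop = FALSE]
    base <- rowMeans(sub[, seq_len(series@nPrecontrast), drop = FALSE])
    r10 <- 1000 / as.vector(t10)[inMask]
    r1 <- signalToR1(sub, base, r10, tdMs, ceilingFrac)
    nClamped <- sum(attr(r1, "clamped"))
    conc[inMask, ] <- r1ToConcentration(as.numeric(r1), r10, relaxivity)
  }
  if (nClamped > 0L)
    warning(nClamped, " voxel-time sample(s) clamped at the saturation ",
            "ceiling in the ", series@role, " series")
  new("ConcentrationSeries",
      data = array(conc, dim = d), times = series@times,
      provenance = rep(series@role, nt))
}

#' Convert one dynamic series to tissue concentration
#'
#' Voxel-wise signal-to-concentration conversion inside the brain mask via
#' [signalToR1()] then [r1ToConcentration()], using the series' own
#' pre-contrast volumes as baseline and the T10 map for the baseline rate.
#' Voxels outside the mask are `NA`.
#'
#' @param series a [DynamicSeries-class].
#' @param t10 3D T10 map (ms).
#' @param brainMask 3D logical mask.
#' @param relaxivity contrast relaxivity (L mmol^-1 s^-1).
#' @param tdMs saturation delay (ms).
#' @param ceilingFrac clamping ceiling, see [signalToR1()].
#' @return a [ConcentrationSeries-class] (single sequence).
#' @export
seriesConcentration <- function(series, t10, brainMask, relaxivity = 5,
                                tdMs = 120, ceilingFrac = 0.999) {
  stopifnot(is(series, "DynamicSeries"))
  if (!any(brainMask)) {
    warning("empty brain mask: returning an all-NA concentration series")
  }
  .convertSeries(series, t10, relaxivity, brainMask, tdMs, ceilingFrac)
}

#' Dual-time tissue concentration
#'
#' Converts the fast and the slow series with their own baselines and merges
#' them into a single time-ordered [ConcentrationSeries-class].
#'
#' @param fast,slow [DynamicSeries-class] objects on a common grid.
#' @inheritParams seriesConcentration
#' @return merged [ConcentrationSeries-class].
#' @export
tissueConcentration <- function(fast, slow, t10, brainMask, relaxivity = 5,
                                tdMs = 120, ceilingFrac = 0.999) {
  stopifnot(is(fast, "DynamicSeries"), is(slow, "DynamicSeries"))
  if (!identical(dim(fast@data)[1:3], dim(slow@data)[1:3]))
    stop("fast and slow series are not on a common grid")
  fc <- seriesConcentration(fast, t10, brainMask, relaxivity, tdMs,
                            ceilingFrac)
  sc <- seriesConcentration(slow, t10, brainMask, relaxivity, tdMs,
                            ceilingFrac)
  mergeDualTime(fc, sc)
}

#' Merge dual-time concentration series
#'
#' Builds the single time-ordered series the Patlak fit consumes: every fast
#' time point up to the end of the fast sequence, then the slow time points
#' after it. Slow points at or before the last fast time (including the slow
#' sequence's pre-contrast volumes) are dropped with a message; provenance
#' flags are preserved, and the merged time stamps are strictly increasing.
#'
#' @param fastConc,slowConc [ConcentrationSeries-class] objects on a common
#'   grid. `slowConc` may be empty (0 time points), in which case the fast
#'   input is returned unchanged.
#' @return merged [ConcentrationSeries-class].
#' @export
mergeDualTime <- function(fastConc, slowConc) {
  stopifnot(is(fastConc, "ConcentrationSeries"),
            is(slowConc, "ConcentrationSeries"))
  if (length(slowConc@times) == 0L) return(fastConc)
  if (!identical(dim(fastConc@data)[1:3], dim(slowConc@data)[1:3]))
    stop("fast and slow concentration series are not on a common grid")
  fEnd <- max(fastConc@times)
  keep <- slowConc@times > fEnd
  nDrop <- sum(!keep)
  if (nDrop > 0L)
    message(nDrop, " slow time point(s) at or before the fast window ",
            "dropped in merge")
  times <- c(fastConc@times, slowConc@times[keep])
  prov <- c(fastConc@provenance, slowConc@provenance[keep])
  d <- dim(fastConc@data)
  dat <- array(NA_real_, dim = c(d[1:3], length(times)))
  dat[, , , seq_len(d[4L])] <- fastConc@data
  if (any(keep))
    dat[, , , d[4L] + seq_len(sum(keep))] <- slowConc@data[, , , keep]
  o <- order(times)
  if (is.unsorted(times))
    dat <- dat[, , , o, drop = FALSE]
  new("ConcentrationSeries", data = dat, times = times[o],
      provenance = prov[o])
}
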