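#' Blood signal calibration curve from the saturation-recovery model
#'
#' Builds the in-vitro style calibration table linking blood gadolinium
#' concentration to the signal-enhancement ratio. The table is computed at
#' the nodes from the saturation-recovery signal equation with the blood
#' relaxation time, and is then treated as the single authoritative
#' enhancement map: both the simulator (concentration to enhancement) and
#' [extractVif()] (enhancement to concentration) evaluate the same monotone
#' Hyman-spline interpolant of this table, so the blood conversion
#' round-trips exactly.
#'
#' @param protocol an [AcquisitionProtocol-class] (supplies TD and
#'   relaxivity).
#' @param bloodT10Ms blood pre-contrast T1 (ms).
#' @param concMaxMm upper end of the in-vitro concentration range (mM);
#'   default 40 mM as in in-vitro phantom protocols.
#' @param stepMm node spacing (mM).
#' @return A [CalibrationCurve-class] object.
#' @export
bloodCalibration <- function(protocol, bloodT10Ms = 1650, concMaxMm = 40,
                             stepMm = 0.5) {
  stopifnot(is(protocol, "AcquisitionProtocol"), bloodT10Ms > 0)
  conc <- c(0, seq(stepMm, concMaxMm, by = stepMm))
  tdS <- protocol@tdMs / 1000
  r10 <- 1000 / bloodT10Ms
  r1 <- r10 + protocol@r1Relaxivity * conc
  s <- 1 - exp(-tdS * r1)
  new("CalibrationCurve", concMm = conc, ratio = s / s[1L])
}

## Monotone interpolant of the calibration table (conc -> ratio).
.calibSpline <- function(curve) {
  splinefun(curve@concMm, curve@ratio, method = "hyman")
}

#' Evaluate and invert a calibration curve
#'
#' `calibrationRatio` maps blood concentration to signal-enhancement ratio
#' through the monotone interpolant of the table; `calibrationConcentration`
#' inverts the same interpolant numerically (bisection to ~1e-12 mM), so the
#' two are exact inverses of each other.
#'
#' @param curve a [CalibrationCurve-class].
#' @param concMm blood concentration values (mM) within the table range.
#' @param ratio enhancement-ratio values.
#' @param allowExtrapolation if `FALSE` (default), ratios above the top of
#'   the table are an error; if `TRUE`, linear extrapolation from the last
#'   segment slope is used and a warning is raised. Ratios below the
#'   zero-concentration baseline are always mapped through the initial
#'   slope to (small) negative concentrations: they are the symmetric
#'   noise excursions the downstream histogram correction relies on, not
#'   out-of-range data.
#' @return numeric vector.
#' @export
calibrationRatio <- function(curve, concMm) {
  stopifnot(is(curve, "CalibrationCurve"))
  rng <- range(curve@concMm)
  if (any(concMm < rng[1L] - 1e-12 | concMm > rng[2L] + 1e-12))
    stop("concentration outside calibration range [", rng[1L], ", ",
         rng[2L], "] mM")
  .calibSpline(curve)(concMm)
}

#' @rdname calibrationRatio
#' @export
calibrationConcentration <- function(curve, ratio,
                                     allowExtrapolation = FALSE) {
  stopifnot(is(curve, "CalibrationCurve"))
  f <- .calibSpline(curve)
  rmin <- curve@ratio[1L]
  rmax <- curve@ratio[length(curve@ratio)]
  cmax <- curve@concMm[length(curve@concMm)]
  out <- numeric(length(ratio))
  above <- ratio > rmax
  if (any(above) && !allowExtrapolation)
    stop("enhancement ratio above calibration range (max ",
         signif(rmax, 6),
         "); pass allowExtrapolation = TRUE to permit linear extrapolation")
  if (any(above))
    warning(sum(above), " point(s) linearly extrapolated above the ",
            "calibration range")
  for (i in seq_along(ratio)) {
    r <- ratio[i]
    if (r <= rmin) {
      ## extend below with the initial slope (covers pre-bolus noise dips)
      slope <- (curve@ratio[2L] - curve@ratio[1L]) /
        (curve@concMm[2L] - curve@concMm[1L])
      out[i] <- (r - rmin) / slope
    } else if (r >= rmax) {
      k <- length(curve@ratio)
      slope <- (curve@ratio[k] - curve@ratio[k - 1L]) /
        (curve@concMm[k] - curve@concMm[k - 1L])
      out[i] <- cmax + (r - rmax) / slope
    } else {
      out[i] <- uniroot(function(cc) f(cc) - r, interval = c(0, cmax),
                        tol = 1e-13 * max(1, cmax))$root
    }
  }
  out
}

#' Read/write a calibration curve as CSV
#'
#' Two-column CSV (`conc_mm`, `ratio`).
#' @param curve a [CalibrationCurve-class].
#' @param path file path.
#' @return `readCalibration` returns a [CalibrationCurve-class];
#'   `writeCalibration` returns `path` invisibly.
#' @export
writeCalibration <- function(curve, path) {
  write.csv(data.frame(conc_mm = curve@concMm, ratio = curve@ratio),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  df <- read.csv(path)
  new("CalibrationCurve", concMm = df$conc_mm, ratio = df$ratio)
}
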