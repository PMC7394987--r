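#' Build the Patlak design from a vascular input function
#'
#' Resamples the plasma concentration to the tissue sampling times by linear
#' interpolation (interpolation only -- tissue times outside the VIF
#' coverage are an error), computes the running trapezoid integral in
#' mM.min, and marks the usable time points. Bolus arrival is detected as
#' the first VIF time at which the plasma concentration exceeds
#' `arrivalFrac` of its peak; pre-arrival points whose concentration is
#' below `cpFloor` are excluded from the usable mask.
#'
#' @param vif a [VascularInputFunction-class].
#' @param tissueTimes tissue sampling times, non-decreasing, inside the VIF
#'   time range.
#' @param cpFloor plasma concentration floor (mM) below which pre-bolus
#'   points are unusable.
#' @param arrivalFrac fraction of the peak defining bolus arrival
#'   (default 0.05).
#' @param timeUnit unit of the time stamps (`"s"` default or `"min"`); the
#'   integral is in mM.min either way.
#' @return a [PatlakDesign-class].
#' @export
buildDesign <- function(vif, tissueTimes, cpFloor = 1e-3,
                        arrivalFrac = 0.05, timeUnit = c("s", "min")) {
  timeUnit <- match.arg(timeUnit)
  stopifnot(is(vif, "VascularInputFunction"))
  if (any(diff(tissueTimes) < 0)) stop("tissue times must be non-decreasing")
  rng <- range(vif@times)
  if (any(tissueTimes < rng[1L] - 1e-9 | tissueTimes > rng[2L] + 1e-9))
    stop("tissue times extend beyond VIF coverage [", rng[1L], ", ",
         rng[2L], "] s; no extrapolation is performed")
  cp <- approx(vif@times, vif@cp, xout = tissueTimes, rule = 1)$y
  toMin <- if (timeUnit == "s") 1 / 60 else 1
  cpInt <- cumtrapz(tissueTimes, cp) * toMin
  peak <- max(vif@cp)
  if (peak > 0 && peak >= cpFloor) {
    tArr <- vif@times[which(vif@cp > arrivalFrac * peak)[1L]]
    usable <- !(tissueTimes < tArr & cp < cpFloor)
  } else {
    tArr <- NA_real_
    usable <- rep(FALSE, length(tissueTimes))
  }
  new("PatlakDesign", times = as.numeric(tissueTimes), cp = cp,
      cpIntegral = cpInt, usable = usable, bolusArrivalS = tArr)
}

## Shared QR factorization of the two-column design. The QR route keeps
## full double precision where the explicit 2x2 normal equations lose
## ~5 digits to cancellation; rank deficiency (Cp proportional to its
## integral over the usable window) shows up as rank < 2.
.patlakDecomp <- function(design) {
  u <- design@usable
  if (sum(u) < 3L)
    stop("need >= 3 usable time points, got ", sum(u))
  A <- cbind(ki = design@cpIntegral[u], vp = design@cp[u])
  qrA <- qr(A)
  list(A = A, qr = qrA, singular = qrA$rank < 2L)
}

#' Fit the Patlak model in one voxel
#'
#' Ordinary least squares of the tissue concentration on the running plasma
#' integral and the plasma concentration over the usable time points -- the
#' direct bilinear form of the Patlak relation, algebraically identical to
#' the classical graphical plot but numerically stable when the plasma
#' concentration is small. The leakage rate is in min^-1 because the
#' design integral is in mM.min.
#'
#' @param ct tissue concentration (mM) at the design times.
#' @param design a [PatlakDesign-class] with >= 3 usable points.
#' @return list with `ki` (min^-1), `vp`, `residSd` (mM, n-2 dof), and
#'   `flagged` (TRUE when the design is rank-deficient or the data are not
#'   finite; parameters are then `NA` sentinels).
#' @export
fitPatlakVoxel <- function(ct, design) {
  stopifnot(is(design, "PatlakDesign"))
  if (length(ct) != length(design@times))
    stop("ct length ", length(ct), " does not match design length ",
         length(design@times))
  nd <- .patlakDecomp(design)
  y <- ct[design@usable]
  if (nd$singular || any(!is.finite(y)))
    return(list(ki = NA_real_, vp = NA_real_, residSd = NA_real_,
                flagged = TRUE))
  beta <- qr.coef(nd$qr, y)
  resid <- y - nd$A %*% beta
  n <- length(y)
  list(ki = unname(beta[1L]), vp = unname(beta[2L]),
       residSd = sqrt(sum(resid^2) / (n - 2L)), flagged = FALSE)
}

#' Voxel-wise Patlak leakage map
#'
#' Applies the Patlak least-squares fit to every voxel inside the mask,
#' sharing the design factorization across voxels. Voxels with non-finite
#' concentrations are flagged and excluded downstream; the count of flagged
#' voxels is reported via `message()`. Deterministic given its inputs.
#'
#' @param conc a merged [ConcentrationSeries-class].
#' @param vif a [VascularInputFunction-class] covering the tissue times.
#' @param brainMask 3D logical mask (non-empty).
#' @param cpFloor,arrivalFrac passed to [buildDesign()].
#' @param slowOnly if `TRUE`, restrict the fit to slow-sequence time points
#'   (plus the usable-mask rule); default `FALSE` fits both phases jointly.
#' @return a [LeakageMap-class].
#' @export
fitPatlakMap <- function(conc, vif, brainMask, cpFloor = 1e-3,
                         arrivalFrac = 0.05, slowOnly = FALSE) {
  stopifnot(is(conc, "ConcentrationSeries"))
  d <- dim(conc@data)
  if (!identical(dim(brainMask), d[1:3]))
    stop("mask grid does not match concentration grid")
  if (!any(brainMask)) stop("empty brain mask")
  design <- buildDesign(vif, conc@times, cpFloor, arrivalFrac)
  if (slowOnly)
    design@usable <- design@usable & conc@provenance == "slow"
  nd <- .patlakDecomp(design)
  if (nd$singular)
    stop("rank-deficient Patlak design: plasma concentration is ",
         "proportional to its integral over the usable window")
  u <- design@usable
  nvox <- prod(d[1:3])
  flat <- matrix(conc@data, nrow = nvox, ncol = d[4L])
  inMask <- as.vector(brainMask)
  Y <- flat[inMask, u, drop = FALSE]
  ok <- rowSums(!is.finite(Y)) == 0L
  coefs <- matrix(NA_real_, nrow = sum(inMask), ncol = 2L)
  rsd <- rep(NA_real_, sum(inMask))
  if (any(ok)) {
    B <- qr.coef(nd$qr, t(Y[ok, , drop = FALSE]))
    coefs[ok, ] <- t(B)
    res <- t(Y[ok, , drop = FALSE]) - nd$A %*% B
    rsd[ok] <- sqrt(colSums(res^2) / (nrow(nd$A) - 2L))
  }
  mk <- function(vals) {
    a <- array(NA_real_, dim = d[1:3])
    a[inMask] <- vals
    a
  }
  flagged <- array(TRUE, dim = d[1:3])
  flagged[inMask] <- !ok
  nFlag <- sum(inMask) - sum(ok)
  message("fitted ", sum(ok), " voxels (", nFlag, " flagged) over ",
          sum(u), " usable time points")
  new("LeakageMap", ki = mk(coefs[, 1L]), vp = mk(coefs[, 2L]),
      residSd = mk(rsd), flagged = flagged,
      df = as.integer(nrow(nd$A) - 2L))
}
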