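## Shared fixtures, built in code. The noiseless default subject is
## expensive enough (~1 s) to cache per test session.

.fixtures <- new.env(parent = emptyenv())

noiselessSubject <- function() {
  if (is.null(.fixtures$noiseless)) {
    .fixtures$noiseless <- suppressMessages(
      simulateSubject(phantomSpec(noiseSd = 0)))
  }
  .fixtures$noiseless
}

## Convert + fit + summarize for a simulated subject, returning map,
## summary and the merged VIF.
runSubjectStages <- function(sub, binWidth = NULL, ...) {
  fv <- extractVif(sub$fast, sub$sinusMask, sub$calibration,
                   hct = sub$spec@hct)
  sv <- extractVif(sub$slow, sub$sinusMask, sub$calibration,
                   hct = sub$spec@hct)
  vif <- mergeVif(fv, sv)
  conc <- suppressMessages(tissueConcentration(
    sub$fast, sub$slow, sub$t10, sub$brainMask,
    relaxivity = sub$protocol@r1Relaxivity, tdMs = sub$protocol@tdMs))
  map <- suppressMessages(fitPatlakMap(conc, vif, sub$brainMask, ...))
  list(vif = vif, conc = conc, map = map,
       summary = summarizeRois(map, sub$masks, binWidth = binWidth))
}

## Ground-truth mean Ki over a mask.
truthMean <- function(sub, mask) mean(sub$groundTruth@ki[mask])

## Gaussian Ki map of given voxel count as a (n x 1 x 1) LeakageMap-like
## array, for histogram-level tests that bypass the imaging stages.
kiNoiseMap <- function(n, sigma, mu = 0) {
  array(rnorm(n, mu, sigma), dim = c(n, 1L, 1L))
}

fullMask <- function(a) array(TRUE, dim = dim(a))

## Corrected whole-ROI mean from a bare Ki array.
correctedMean <- function(values, binWidth = NULL) {
  a <- array(values, dim = c(length(values), 1L, 1L))
  meanKi(noiseCorrect(kiHistogram(a, fullMask(a), binWidth)))
}

## Null spec for cohort generators: all programmed age effects zero.
nullAgeBeta <- setNames(rep(0, 5), c("white_matter", "gray_matter",
                                     "primary", "secondary", "tertiary"))
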