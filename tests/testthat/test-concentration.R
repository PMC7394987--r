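test_that("signal-to-R1 conversion inverts the saturation-recovery model", {
  r10 <- 1000 / 1100
  td <- 120
  sBase <- 1000 * (1 - exp(-0.12 * r10))
  ## identity at baseline
  expect_equal(as.numeric(signalToR1(sBase, sBase, r10, td)), r10)
  ## linearized regime: small TD*R10 and small enhancement
  r10s <- 0.2; tds <- 10
  sB <- 1 - exp(-0.01 * r10s)
  dS <- 1e-4 * sB
  dR1 <- as.numeric(signalToR1(sB + dS, sB, r10s, tds)) - r10s
  expect_equal(dR1, (dS / sB) * r10s, tolerance = 1e-2)
  ## round trip against known R1(t)
  p <- acquisitionProtocol()
  r1True <- seq(0.5, 5, length.out = 20)
  sig <- 1000 * (1 - exp(-0.12 * r1True))
  r1Est <- signalToR1(sig, 1000 * (1 - exp(-0.12 * r10)), r10, td)
  expect_equal(as.numeric(r1Est), r1True, tolerance = 1e-10)
  ## above-ceiling samples are clamped and flagged, never non-finite
  over <- signalToR1(c(sBase, 2000), sBase, r10, td)
  expect_true(all(is.finite(over)))
  expect_identical(attr(over, "clamped"), c(FALSE, TRUE))
  expect_error(signalToR1(1, 0, r10, td), "baselineSignal")
})

test_that("relaxation-to-concentration is linear and sign-preserving", {
  expect_equal(r1ToConcentration(1.5, 1.0, 5.0), 0.1)
  expect_equal(r1ToConcentration(1.0, 1.0, 5.0), 0)
  expect_equal(r1ToConcentration(0.8, 1.0, 5.0), -0.04)  # noise retained
  a <- 3.7
  expect_equal(r1ToConcentration(1 + a * 0.5, 1, 5),
               a * r1ToConcentration(1.5, 1, 5))
  expect_error(r1ToConcentration(1, 1, 0), "relaxivity")
})

test_that("calibration curve is monotone and self-inverse", {
  curve <- bloodCalibration(acquisitionProtocol(), bloodT10Ms = 1650)
  expect_true(all(diff(curve@ratio) > 0))
  conc <- c(0, 0.037, 0.5, 3.21, 6, 17.3)
  back <- calibrationConcentration(curve, calibrationRatio(curve, conc))
  expect_equal(back, conc, tolerance = 1e-9)
  ## monotone in the enhancement ratio
  r <- seq(1, max(curve@ratio), length.out = 40)
  expect_true(all(diff(calibrationConcentration(curve, r)) > 0))
  ## sub-baseline ratios map to small negative concentrations
  expect_lt(calibrationConcentration(curve, 0.995), 0)
  ## above-range refusal without the explicit flag
  expect_error(calibrationConcentration(curve, max(curve@ratio) + 1),
               "allowExtrapolation")
  expect_warning(
    calibrationConcentration(curve, max(curve@ratio) + 1,
                             allowExtrapolation = TRUE),
    "extrapolated")
})

test_that("VIF extraction recovers the ground-truth plasma curve", {
  sub <- noiselessSubject()
  fv <- extractVif(sub$fast, sub$sinusMask, sub$calibration)
  sv <- extractVif(sub$slow, sub$sinusMask, sub$calibration)
  vif <- mergeVif(fv, sv)
  gt <- sub$groundTruth
  idx <- match(vifTimes(vif), gt@cpTimes)
  expect_false(anyNA(idx))
  expect_lt(max(abs(vifCp(vif) - gt@cp[idx])), 1e-9)
  expect_gte(vif@nVoxels, 20L)
})

test_that("VIF extraction rejects undersized masks naming the count", {
  sub <- noiselessSubject()
  small <- array(FALSE, dim = dim(sub$sinusMask))
  small[which(sub$sinusMask)[1:19]] <- TRUE
  expect_error(extractVif(sub$fast, small, sub$calibration), "19 < 20")
})

test_that("an all-baseline series yields a zero input function", {
  d <- c(6, 6, 4)
  dat <- array(70, dim = c(d, 10))
  ser <- dynamicSeries(dat, seq(0, 27, by = 3), "fast", 3L)
  mask <- array(TRUE, dim = d)
  curve <- bloodCalibration(acquisitionProtocol())
  vif <- extractVif(ser, mask, curve)
  expect_equal(vifCp(vif), rep(0, 10))
})

test_that("noiseless tissue conversion reproduces the forward model", {
  sub <- noiselessSubject()
  conc <- suppressMessages(tissueConcentration(
    sub$fast, sub$slow, sub$t10, sub$brainMask))
  gt <- sub$groundTruth
  times <- seriesTimes(conc)
  idx <- match(times, gt@cpTimes)
  x <- c(0, cumsum(diff(gt@cpTimes) *
                   (gt@cp[-1] + gt@cp[-length(gt@cp)]) / 2))[idx] / 60
  wmVox <- which(roiMask(sub$masks, "white_matter"), arr.ind = TRUE)[1, ]
  ct <- seriesData(conc)[wmVox[1], wmVox[2], wmVox[3], ]
  truth <- 11.4e-7 * x + 0.008 * gt@cp[idx]
  expect_lt(max(abs(ct - truth)), 1e-9)
  ## pre-contrast concentrations are numerically zero without noise
  expect_lt(max(abs(ct[1:5])), 1e-12)
})

test_that("pre-contrast concentration is zero-mean under noise", {
  spec <- phantomSpec(dim = c(16L, 16L, 8L), noiseSd = 0.02,
                      noiseModel = "gaussian", seed = 21L)
  sub <- simulateSubject(spec)
  conc <- suppressWarnings(suppressMessages(tissueConcentration(
    sub$fast, sub$slow, sub$t10, sub$brainMask)))
  pre <- seriesData(conc)[, , , 1:4]
  v <- pre[!is.na(pre)]
  expect_lt(abs(mean(v)), 4 * sd(v) / sqrt(length(v)))
})

test_that("empty mask conversion warns and returns all-NA", {
  sub <- noiselessSubject()
  empty <- array(FALSE, dim = dim(sub$t10))
  expect_warning(cs <- seriesConcentration(sub$fast, sub$t10, empty),
                 "empty brain mask")
  expect_true(all(is.na(seriesData(cs))))
})

test_that("dual-time merge keeps fast points, appends late slow points", {
  sub <- noiselessSubject()
  fc <- suppressMessages(seriesConcentration(sub$fast, sub$t10,
                                             sub$brainMask))
  sc <- suppressMessages(seriesConcentration(sub$slow, sub$t10,
                                             sub$brainMask))
  merged <- suppressMessages(mergeDualTime(fc, sc))
  tm <- seriesTimes(merged)
  expect_true(all(diff(tm) > 0))
  expect_lte(length(tm), 59L)                 # 29 fast + 30 slow at most
  expect_identical(sum(merged@provenance == "fast"), 29L)
  ## slow pre-contrast volumes (before the fast window) are dropped, logged
  expect_message(mergeDualTime(fc, sc), "dropped in merge")
  ## fast-only input is the identity
  emptySlow <- new("ConcentrationSeries",
                   data = array(0, dim = c(dim(seriesData(fc))[1:3], 0)),
                   times = numeric(0), provenance = character(0))
  expect_identical(mergeDualTime(fc, emptySlow), fc)
})
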