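test_that("design integrals are exact for constants and ramps", {
  t <- seq(0, 300, by = 3)
  vif <- vascularInputFunction(t, rep(2, length(t)), 25L)
  des <- buildDesign(vif, t)
  expect_equal(des@cpIntegral, 2 * t / 60)     # trapezoid exact for constants
  a <- 0.01
  vifRamp <- vascularInputFunction(t, a * t, 25L)
  desRamp <- buildDesign(vifRamp, t)
  expect_equal(desRamp@cpIntegral, a * t^2 / 2 / 60, tolerance = 1e-12)
  ## zero plasma curve leaves no usable points
  vif0 <- vascularInputFunction(t, rep(0, length(t)), 25L)
  expect_false(any(buildDesign(vif0, t)@usable))
  ## coverage is interpolation-only
  expect_error(buildDesign(vif, c(t, 400)), "beyond VIF coverage")
  expect_error(buildDesign(vif, c(3, 2, 1)), "non-decreasing")
})

test_that("voxel fits recover forward-model parameters exactly", {
  t <- seq(0, 900, by = 10)
  cp <- populationAif(t, 20, 6, c(0.05, 8e-4))
  vif <- vascularInputFunction(t, cp, 25L)
  des <- buildDesign(vif, t)
  ki <- 11.4e-7                 # white-matter median leakage rate
  vp <- 0.01
  ct <- forwardPatlak(ki, vp, cp, t)
  fit <- fitPatlakVoxel(ct, des)
  expect_equal(fit$ki, ki, tolerance = 1e-12)
  expect_equal(fit$vp, vp, tolerance = 1e-12)
  expect_false(fit$flagged)
  ## all-zero tissue curve
  fit0 <- fitPatlakVoxel(numeric(length(t)), des)
  expect_identical(c(fit0$ki, fit0$vp, fit0$residSd), c(0, 0, 0))
  ## degenerate design: regressor columns carry no independent information
  bad <- new("PatlakDesign", times = t, cp = numeric(length(t)),
             cpIntegral = numeric(length(t)),
             usable = rep(TRUE, length(t)), bolusArrivalS = 20)
  fitBad <- fitPatlakVoxel(ct, bad)
  expect_true(fitBad$flagged)
  expect_true(is.na(fitBad$ki))
  ## too few usable points
  des3 <- des
  des3@usable[-(1:2)] <- FALSE
  expect_error(fitPatlakVoxel(ct, des3), ">= 3 usable")
})

test_that("least squares agrees with a brute-force SSE grid oracle", {
  set.seed(4)
  t <- seq(0, 900, by = 15)
  cp <- populationAif(t, 20, 6, c(0.05, 8e-4))
  vif <- vascularInputFunction(t, cp, 25L)
  des <- buildDesign(vif, t)
  u <- des@usable
  ## grid half-widths equilibrated by the design column norms, so the
  ## diagonal SSE valley cannot carry the argmin more than ~1 step away
  hk <- 5e-7
  hv <- hk * sqrt(sum(des@cpIntegral[u]^2) / sum(des@cp[u]^2))
  for (rep in 1:3) {
    kiTrue <- runif(1, 0, 1.8e-5)
    vpTrue <- runif(1, 0.002, 0.045)
    kiGrid <- kiTrue + seq(-hk, hk, length.out = 60)
    vpGrid <- vpTrue + seq(-hv, hv, length.out = 60)
    ct <- forwardPatlak(kiTrue, vpTrue, cp, t)
    fit <- fitPatlakVoxel(ct, des)
    sse <- outer(kiGrid, vpGrid, Vectorize(function(k, v)
      sum((ct[u] - k * des@cpIntegral[u] - v * des@cp[u])^2)))
    best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    expect_lt(abs(fit$ki - kiGrid[best[1]]), 1.5 * diff(kiGrid[1:2]))
    expect_lt(abs(fit$vp - vpGrid[best[2]]), 1.5 * diff(vpGrid[1:2]))
  }
})

test_that("map fitting matches the voxel fit and flags bad voxels", {
  sub <- noiselessSubject()
  st <- runSubjectStages(sub)
  ok <- !flaggedMap(st$map)
  expect_lt(max(abs(kiMap(st$map)[ok] - sub$groundTruth@ki[ok])), 1e-9)
  expect_lt(max(abs(vpMap(st$map)[ok] - sub$groundTruth@vp[ok])), 1e-9)
  expect_equal(sum(ok), sum(sub$brainMask))
  ## single-voxel mask
  one <- array(FALSE, dim = dim(sub$t10))
  one[which(sub$brainMask)[1]] <- TRUE
  conc <- st$conc
  m1 <- suppressMessages(fitPatlakMap(conc, st$vif, one))
  expect_equal(sum(!flaggedMap(m1)), 1L)
  ## empty mask is an error
  none <- array(FALSE, dim = dim(sub$t10))
  expect_error(fitPatlakMap(conc, st$vif, none), "empty")
  ## NA voxels (outside conversion mask) are flagged, not propagated
  widened <- array(TRUE, dim = dim(sub$t10))
  mWide <- suppressMessages(fitPatlakMap(conc, st$vif, widened))
  expect_true(all(is.na(kiMap(mWide)[flaggedMap(mWide) & widened])))
})

test_that("fitted Ki is linear in the data and unit-invariant", {
  t <- seq(0, 900, by = 10)
  cp <- populationAif(t, 20, 6, c(0.05, 8e-4))
  des <- buildDesign(vascularInputFunction(t, cp, 25L), t)
  ct <- forwardPatlak(2e-6, 0.01, cp, t)
  base <- fitPatlakVoxel(ct, des)
  scaled <- fitPatlakVoxel(3.5 * ct, des)
  expect_equal(scaled$ki, 3.5 * base$ki, tolerance = 1e-12)
  expect_equal(scaled$vp, 3.5 * base$vp, tolerance = 1e-12)
  ## minutes-based design gives the same Ki in min^-1
  desMin <- buildDesign(vascularInputFunction(t / 60, cp, 25L), t / 60,
                        timeUnit = "min")
  fitMin <- fitPatlakVoxel(ct, desMin)
  expect_equal(fitMin$ki, base$ki, tolerance = 1e-10)
})

test_that("the null fit is unbiased and sign-symmetric", {
  set.seed(9)
  t <- seq(0, 900, by = 10)
  cp <- populationAif(t, 20, 6, c(0.05, 8e-4))
  des <- buildDesign(vascularInputFunction(t, cp, 25L), t)
  u <- des@usable
  A <- cbind(des@cpIntegral[u], des@cp[u])
  kis <- vapply(1:1000, function(i) {
    ct <- rnorm(length(t), 0, 0.005)
    fitPatlakVoxel(ct, des)$ki
  }, numeric(1))
  se <- sd(kis) / sqrt(length(kis))
  expect_lt(abs(mean(kis)), 2.5 * se)          # CI covers zero
  expect_gt(mean(kis < 0), 0.45)               # ~half the voxels negative
  expect_lt(mean(kis < 0), 0.55)
})
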