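test_that("population input function is zero pre-bolus, peaks by construction", {
  t <- seq(0, 100, by = 0.5)
  cp <- populationAif(t, bolusArrival = 20, peakConcentration = 6,
                      decayRates = c(0.05, 8e-4), riseTime = 8)
  expect_true(all(cp[t <= 20] == 0))
  expect_equal(cp[t == 28], 6)          # exactly the peak at arrival + rise
  expect_true(all(cp >= 0))
  expect_equal(which.max(cp), which(t == 28))  # single-peaked
  expect_error(populationAif(c(0, 2, 1), 0.5, 1, c(1, 1)),
               "offending index: 3")
})

test_that("input-function integral matches the closed form", {
  ## oracle: dense trapezoid quadrature of the curve itself
  P <- 6; t0 <- 20; rise <- 8; a <- 3; w <- 0.6; k <- c(0.05, 8e-4)
  horizon <- 5000
  tDense <- seq(0, horizon, by = 0.01)
  cp <- populationAif(tDense, t0, P, k, riseTime = rise, alpha = a,
                      washoutWeight = w)
  quad <- sum(diff(tDense) * (cp[-1] + cp[-length(cp)]) / 2)
  ## closed form: incomplete-gamma rise + biexponential washout
  T <- horizon - t0 - rise
  riseInt <- P * rise * exp(a) * a^(-(a + 1)) * gamma(a + 1) *
    pgamma(a, shape = a + 1, rate = 1)
  washInt <- P * (w / k[1] * (1 - exp(-k[1] * T)) +
                  (1 - w) / k[2] * (1 - exp(-k[2] * T)))
  expect_equal(quad, riseInt + washInt, tolerance = 1e-3)
})

test_that("forward Patlak model is linear and unit-consistent", {
  t <- seq(0, 600, by = 3.2)
  expect_equal(forwardPatlak(0, 0, rep(1, length(t)), t),
               rep(0, length(t)))
  ## constant plasma concentration: Ct(t) = K * t / 60
  K <- 2e-6
  expect_equal(forwardPatlak(K, 0, rep(1, length(t)), t), K * t / 60)
  expect_error(forwardPatlak(1e-6, 0.01, c(1, 2), c(0, 1, 2)),
               "same length")
  ## identical result when times are supplied in minutes
  cp <- populationAif(t, 20, 6, c(0.05, 8e-4))
  expect_equal(forwardPatlak(K, 0.01, cp, t),
               forwardPatlak(K, 0.01, cp, t / 60, timeUnit = "min"))
})

test_that("signal synthesis hits its analytic limits and inverts", {
  p <- acquisitionProtocol()
  tdS <- p@tdMs / 1000
  r10 <- 1000 / 1100
  s0 <- 1000
  expect_equal(concentrationToSignal(0, 1100, p, s0),
               s0 * (1 - exp(-tdS * r10)))
  ## saturation-recovery ceiling at huge concentration
  expect_equal(concentrationToSignal(1e6, 1100, p, s0), s0,
               tolerance = 1e-12)
  expect_error(concentrationToSignal(1, -5, p), "non-physical T10")
  ## round trip through the conversion stage
  conc <- c(-0.05, 0, 0.01, 0.4, 2)
  sig <- concentrationToSignal(conc, 1100, p, s0)
  r1 <- signalToR1(sig, concentrationToSignal(0, 1100, p, s0), r10, p@tdMs)
  back <- r1ToConcentration(as.numeric(r1), r10, p@r1Relaxivity)
  expect_equal(back, conc, tolerance = 1e-10)
})

test_that("simulated subjects are seed-deterministic", {
  spec <- phantomSpec(dim = c(12L, 12L, 8L), noiseSd = 0.05, seed = 11L)
  a <- simulateSubject(spec)
  b <- simulateSubject(spec)
  expect_identical(seriesData(a$fast), seriesData(b$fast))
  expect_identical(seriesData(a$slow), seriesData(b$slow))
  c <- simulateSubject(phantomSpec(dim = c(12L, 12L, 8L), noiseSd = 0.05,
                                   seed = 12L))
  expect_false(identical(seriesData(a$fast), seriesData(c$fast)))
})

test_that("zero kinetics give a flat baseline signal", {
  zero <- setNames(rep(0, 5), names(nullAgeBeta))
  spec <- phantomSpec(dim = c(12L, 12L, 8L), noiseSd = 0,
                      ki = zero,
                      vp = setNames(rep(0, 5), names(nullAgeBeta)))
  sub <- simulateSubject(spec)
  dat <- seriesData(sub$fast)
  wm <- roiMask(sub$masks, "white_matter")
  first <- dat[, , , 1][wm]
  for (k in c(2, 10, 29)) expect_equal(dat[, , , k][wm], first)
})

test_that("cohort tables have the full schema at minimal n", {
  tab <- simulateCohort(cohortSpec(nSubjects = 3L, seed = 5L))
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("id", "age", "sex", "sbp", "bmi", "diabetes", "smoker",
                    "wmhVolume", "corticalThickness", "hippocampalVolume",
                    paste0("ki_", names(nullAgeBeta))) %in% names(tab)))
  expect_true(all(tab$age >= 47 & tab$age <= 91))
  expect_identical(tab, simulateCohort(cohortSpec(nSubjects = 3L,
                                                  seed = 5L)))
})

test_that("a zero programmed age effect is a true null", {
  ## age-Ki correlation should be non-significant in >= 90% of seeds
  hits <- vapply(1:100, function(s) {
    tab <- simulateCohort(cohortSpec(nSubjects = 57L, ageBeta = nullAgeBeta,
                                     seed = s))
    cor.test(tab$age, transformKi(tab$ki_white_matter))$p.value >= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("regional Ki distributions track the programmed medians", {
  ## large-n sample medians sit near the anchor values
  tab <- simulateCohort(cohortSpec(nSubjects = 2000L, seed = 3L))
  med <- vapply(names(nullAgeBeta),
                function(r) median(tab[[paste0("ki_", r)]]), numeric(1))
  expect_equal(unname(med["white_matter"]), 11.4e-7, tolerance = 0.1)
  expect_equal(unname(med["tertiary"]), 9.2e-7, tolerance = 0.15)
})
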