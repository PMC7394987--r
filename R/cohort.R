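#' Variable transforms for the cohort analysis
#'
#' `transformKi` is the signed cube root, `sign(x) |x|^{1/3}`: it normalizes
#' the right-skewed regional mean leakage rates while remaining defined for
#' the negative means a noise-corrected summary can produce. It is strictly
#' monotone and invertible, so it never changes the sign or ordering of the
#' ROI means. `transformWmh` is the natural log used for white matter
#' hyperintensity volumes; non-positive volumes are an error unless a small
#' positive `offset` is supplied, in which case they are shifted with a
#' warning.
#'
#' @param values numeric vector (finite).
#' @param offset optional offset added inside the log for non-positive WMH
#'   volumes (`NULL` disables, the default).
#' @return transformed numeric vector.
#' @examples
#' transformKi(c(8, -8, 0))   # 2 -2 0
#' transformWmh(exp(1))       # 1
#' @export
transformKi <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite")
  signedCbrt(values)
}

#' @rdname transformKi
#' @export
transformWmh <- function(values, offset = NULL) {
  bad <- values <= 0
  if (any(bad)) {
    if (is.null(offset))
      stop(sum(bad), " non-positive WMH volume(s); supply a positive ",
           "`offset` to handle zeros")
    stopifnot(offset > 0)
    warning(sum(bad), " non-positive WMH volume(s) offset by ", offset)
    values[bad] <- offset
  }
  log(values)
}

#' Standardized ordinary least squares
#'
#' The shared regression core: OLS of `outcome` on `predictors` with
#' coefficients standardized on the analysis sample,
#' beta = b * SD(x)/SD(y) (binary predictors standardized the same way),
#' and two-sided t-test p-values. With a single predictor the standardized
#' coefficient equals the Pearson correlation.
#'
#' @param df data.frame holding outcome and predictors.
#' @param outcome outcome column name.
#' @param predictors predictor column names (constant predictors are an
#'   error naming the offender).
#' @return data.frame with columns `term, b, beta, p`.
#' @export
standardizedFit <- function(df, outcome, predictors) {
  for (p in predictors) {
    if (sd(df[[p]]) == 0)
      stop("constant predictor: ", p)
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = df)
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  sdy <- sd(df[[outcome]])
  data.frame(
    term = terms,
    b = sm[terms, "Estimate"],
    beta = sm[terms, "Estimate"] *
      vapply(terms, function(p) sd(df[[p]]), numeric(1)) / sdy,
    p = sm[terms, "Pr(>|t|)"],
    row.names = NULL)
}

## Complete-case analysis frame for one ROI.
.analysisFrame <- function(table, roi, extra = character()) {
  kiCol <- paste0("ki_", roi)
  if (!kiCol %in% names(table))
    stop("cohort table has no column ", kiCol)
  need <- c(kiCol, "age", "sex", extra)
  df <- table[, need, drop = FALSE]
  cc <- complete.cases(df)
  nDropped <- sum(!cc)
  if (nDropped > 0L)
    message(nDropped, " incomplete row(s) dropped for ROI ", roi)
  df <- df[cc, , drop = FALSE]
  df$y <- transformKi(df[[kiCol]])
  list(df = df, nDropped = nDropped)
}

#' Standardized regression of regional leakage on age
#'
#' Multiple linear regression of the cube-root-transformed mean leakage
#' rate of one region on age and sex; with `confounders = TRUE`, mean
#' systolic blood pressure, BMI, diabetes and smoking are added. The
#' reported coefficients are standardized (beta = b SD(x)/SD(y) on the
#' analysis sample) with two-sided t-test p-values; significance is read at
#' p < .05. Incomplete rows are dropped complete-case with a logged count.
#'
#' @param table a cohort table as produced by [simulateCohort()] (columns
#'   `age`, `sex`, covariates, and `ki_<roi>`).
#' @param roi region label (e.g. `"white_matter"`).
#' @param confounders add the confounder set (default `FALSE`).
#' @return a [RegressionResult-class].
#' @export
fitAgeModel <- function(table, roi, confounders = FALSE) {
  extra <- if (confounders) c("sbp", "bmi", "diabetes", "smoker")
           else character()
  af <- .analysisFrame(table, roi, extra)
  if (nrow(af$df) < 10L)
    stop("need >= 10 complete rows, got ", nrow(af$df))
  cf <- standardizedFit(af$df, "y", c("age", "sex", extra))
  new("RegressionResult", roi = roi, coefficients = cf,
      n = nrow(af$df), nDropped = as.integer(af$nDropped),
      interactionPruned = NA, stages = list())
}

#' Brain-integrity interaction model with pruning
#'
#' The post-hoc integrity analysis: regress the transformed regional
#' leakage on age, sex, one brain-integrity measure (WMH volume is
#' log-transformed first), and the age x measure interaction, with age and
#' the measure mean-centered before multiplication. If the interaction term
#' is not significant (p >= .05) it is removed and the main effects are
#' read from the reduced model. Both stages are reported.
#'
#' @param table cohort table.
#' @param roi region label.
#' @param measure one of `"wmhVolume"`, `"corticalThickness"`,
#'   `"hippocampalVolume"`.
#' @param wmhOffset offset passed to [transformWmh()] for zero volumes.
#' @return a [RegressionResult-class]; `coefficients` holds the model the
#'   main effects are read from, `resultStages()` both stages, and
#'   `interactionPruned()` whether the interaction was removed.
#' @export
fitInteractionModel <- function(table, roi,
                                measure = c("wmhVolume",
                                            "corticalThickness",
                                            "hippocampalVolume"),
                                wmhOffset = NULL) {
  measure <- match.arg(measure)
  af <- .analysisFrame(table, roi, measure)
  df <- af$df
  if (nrow(df) < 10L)
    stop("need >= 10 complete rows, got ", nrow(df))
  df$measure <- if (measure == "wmhVolume")
    transformWmh(df[[measure]], offset = wmhOffset) else df[[measure]]
  df$ageC <- df$age - mean(df$age)
  df$measureC <- df$measure - mean(df$measure)
  df$interaction <- df$ageC * df$measureC
  full <- standardizedFit(df, "y", c("age", "sex", "measure",
                                      "interaction"))
  pInt <- full$p[full$term == "interaction"]
  pruned <- pInt >= 0.05
  stages <- list(full = full)
  if (pruned) {
    reduced <- standardizedFit(df, "y", c("age", "sex", "measure"))
    stages$reduced <- reduced
    cf <- reduced
  } else {
    cf <- full
  }
  cf$term[cf$term == "measure"] <- measure
  new("RegressionResult", roi = roi, coefficients = cf,
      n = nrow(df), nDropped = as.integer(af$nDropped),
      interactionPruned = pruned, stages = stages)
}

#' Cohort-wide regression table
#'
#' Runs [fitAgeModel()] (or [fitInteractionModel()]) for every region and
#' returns one tidy data.frame of standardized coefficients.
#'
#' @param table cohort table.
#' @param model `"age"`, `"confounders"` or `"interaction"`.
#' @param measure integrity measure for the interaction model.
#' @param pAdjust optional multiple-testing correction across regions for
#'   the age p-values (`"none"` default, or a `p.adjust` method such as
#'   `"holm"`); the published analysis reports per-region p-values at .05.
#' @return data.frame with columns `roi, term, b, beta, p` (and
#'   `interaction_pruned` for the interaction model), plus `p_adj` when
#'   `pAdjust != "none"`.
#' @export
cohortRegressions <- function(table,
                              model = c("age", "confounders",
                                        "interaction"),
                              measure = "wmhVolume", pAdjust = "none") {
  model <- match.arg(model)
  rois <- sub("^ki_", "", grep("^ki_", names(table), value = TRUE))
  rows <- lapply(rois, function(r) {
    res <- switch(model,
      age = fitAgeModel(table, r),
      confounders = fitAgeModel(table, r, confounders = TRUE),
      interaction = fitInteractionModel(table, r, measure))
    cf <- resultCoefficients(res)
    cf$roi <- r
    if (model == "interaction")
      cf$interaction_pruned <- interactionPruned(res)
    cf
  })
  out <- do.call(rbind, rows)
  out <- out[, c("roi", setdiff(names(out), "roi"))]
  if (pAdjust != "none") {
    ageRows <- out$term == "age"
    out$p_adj <- NA_real_
    out$p_adj[ageRows] <- stats::p.adjust(out$p[ageRows], method = pAdjust)
  }
  out
}
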