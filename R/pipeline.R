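#' Resolve a pipeline configuration
#'
#' Merges a user configuration (an R list or a JSON file path) over the
#' package defaults and validates parameter ranges. The resolved
#' configuration is serialized alongside every pipeline output so a run can
#' be reproduced from its output directory alone.
#'
#' @param config `NULL` (all defaults), a named list, or a path to a JSON
#'   file.
#' @return the resolved configuration list.
#' @export
resolveConfig <- function(config = NULL) {
  defaults <- list(
    simulate = TRUE,
    seed = 1L,
    relaxivity = 5.0,
    hct = 0.45,
    tdMs = 120,
    ceilingFrac = 0.999,
    cpFloor = 1e-3,
    arrivalFrac = 0.05,
    slowOnly = FALSE,
    binWidth = NULL,
    denominator = "roi",
    noiseSd = 0.02,
    noiseModel = "rician",
    cohort = list(run = TRUE, nSubjects = 57L),
    inputs = list(fast = NULL, slow = NULL, t10 = NULL, sinusMask = NULL,
                  brainMask = NULL, labels = NULL, calibration = NULL)
  )
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(defaults, config %||% list())
  stopifnot(cfg$relaxivity > 0, cfg$hct > 0, cfg$hct < 1, cfg$tdMs > 0,
            cfg$cpFloor >= 0, cfg$arrivalFrac > 0, cfg$arrivalFrac < 1,
            cfg$denominator %in% c("roi", "corrected"),
            cfg$noiseSd >= 0)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Validate that every configured input path exists, before any compute.
.checkInputs <- function(cfg) {
  if (isTRUE(cfg$simulate)) return(invisible(TRUE))
  need <- c("fast", "slow", "t10", "sinusMask", "brainMask", "labels",
            "calibration")
  for (nm in need) {
    p <- cfg$inputs[[nm]]
    if (is.null(p)) stop("input '", nm, "' is required when simulate=FALSE")
    if (!file.exists(p)) stop("input '", nm, "' not found: ", p)
  }
  invisible(TRUE)
}

.loadSubject <- function(cfg) {
  if (isTRUE(cfg$simulate)) {
    spec <- phantomSpec(noiseSd = cfg$noiseSd, noiseModel = cfg$noiseModel,
                        hct = cfg$hct, seed = cfg$seed)
    protocol <- acquisitionProtocol(tdMs = cfg$tdMs,
                                    r1Relaxivity = cfg$relaxivity)
    return(simulateSubject(spec, protocol))
  }
  fast <- readDynamicSeries(cfg$inputs$fast)
  slow <- readDynamicSeries(cfg$inputs$slow)
  t10 <- readNifti(cfg$inputs$t10)
  sinus <- readNifti(cfg$inputs$sinusMask) > 0
  brain <- readNifti(cfg$inputs$brainMask) > 0
  labels <- readNifti(cfg$inputs$labels)
  for (other in list(t10, sinus, brain, labels))
    checkAffineMatch(attr(fast, "affine") %||% diag(4),
                     attr(other, "affine") %||% diag(4))
  list(fast = fast, slow = slow, t10 = t10,
       sinusMask = array(sinus, dim = dim(sinus)),
       brainMask = array(brain, dim = dim(brain)),
       masks = roiMaskSet(array(as.integer(labels), dim = dim(labels))),
       calibration = readCalibration(cfg$inputs$calibration))
}

#' Run the full leakage pipeline
#'
#' Executes simulate (optional) -> convert -> fit -> summarize -> cohort
#' statistics, writing every intermediate to `outDir`: Ki/vp/residual maps
#' (NIfTI), the VIF and regional summary (CSV), the regression tables
#' (CSV + JSON), the resolved configuration, and a run manifest with input
#' digests, parameter hash, package version and collected warnings. Any
#' stage failure aborts with the stage name.
#'
#' @param config see [resolveConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with `summary` (data.frame),
#'   `regressions` (data.frame or NULL), `map` ([LeakageMap-class]) and
#'   `manifest`.
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("bbbleak")) {
  cfg <- resolveConfig(config)
  .checkInputs(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  warningsLog <- character()
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warningsLog <<- c(warningsLog, paste0(name, ": ",
                                            conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sub <- stage("simulate/load", .loadSubject(cfg))

  vif <- stage("convert", {
    fastVif <- extractVif(sub$fast, sub$sinusMask, sub$calibration,
                          hct = cfg$hct)
    slowVif <- extractVif(sub$slow, sub$sinusMask, sub$calibration,
                          hct = cfg$hct)
    mergeVif(fastVif, slowVif)
  })
  conc <- stage("convert", tissueConcentration(
    sub$fast, sub$slow, sub$t10, sub$brainMask,
    relaxivity = cfg$relaxivity, tdMs = cfg$tdMs,
    ceilingFrac = cfg$ceilingFrac))

  map <- stage("fit", fitPatlakMap(conc, vif, sub$brainMask,
                                   cpFloor = cfg$cpFloor,
                                   arrivalFrac = cfg$arrivalFrac,
                                   slowOnly = isTRUE(cfg$slowOnly)))

  summary <- stage("summarize", summarizeRois(
    map, sub$masks, binWidth = cfg$binWidth,
    denominator = cfg$denominator))

  regressions <- NULL
  if (isTRUE(cfg$cohort$run)) {
    regressions <- stage("stats", {
      cspec <- cohortSpec(nSubjects = cfg$cohort$nSubjects %||% 57L,
                          seed = cfg$seed)
      tab <- simulateCohort(cspec)
      write.csv(tab, file.path(outDir, "cohort_table.csv"),
                row.names = FALSE)
      cohortRegressions(tab, model = "age")
    })
  }

  stage("write", {
    writeNifti(kiMap(map), file.path(outDir, "ki.nii.gz"))
    writeNifti(vpMap(map), file.path(outDir, "vp.nii.gz"))
    writeNifti(residSdMap(map), file.path(outDir, "resid_sd.nii.gz"))
    write.csv(data.frame(time_s = vifTimes(vif), cp_mm = vifCp(vif)),
              file.path(outDir, "vif.csv"), row.names = FALSE)
    write.csv(summary, file.path(outDir, "leakage_summary.csv"),
              row.names = FALSE)
    if (!is.null(regressions)) {
      write.csv(regressions, file.path(outDir, "regressions.csv"),
                row.names = FALSE)
      jsonlite::write_json(regressions,
                           file.path(outDir, "regressions.json"),
                           dataframe = "rows", digits = NA)
    }
  })

  outputs <- list.files(outDir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "bbbleak",
    version = as.character(utils::packageVersion("bbbleak")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    parameter_hash = unname(tools::md5sum(cfgPath)),
    stages = c("simulate/load", "convert", "fit", "summarize",
               if (!is.null(regressions)) "stats", "write"),
    input_digests = if (isTRUE(cfg$simulate)) list(simulated = cfg$seed)
      else as.list(tools::md5sum(unlist(cfg$inputs))),
    output_digests = as.list(tools::md5sum(outputs)),
    warnings = warningsLog)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(summary = summary, regressions = regressions, map = map,
                 vif = vif, manifest = manifest, outDir = outDir))
}
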