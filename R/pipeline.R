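#' Study configuration for an end-to-end repeatability run
#'
#' Exactly one input mode is active: \code{"simulate"} draws a synthetic
#' cohort from a \code{\link{CohortConfig-class}}, \code{"load"} reads an
#' existing repeated-measures TSV (schema of \code{\link{readLongTable}}).
#'
#' @param mode \code{"simulate"} or \code{"load"}
#' @param cohortConfig simulation parameters (simulate mode)
#' @param loadPath path to a repeated-measures TSV (load mode)
#' @param estimates estimate registry; defaults to
#'   \code{\link{builtinEstimates}} on the cohort config's protocols
#' @param cohorts cohort filters to report, subset of
#'   \code{c("mixed", "HC", "MS")}
#' @param alpha significance level for ICC confidence intervals
#' @param outDir output directory (created if absent)
#' @param seed integer; overrides the cohort config's seed so one flag
#'   controls all randomness
#' @return list of class \code{"StudyConfig"}
#' @export
studyConfig <- function(mode = c("simulate", "load"),
                        cohortConfig = CohortConfig(),
                        loadPath = NULL, estimates = NULL,
                        cohorts = c("mixed", "HC", "MS"), alpha = 0.05,
                        outDir = tempfile("octrepeat_"), seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(loadPath)) stop("load mode requires 'loadPath'")
  } else {
    if (!is.null(seed)) cohortConfig@seed <- as.integer(seed)
    if (is.null(estimates))
      estimates <- builtinEstimates(protocols = cohortConfig@protocols)
  }
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  structure(list(mode = mode, cohortConfig = cohortConfig,
                 loadPath = loadPath, estimates = estimates,
                 cohorts = cohorts, alpha = alpha, outDir = outDir,
                 seed = if (is.null(seed)) cohortConfig@seed else
                   as.integer(seed)),
            class = "StudyConfig")
}

## 32-bit FNV-1a over a string; cheap content fingerprint for manifests
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)  # xor touches the low byte only
    ## exact 32-bit modular multiply, split to stay within double precision
    hLo <- h %% 65536
    hHi <- h %/% 65536
    h <- (hLo * 16777619 + ((hHi * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.configAsList <- function(config) {
  cc <- config$cohortConfig
  list(mode = config$mode, loadPath = config$loadPath,
       cohorts = config$cohorts, alpha = config$alpha,
       seed = config$seed,
       cohort = if (is.null(cc)) NULL else list(
         nHcSubjects = cc@nHcSubjects, nMsSubjects = cc@nMsSubjects,
         sessionsHc = cc@sessionsHc, sessionsMs = cc@sessionsMs,
         eyesPerSubject = cc@eyesPerSubject,
         protocols = lapply(cc@protocols, function(p) list(
           name = p@name, widthMm = p@widthMm, heightMm = p@heightMm,
           axialScaleUmPerPx = p@axialScaleUmPerPx,
           artFrames = p@artFrames, device = p@device)),
         sigmaBetween = as.list(cc@sigmaBetween),
         sigmaOffset = cc@sigmaOffset, sigmaField = cc@sigmaField,
         fieldCorrLengthMm = cc@fieldCorrLengthMm,
         jitterSdMm = cc@jitterSdMm, hflAmplitude = cc@hflAmplitude,
         hflThetaRange = cc@hflThetaRange,
         msInnerScale = cc@msInnerScale, seed = cc@seed))
}

#' Run a complete repeatability study
#'
#' Simulates or loads a repeated-measures table, computes the ICC and CR
#' grid and the Bland-Altman point sets for every requested cohort filter,
#' and writes, per cohort: the formatted ICC table
#' (\code{icc_<cohort>.csv}, cells "icc [low-high]" to two decimals), the
#' formatted CR table (\code{cr_<cohort>.csv}, micrometres to two
#' decimals), the full-precision grid (\code{repeatability_<cohort>.tsv})
#' and the pooled Bland-Altman points
#' (\code{bland_altman_<cohort>.csv}, one row per eye-session-pair with
#' its estimate and layer). The measurement table itself is stored as
#' \code{measurements.tsv} and a run manifest (config echo, fingerprint,
#' seed, package version, file list) as \code{manifest.json}. Outputs are
#' deterministic: the same config and seed reproduce every byte.
#'
#' @param config a \code{\link{studyConfig}} object
#' @param quiet suppress progress messages (default FALSE; messages go to
#'   stderr)
#' @return invisibly, a list with the measurement \code{table}, per-cohort
#'   \code{reports} (long grids) and the \code{manifest}
#' @export
runStudy <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "StudyConfig"))
  say <- function(...) if (!quiet) message("[octrepeat] ", ...)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "simulate") {
    say("simulating cohort (seed ", config$cohortConfig@seed, ")")
    sim <- simulateCohort(config$cohortConfig)
    say("evaluating ", length(config$estimates), " estimates on ",
        length(sim$cohort), " volumes")
    tab <- applyAll(config$estimates, sim$cohort)
  } else {
    say("loading measurements from ", config$loadPath)
    tab <- readLongTable(config$loadPath)
  }
  writeLongTable(tab, file.path(config$outDir, "measurements.tsv"))

  reports <- list()
  files <- "measurements.tsv"
  for (cohort in config$cohorts) {
    sub <- if (cohort == "mixed") tab else
      tab[tab$group == cohort, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("cohort filter '", cohort, "' leaves no records")
    say("repeatability grid for cohort '", cohort, "'")
    grid <- suppressWarnings(
      repeatabilityTable(sub, cohort = "mixed", alpha = config$alpha))
    reports[[cohort]] <- grid

    f1 <- paste0("icc_", cohort, ".csv")
    f2 <- paste0("cr_", cohort, ".csv")
    f3 <- paste0("repeatability_", cohort, ".tsv")
    f4 <- paste0("bland_altman_", cohort, ".csv")
    utils::write.csv(formatICCTable(grid), file.path(config$outDir, f1),
                     row.names = FALSE, na = "NA")
    utils::write.csv(formatCRTable(grid), file.path(config$outDir, f2),
                     row.names = FALSE, na = "NA")
    utils::write.table(format(grid, digits = 15),
                       file.path(config$outDir, f3), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ba <- list()
    for (i in seq_len(nrow(grid))) {
      cell <- sub[sub$estimate == grid$estimate[i] &
                    sub$layer == grid$layer[i], , drop = FALSE]
      res <- blandAltman(cell$thickness_um,
                         paste(cell$subject_id, cell$eye, sep = ":"),
                         cell$session)
      pts <- res@points
      pts$estimate <- grid$estimate[i]
      pts$layer <- grid$layer[i]
      ba[[i]] <- pts[, c("estimate", "layer", "unit", "mean", "diff")]
    }
    utils::write.csv(do.call(rbind, ba), file.path(config$outDir, f4),
                     row.names = FALSE)
    files <- c(files, f1, f2, f3, f4)
  }

  cfgList <- .configAsList(config)
  cfgJson <- jsonlite::toJSON(cfgList, auto_unbox = TRUE, digits = NA,
                              null = "null")
  manifest <- list(
    tool = "OCTrepeat",
    version = as.character(utils::packageVersion("OCTrepeat")),
    seed = config$seed, configHash = .fnv1a(as.character(cfgJson)),
    config = cfgList, files = files)
  jsonlite::write_json(manifest, file.path(config$outDir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("report written to ", config$outDir)
  invisible(list(table = tab, reports = reports, manifest = manifest))
}
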