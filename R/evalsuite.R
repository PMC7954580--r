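#' @include AllClasses.R pipeline.R synthgen.R
NULL

#' EvalReport: segmentation quality over a suite of vocalizations
#'
#' @slot perVocalization data.frame with one row per (vocalization, mode):
#'   id, tier, mode, medianAbsError, fracWithin1px, success, iterations.
#' @slot summary data.frame of per-mode (and per-tier) success rates.
#' @slot masterSeed integer seed that generated the suite.
#' @export
setClass("EvalReport",
  slots = c(perVocalization = "data.frame", summary = "data.frame",
            masterSeed = "integer"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d vocalization runs, master seed %d\n",
              nrow(object@perVocalization), object@masterSeed))
  print(object@summary, row.names = FALSE)
})

edgeErrors <- function(detUpper, detLower, truth) {
  open <- truth@openFlag
  c(detUpper[open] - truth@upperEdge[open],
    detLower[open] - truth@lowerEdge[open])
}

#' Score detected edges against synthetic ground truth
#'
#' Errors are `detected - true` edge rows, pooled over the upper and lower
#' sides on open-phase columns only (the open-column set is taken from the
#' truth, never from the detector; closed phases have no edge to localize).
#' Success means the median absolute error is at most one pixel.
#'
#' @param edges an [EdgePair-class], or an edge-table data.frame from
#'   [registerEdges()] / [runVocalization()] covering the truth's frames
#'   (scored per cross-section with errors pooled; row order is irrelevant).
#' @param truth a [SyntheticTruth-class].
#' @return list with `medianAbsError`, `fracWithin1px`, `success`, `nOpen`.
#' @export
scoreVocalization <- function(edges, truth) {
  if (is(edges, "EdgePair")) {
    if (length(edges@upper) != length(truth@upperEdge))
      stop("edges and truth cover different numbers of columns",
           call. = FALSE)
    errs <- edgeErrors(edges@upper, edges@lower, truth)
  } else {
    frames <- sort(unique(edges$frame_number))
    if (length(frames) != length(truth@upperEdge))
      stop("edge table and truth cover different frame sets", call. = FALSE)
    errs <- numeric(0)
    for (csr in unique(edges$cross_section_row)) {
      sub <- edges[edges$cross_section_row == csr, , drop = FALSE]
      up <- sub[sub$edge_side == "upper", , drop = FALSE]
      lo <- sub[sub$edge_side == "lower", , drop = FALSE]
      up <- up[order(up$frame_number), ]
      lo <- lo[order(lo$frame_number), ]
      errs <- c(errs, edgeErrors(up$kymogram_row, lo$kymogram_row, truth))
    }
  }
  med <- median(abs(errs))
  list(medianAbsError = med, fracWithin1px = mean(abs(errs) <= 1),
       success = med <= 1, nOpen = sum(truth@openFlag))
}

#' Run the synthetic validation study
#'
#' Generates `n` synthetic vocalizations (a seeded mix of decent and
#' challenging tiers), runs the requested pipeline modes on each kymogram,
#' and scores every run against its exact ground truth. The per-vocalization
#' success criterion is a median open-phase absolute edge error of at most
#' one pixel.
#'
#' @param n number of vocalizations (default 76).
#' @param tierMix fraction of decent-tier vocalizations (default 0.8).
#' @param masterSeed integer master seed; drives tier assignment, rendering
#'   noise and clustering restarts.
#' @param modes pipeline modes to run (default hybrid and the
#'   uninformed-initialization `acm_only` baseline).
#' @param cfg base [PipelineConfig-class]; its mode and seed are overridden
#'   per run.
#' @param vm the [VibrationModel-class] shared by all vocalizations.
#' @param height kymogram height in pixels.
#' @return an [EvalReport-class].
#' @export
runValidationSuite <- function(n = 76L, tierMix = 0.8, masterSeed = 1L,
                               modes = c("hybrid", "acm_only"),
                               cfg = PipelineConfig(),
                               vm = VibrationModel(), height = 41L) {
  nDecent <- round(tierMix * n)
  tiers <- withSeed(masterSeed,
                    sample(c(rep("decent", nDecent),
                             rep("challenging", n - nDecent))))
  seeds <- deriveSeeds(masterSeed + 1L, n)
  rows <- list()
  for (i in seq_len(n)) {
    voc <- syntheticVocalization(seeds[i], tiers[i], vm = vm,
                                 height = height,
                                 vocalizationId = sprintf("voc%03d", i))
    for (mode in modes) {
      runCfg <- cfg
      runCfg@mode <- mode
      runCfg@masterSeed <- seeds[i]
      res <- runKymogram(voc$kymogram, runCfg)
      sc <- scoreVocalization(res$edges, voc$truth)
      rows[[length(rows) + 1L]] <-
        data.frame(id = sprintf("voc%03d", i), tier = tiers[i], mode = mode,
                   medianAbsError = sc$medianAbsError,
                   fracWithin1px = sc$fracWithin1px, success = sc$success,
                   iterations = res$iterations, stringsAsFactors = FALSE)
    }
  }
  perVoc <- do.call(rbind, rows)
  summarise <- function(df, tier) {
    data.frame(mode = unique(df$mode)[order(unique(df$mode))],
               tier = tier,
               n = as.integer(tapply(df$success, df$mode, length)),
               successRate = as.numeric(tapply(df$success, df$mode, mean)),
               medianError = as.numeric(tapply(df$medianAbsError, df$mode,
                                               median)),
               totalIterations = as.integer(tapply(df$iterations, df$mode,
                                                   sum)),
               stringsAsFactors = FALSE)
  }
  summ <- summarise(perVoc, "all")
  for (tr in unique(perVoc$tier))
    summ <- rbind(summ, summarise(perVoc[perVoc$tier == tr, ], tr))
  new("EvalReport", perVocalization = perVoc, summary = summ,
      masterSeed = as.integer(masterSeed))
}

#' Write an EvalReport as JSON (plus an optional CSV table)
#'
#' @param report an [EvalReport-class].
#' @param path output JSON path.
#' @param csvPath optional CSV path for the per-vocalization table.
#' @return invisibly, `path`.
#' @export
writeEvalReportJSON <- function(report, path, csvPath = NULL) {
  obj <- list(master_seed = report@masterSeed,
              summary = report@summary,
              per_vocalization = report@perVocalization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csvPath))
    write.csv(report@perVocalization, csvPath, row.names = FALSE)
  invisible(path)
}
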