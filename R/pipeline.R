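#' @include AllClasses.R kymograph.R features.R cluster.R glottis.R snake.R
NULL

#' Run the hybrid segmentation on one kymogram
#'
#' The per-kymogram core of the method: moving-average smoothing, moment
#' line, Tukey weighting, feature extraction, per-chunk two-class k-means,
#' glottis-label identification, seeded mask growth, edge extraction, spline
#' smoothing and (mode permitting) snake refinement.
#'
#' Modes: `"hybrid"` runs clustering followed by the snake; `"cluster_only"`
#' stops at the smoothed cluster edges; `"acm_only"` skips clustering
#' entirely and initializes flat contours at the moment line +/- 8 pixels --
#' the uninformed-initialization baseline.
#'
#' @param k a [Kymogram-class].
#' @param cfg a [PipelineConfig-class].
#' @return list with `edges` (final [EdgePair-class]), `initial` (pre-snake
#'   [EdgePair-class]), `momentLine`, `labels`, `mask`
#'   ([GlottalMask-class] or `NULL`), `iterations` (snake iterations) and
#'   `mode`.
#' @export
runKymogram <- function(k, cfg = PipelineConfig()) {
  sm <- movingAverageRows(k, cfg@smoothingWindow)
  ml <- momentLine(sm)
  H <- dim(k@pixels)[1]

  labels <- NULL; mask <- NULL
  if (cfg@mode == "acm_only") {
    init <- EdgePair(rep(clamp(ml - 8, 0, H - 1), dim(k@pixels)[2]),
                     rep(clamp(ml + 8, 0, H - 1), dim(k@pixels)[2]))
  } else {
    wk <- tukeyWeight(sm, cfg@tukeyLength, cfg@tukeyAlpha, center = ml)
    chunks <- chunkKymogram(dim(k@pixels)[2], cfg@chunkMaxFrames)
    feats <- buildFeatureStack(wk, chunks, cfg@gradientStep)
    labels <- labelKymogram(feats, chunks, seed = cfg@masterSeed)
    green <- wk@pixels[, , 2]
    gl <- integer(length(chunks))
    for (ci in seq_along(chunks)) {
      cols <- chunks[[ci]][1]:chunks[[ci]][2]
      gl[ci] <- identifyGlottisLabel(labels[, cols, drop = FALSE], ml,
                                     band = 12L,
                                     greenChunk = green[, cols,
                                                        drop = FALSE])
    }
    mask <- growGlottalMask(labels, gl, chunks, ml, seedBand = 7L)
    init <- smoothEdges(edgesFromMask(mask), ml, height = H)
  }

  if (cfg@mode == "cluster_only") {
    edges <- init
    iters <- 0L
  } else {
    edges <- refineEdges(sm, init, cfg@snake)
    iters <- attr(edges, "iterations")
  }
  list(edges = edges, initial = init, momentLine = ml, labels = labels,
       mask = mask, iterations = iters, mode = cfg@mode)
}

#' Automatic cross-section placement
#'
#' `n` rows evenly spaced over the middle 60 percent of the crop height.
#'
#' @param cropHeight crop height in pixels.
#' @param n number of cross-sections.
#' @return integer 0-based rows.
#' @export
autoCrossSections <- function(cropHeight, n = 5L) {
  lo <- 0.2 * (cropHeight - 1); hi <- 0.8 * (cropHeight - 1)
  unique(as.integer(round(seq(lo, hi, length.out = n))))
}

#' Register kymogram-space edges back to frame coordinates
#'
#' Kymogram column `t` at edge row `y` maps to
#' `frame_x = window$left + y` and `frame_y = window$top + crossSectionRow`
#' of original frame `frameNumbers[t]` (kymogram rows are left--right
#' positions, i.e. frame columns).
#'
#' @param e an [EdgePair-class].
#' @param crossSectionRow 0-based crop row of the kymogram.
#' @param windows crop-window data.frame covering every frame.
#' @param frameNumbers original frame number per kymogram column.
#' @param vocalizationId identifier for the output rows.
#' @return an edge-table data.frame (two rows per column: upper and lower).
#' @export
registerEdges <- function(e, crossSectionRow, windows, frameNumbers,
                          vocalizationId = "voc") {
  idx <- match(frameNumbers, windows$frame_number)
  if (anyNA(idx))
    stop("no crop window for frame ", frameNumbers[which(is.na(idx))[1]],
         call. = FALSE)
  T <- length(e@upper)
  one <- function(side, y) {
    data.frame(vocalization_id = vocalizationId,
               frame_number = frameNumbers,
               cross_section_row = as.integer(crossSectionRow),
               edge_side = side,
               kymogram_row = y,
               frame_x = windows$left[idx] + y,
               frame_y = windows$top[idx] + crossSectionRow,
               closed_flag = !e@valid,
               stringsAsFactors = FALSE)
  }
  rbind(one("upper", e@upper), one("lower", e@lower))
}

#' Run the full pipeline on one vocalization
#'
#' For every cross-section row: extract the kymogram from the cropped
#' frames, run the per-kymogram hybrid segmentation and register the
#' detected edges back to frame coordinates. A failure in one cross-section
#' is reported as a warning and the remaining cross-sections proceed.
#'
#' @param stack a [FrameStack-class].
#' @param windows crop-window data.frame (or `NULL` for full-frame windows).
#' @param cfg a [PipelineConfig-class]; `crossSectionRows = NA` selects
#'   automatic placement.
#' @param vocalizationId identifier.
#' @return list with `edgeTable` (data.frame over all cross-sections),
#'   `results` (per-cross-section [runKymogram()] outputs, named by row) and
#'   `iterations` (total snake iterations).
#' @export
runVocalization <- function(stack, windows, cfg = PipelineConfig(),
                            vocalizationId = "voc") {
  d <- dim(stack@frames)
  if (is.null(windows))
    windows <- data.frame(frame_number = stack@frameNumbers, top = 0L,
                          left = 0L, height = d[1], width = d[2])
  rows <- cfg@crossSectionRows
  if (length(rows) == 1L && is.na(rows))
    rows <- autoCrossSections(windows$height[1], cfg@nAutoSections)
  edgeTable <- emptyEdgeTable()
  results <- list()
  totalIters <- 0L
  for (r in rows) {
    res <- tryCatch({
      kym <- extractKymogram(stack, windows, r, vocalizationId)
      runKymogram(kym, cfg)
    }, error = function(err) {
      warning("cross-section ", r, " failed: ", conditionMessage(err),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    results[[as.character(r)]] <- res
    totalIters <- totalIters + res$iterations
    edgeTable <- rbind(edgeTable,
                       registerEdges(res$edges, r, windows,
                                     stack@frameNumbers, vocalizationId))
  }
  list(edgeTable = edgeTable, results = results, iterations = totalIters)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [PipelineConfig()] arguments in snake_case
#' (`cross_section_rows`, `chunk_max_frames`, `smoothing_window`,
#' `tukey_length`, `tukey_alpha`, `gradient_step`, `mode`, `master_seed`,
#' and a `snake:` block with `alpha, beta, gamma, sigma, max_iters, tol`).
#' Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- SnakeParams()
  if (!is.null(y$snake)) {
    s <- y$snake
    sp <- SnakeParams(
      alpha = s$alpha %||% 0.02, beta = s$beta %||% 0.1,
      gamma = s$gamma %||% 1.0, sigma = s$sigma %||% 1.5,
      maxIters = s$max_iters %||% 200L, tol = s$tol %||% 0.01)
  }
  PipelineConfig(
    crossSectionRows = unlist(y$cross_section_rows) %||% NA_integer_,
    nAutoSections = y$n_auto_sections %||% 5L,
    chunkMaxFrames = y$chunk_max_frames %||% 50L,
    smoothingWindow = y$smoothing_window %||% 5L,
    tukeyLength = y$tukey_length %||% 15L,
    tukeyAlpha = y$tukey_alpha %||% 0.25,
    gradientStep = y$gradient_step %||% 8L,
    mode = y$mode %||% "hybrid",
    snake = sp,
    masterSeed = y$master_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
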