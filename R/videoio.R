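#' @include AllClasses.R
NULL

## integer embedded in a filename (the last run of digits before the
## extension) -- numbered image sequences are ordered by this, never
## lexicographically
fileFrameNumber <- function(path) {
  base <- sub("\\.[A-Za-z]+$", "", basename(path))
  m <- regmatches(base, gregexpr("[0-9]+", base))[[1]]
  if (length(m) == 0L) return(NA_integer_)
  as.integer(m[length(m)])
}

readImageFile <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF frames",
           call. = FALSE)
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("frame is not RGB: ", path, call. = FALSE)
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Read an RGB frame stack from an AVI file or numbered image sequence
#'
#' Accepts either an uncompressed 24-bit RGB AVI file or a directory of
#' numbered PNG/TIFF images. Image sequences are ordered by the integer
#' embedded in each filename (never lexicographically), and that integer
#' becomes the frame's original recording number; AVI frames are numbered
#' `0:(T-1)`.
#'
#' @param path AVI file or directory of numbered PNG/TIFF frames.
#' @param frameRange optional inclusive pair of original frame numbers to
#'   keep.
#' @param fps frame rate used when the source does not record one
#'   (image sequences).
#' @return a [FrameStack-class].
#' @export
readFrameStack <- function(path, frameRange = NULL, fps = 4000) {
  if (!file.exists(path))
    stop("input not found: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L)
      stop("no PNG/TIFF frames found in ", path, call. = FALSE)
    nums <- vapply(files, fileFrameNumber, integer(1))
    if (anyNA(nums))
      stop("frame filename without an embedded number: ",
           basename(files[which(is.na(nums))[1]]), call. = FALSE)
    ord <- order(nums)
    files <- files[ord]; nums <- nums[ord]
    imgs <- vector("list", length(files))
    for (i in seq_along(files)) {
      imgs[[i]] <- readImageFile(files[i])
      if (i > 1L && !identical(dim(imgs[[i]]), dim(imgs[[1]])))
        stop("inconsistent frame size at ", basename(files[i]),
             call. = FALSE)
    }
    st <- FrameStack(imgs, frameNumbers = nums, fps = fps)
  } else {
    av <- readAVI(path)
    st <- FrameStack(av$frames, fps = av$fps)
  }
  if (!is.null(frameRange)) {
    keep <- st@frameNumbers >= frameRange[1] & st@frameNumbers <= frameRange[2]
    if (!any(keep))
      stop("frameRange selects no frames", call. = FALSE)
    st <- FrameStack(st@frames[, , , keep, drop = FALSE],
                     frameNumbers = st@frameNumbers[keep], fps = st@fps)
  }
  st
}

#' Write a frame stack as an AVI file or PNG sequence
#'
#' @param stack a [FrameStack-class].
#' @param path output `.avi` file, or a directory for a PNG sequence
#'   (`frame_%06d.png`, numbered by original frame numbers).
#' @param format `"avi"` or `"png"`; inferred from `path` when missing.
#' @return invisibly, `path`.
#' @export
writeFrameStack <- function(stack, path,
                            format = c("auto", "avi", "png")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.avi$", path, ignore.case = TRUE)) "avi" else "png"
  if (format == "avi") {
    writeAVI(stack@frames, path, fps = stack@fps)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_along(stack@frameNumbers)) {
      png::writePNG(stack@frames[, , , i] / 255,
                    file.path(path, sprintf("frame_%06d.png",
                                            stack@frameNumbers[i])))
    }
  }
  invisible(path)
}

#' Read per-frame crop windows from a sidecar CSV
#'
#' The sidecar table carries the motion-compensation output: one crop window
#' per frame, columns `frame_number, top, left, height, width` (0-based
#' origin). Windows are validated against the frame bounds at load time when
#' `frameDim` is supplied, and within one table all windows must share a
#' common height and width (the motion window tracks position, not size).
#'
#' @param path CSV file path.
#' @param frameDim optional `c(H, W)` of the full frames for bounds checking.
#' @return a data.frame of crop windows (possibly zero rows).
#' @export
readCropWindows <- function(path, frameDim = NULL) {
  if (!file.exists(path)) stop("crop window file not found: ", path,
                               call. = FALSE)
  w <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame_number", "top", "left", "height", "width")
  if (!all(needed %in% names(w)))
    stop("crop window CSV must have columns ",
         paste(needed, collapse = ","), call. = FALSE)
  w <- w[, needed, drop = FALSE]
  if (nrow(w) == 0L) return(w)
  validateCropWindows(w, frameDim)
  w
}

#' Validate a crop-window table
#'
#' @param windows data.frame with `frame_number, top, left, height, width`.
#' @param frameDim optional `c(H, W)` full-frame dimensions.
#' @return invisibly, `windows`.
#' @export
validateCropWindows <- function(windows, frameDim = NULL) {
  if (nrow(windows) == 0L) return(invisible(windows))
  if (any(windows$height < 1L) || any(windows$width < 1L))
    stop("crop windows must have height, width >= 1", call. = FALSE)
  if (any(windows$top < 0L) || any(windows$left < 0L))
    stop("crop windows must have non-negative origin", call. = FALSE)
  if (length(unique(windows$height)) > 1L ||
      length(unique(windows$width)) > 1L)
    stop("all crop windows in one vocalization must share height and width",
         call. = FALSE)
  if (!is.null(frameDim)) {
    bad <- windows$top + windows$height > frameDim[1] |
           windows$left + windows$width > frameDim[2]
    if (any(bad))
      stop("crop window exceeds frame bounds at frame ",
           windows$frame_number[which(bad)[1]], call. = FALSE)
  }
  invisible(windows)
}

edgeTableColumns <- c("vocalization_id", "frame_number", "cross_section_row",
                      "edge_side", "kymogram_row", "frame_x", "frame_y",
                      "closed_flag")

#' Create an empty edge table
#' @return a zero-row data.frame with the edge-table schema.
#' @export
emptyEdgeTable <- function() {
  data.frame(vocalization_id = character(0), frame_number = integer(0),
             cross_section_row = integer(0), edge_side = character(0),
             kymogram_row = numeric(0), frame_x = numeric(0),
             frame_y = numeric(0), closed_flag = logical(0),
             stringsAsFactors = FALSE)
}

#' Write a detected-edge table as CSV
#'
#' One row per (frame, cross-section, side); floats are rendered with four
#' decimals, so a write/read round trip preserves values to 1e-3.
#'
#' @param edges edge-table data.frame (see [emptyEdgeTable()] for the
#'   schema).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeEdgeTable <- function(edges, path) {
  if (!all(edgeTableColumns %in% names(edges)))
    stop("edge table missing columns: ",
         paste(setdiff(edgeTableColumns, names(edges)), collapse = ","),
         call. = FALSE)
  out <- edges[, edgeTableColumns, drop = FALSE]
  for (col in c("kymogram_row", "frame_x", "frame_y"))
    out[[col]] <- sprintf("%.4f", out[[col]])
  out$closed_flag <- ifelse(out$closed_flag, "true", "false")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge table written by [writeEdgeTable()]
#' @param path CSV path.
#' @return data.frame with the edge-table schema.
#' @export
readEdgeTable <- function(path) {
  if (!file.exists(path)) stop("edge table not found: ", path, call. = FALSE)
  e <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(closed_flag = "character"))
  if (nrow(e) == 0L) return(emptyEdgeTable())
  e$closed_flag <- e$closed_flag == "true"
  e$vocalization_id <- as.character(e$vocalization_id)
  e[, edgeTableColumns, drop = FALSE]
}

#' Export a kymogram as an 8-bit PNG
#'
#' @param k a [Kymogram-class].
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
writeKymogramPNG <- function(k, path) {
  png::writePNG(clamp(round(k@pixels), 0, 255) / 255, path)
  invisible(path)
}

#' Export a kymogram with edge traces (and optionally the glottal mask)
#' overlaid
#'
#' Edges are drawn in yellow; masked pixels, if given, are brightened toward
#' white.
#'
#' @param k a [Kymogram-class].
#' @param edges an [EdgePair-class].
#' @param path output PNG path.
#' @param mask optional [GlottalMask-class].
#' @return invisibly, `path`.
#' @export
writeOverlayPNG <- function(k, edges, path, mask = NULL) {
  img <- clamp(round(k@pixels), 0, 255)
  if (!is.null(mask)) {
    m <- mask@mask
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- clamp(plane[m] + 120, 0, 255)
      img[, , ch] <- plane
    }
  }
  H <- dim(img)[1]
  for (tcol in seq_along(edges@upper)) {
    for (y in unique(clamp(round(c(edges@upper[tcol], edges@lower[tcol])),
                           0, H - 1)) + 1L) {
      img[y, tcol, 1] <- 255; img[y, tcol, 2] <- 255; img[y, tcol, 3] <- 0
    }
  }
  png::writePNG(img / 255, path)
  invisible(path)
}
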