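#' @include AllClasses.R videoio.R
NULL

#' Extract a kymogram from a cropped frame stack
#'
#' Cuts one space--time image at a fixed cross-section: column `t` of the
#' kymogram is row `crossSectionRow` of frame `t`'s crop window, so kymogram
#' row `r` corresponds to cropped-frame column `r` (the left--right axis).
#' All three channels are carried. Every frame in the stack must have a crop
#' window; windows must share a common height and width.
#'
#' @param stack a [FrameStack-class].
#' @param windows crop-window data.frame (see [readCropWindows()]), or `NULL`
#'   to use each full frame as its own window.
#' @param crossSectionRow 0-based row within the crop.
#' @param vocalizationId identifier stored in the kymogram.
#' @return a [Kymogram-class] of shape `width x T x 3`.
#' @export
extractKymogram <- function(stack, windows, crossSectionRow,
                            vocalizationId = "voc") {
  d <- dim(stack@frames)
  if (is.null(windows)) {
    windows <- data.frame(frame_number = stack@frameNumbers, top = 0L,
                          left = 0L, height = d[1], width = d[2])
  }
  validateCropWindows(windows, frameDim = d[1:2])
  ch <- windows$height[1]; cw <- windows$width[1]
  if (crossSectionRow < 0L || crossSectionRow >= ch)
    stop("crossSectionRow must lie within the crop height", call. = FALSE)
  n <- length(stack@frameNumbers)
  idx <- match(stack@frameNumbers, windows$frame_number)
  if (anyNA(idx))
    stop("no crop window for frame ",
         stack@frameNumbers[which(is.na(idx))[1]], call. = FALSE)
  pix <- array(0, dim = c(cw, n, 3L))
  for (i in seq_len(n)) {
    top <- windows$top[idx[i]]; left <- windows$left[idx[i]]
    pix[, i, ] <- stack@frames[top + crossSectionRow + 1L,
                               (left + 1L):(left + cw), , i]
  }
  Kymogram(pix, crossSectionRow = crossSectionRow,
           frameNumbers = stack@frameNumbers,
           vocalizationId = vocalizationId)
}

## 1-D centered moving average along the row (y) axis of an H x T matrix,
## reflect (mirror-about-edge-pixel) padding.
movingAverageMatrix <- function(m, window) {
  H <- nrow(m)
  half <- (window - 1L) %/% 2L
  out <- matrix(0, H, ncol(m))
  for (k in -half:half) {
    out <- out + m[reflectIndex(seq_len(H) + k, H), , drop = FALSE]
  }
  out / window
}

#' Smooth a kymogram along the left--right axis
#'
#' Applies a centered moving-average filter of odd length (default 5 pixels,
#' center pixel included) to every channel along the row (y) axis; the time
#' axis is untouched. Borders use reflect padding.
#'
#' @param k a [Kymogram-class].
#' @param window odd window length in pixels.
#' @return the smoothed [Kymogram-class].
#' @export
movingAverageRows <- function(k, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be odd and >= 1", call. = FALSE)
  if (dim(k@pixels)[1] < window)
    stop("kymogram height is smaller than the smoothing window",
         call. = FALSE)
  pix <- k@pixels
  for (ch in 1:3) pix[, , ch] <- movingAverageMatrix(k@pixels[, , ch], window)
  initialize(k, pixels = pix)
}

## Tukey(alpha) window of odd length n: split-cosine-bell taper applied to a
## unit vector; alpha is the total tapered fraction (0 = rectangular).
tukeyWindowVector <- function(n, alpha) {
  spec.taper(rep(1, n), p = min(0.5, alpha / 2))
}

#' Down-weight kymogram rows away from the glottal midline
#'
#' Builds a Tukey window of `length` pixels centered at `round(center)` and
#' shrinks each pixel toward its channel mean: `out = m + w(r) * (in - m)`.
#' Rows outside the window span become exactly the channel mean (w = 0), the
#' window center keeps its value (w = 1), and tapered rows blend. Shrinking
#' toward the mean (rather than toward black) de-emphasizes border rows
#' without painting them glottis-dark.
#'
#' @param k a [Kymogram-class].
#' @param length odd Tukey window length in pixels (default 15).
#' @param alpha taper fraction in `[0, 1]` (0 = rectangular).
#' @param center float row at which to center the window (typically the
#'   moment line); defaults to the geometric mid-row.
#' @return the weighted [Kymogram-class].
#' @export
tukeyWeight <- function(k, length = 15L, alpha = 0.25, center = NULL) {
  length <- as.integer(length)
  H <- dim(k@pixels)[1]
  if (length > H)
    stop("Tukey window length exceeds the kymogram height", call. = FALSE)
  if (length %% 2L == 0L) stop("Tukey window length must be odd",
                               call. = FALSE)
  if (is.null(center)) center <- (H - 1) / 2
  c0 <- as.integer(round(center))
  half <- (length - 1L) %/% 2L
  w <- rep(0, H)
  span <- (c0 - half):(c0 + half)
  inside <- span >= 0L & span <= H - 1L
  w[span[inside] + 1L] <- tukeyWindowVector(length, alpha)[inside]
  pix <- k@pixels
  for (ch in 1:3) {
    m <- mean(k@pixels[, , ch])
    pix[, , ch] <- m + w * (k@pixels[, , ch] - m)
  }
  initialize(k, pixels = pix)
}
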