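#' @include AllClasses.R cluster.R
NULL

#' Red and green intensity feature planes
#'
#' Returns the red and green channel planes of the kymogram unchanged; the
#' blue channel, the noisiest of the three on color high-speed sensors, is
#' never read.
#'
#' @param k a [Kymogram-class].
#' @return list with matrices `red` and `green` (`H_k x T`).
#' @export
intensityFeatures <- function(k) {
  list(red = k@pixels[, , 1], green = k@pixels[, , 2])
}

#' Gradient-magnitude feature plane
#'
#' Computes forward differences of the green channel along both axes with a
#' step of `step` pixels, using replicate (clamped-index) padding at the
#' borders; splits each difference into its positive and negative parts and
#' returns `sqrt(Px^2 + Nx^2 + Py^2 + Ny^2)`.
#'
#' @param k a [Kymogram-class].
#' @param step difference step in pixels (default 8).
#' @return matrix `H_k x T` of gradient magnitudes.
#' @export
gradientFeature <- function(k, step = 8L) {
  step <- as.integer(step)
  G <- k@pixels[, , 2]
  H <- nrow(G); T <- ncol(G)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (step >= min(H, T))
    stop("step must be smaller than both kymogram dimensions", call. = FALSE)
  Dx <- G[, pmin(seq_len(T) + step, T), drop = FALSE] - G
  Dy <- G[pmin(seq_len(H) + step, H), , drop = FALSE] - G
  Px <- pmax(Dx, 0); Nx <- pmin(Dx, 0)
  Py <- pmax(Dy, 0); Ny <- pmin(Dy, 0)
  sqrt(Px^2 + Nx^2 + Py^2 + Ny^2)
}

#' Min-max normalize a feature plane to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant plane maps to all zeros.
#'
#' @param plane numeric matrix.
#' @return normalized matrix.
#' @export
normalize01 <- function(plane) {
  lo <- min(plane); hi <- max(plane)
  if (hi - lo <= 0) return(array(0, dim = dim(plane)))
  (plane - lo) / (hi - lo)
}

#' Assemble the per-chunk normalized feature stack
#'
#' Computes the three feature planes (red intensity, green intensity,
#' gradient magnitude; the gradient once over the whole kymogram so step-wide
#' differences see true neighbours across chunk borders), then min-max
#' normalizes each feature independently within each chunk -- the scope on
#' which clustering operates, so chunk-local contrast adapts to dim segments.
#'
#' @param k a [Kymogram-class].
#' @param chunks list of `c(start, end)` 1-based column spans (see
#'   [chunkKymogram()]); default one chunk covering everything.
#' @param step gradient step in pixels.
#' @return a [FeatureStack-class].
#' @export
buildFeatureStack <- function(k, chunks = NULL, step = 8L) {
  T <- dim(k@pixels)[2]
  if (is.null(chunks)) chunks <- list(c(1L, T))
  planes <- list(intensityFeatures(k)$red, intensityFeatures(k)$green,
                 gradientFeature(k, step))
  vals <- array(0, dim = c(dim(k@pixels)[1], T, 3L))
  for (span in chunks) {
    cols <- span[1]:span[2]
    for (f in 1:3)
      vals[, cols, f] <- normalize01(planes[[f]][, cols, drop = FALSE])
  }
  new("FeatureStack", values = vals, step = as.integer(step),
      chunks = chunks, sourceId = k@vocalizationId)
}
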