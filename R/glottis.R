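#' @include AllClasses.R
NULL

#' First moment of inertia of the inverted green channel
#'
#' The intensity-weighted mean row of `255 - G` over the whole kymogram: a
#' horizontal line through the center of darkness, i.e. the glottal midline.
#' Computed on the green channel, the least noisy of the three. An all-white
#' kymogram (zero total inverted mass) falls back to the geometric mid-row.
#'
#' @param k a [Kymogram-class].
#' @return float row (0-based).
#' @export
momentLine <- function(k) {
  G <- k@pixels[, , 2]
  w <- 255 - G
  denom <- sum(w)
  if (denom <= 0) return((nrow(G) - 1) / 2)
  rows <- seq_len(nrow(G)) - 1
  sum(rowSums(w) * rows) / denom
}

#' Identify which cluster label is the glottis within one chunk
#'
#' The mode of the labels within `band` pixels above and below the moment
#' line (clamped to the image) is declared non-glottis -- the glottis is a
#' minority, dark structure near the midline surrounded by tissue -- and the
#' other label is returned. A chunk carrying a single label (the degenerate
#' closed-phase fit) returns the absent label, so the downstream mask is
#' empty. An exact tie in the band is broken by mean green intensity: the
#' darker cluster is the glottis.
#'
#' @param labels integer `H_k x T_chunk` label matrix of one chunk.
#' @param ml moment-line row (float).
#' @param band half-height of the mode band in pixels (default 12).
#' @param greenChunk optional green-channel matrix of the chunk, used only
#'   for the tie-break.
#' @return glottis label, 1 or 2.
#' @export
identifyGlottisLabel <- function(labels, ml, band = 12L,
                                 greenChunk = NULL) {
  present <- sort(unique(as.vector(labels)))
  if (length(present) == 1L) return(if (present == 1L) 2L else 1L)
  H <- nrow(labels)
  rows <- which(abs(seq_len(H) - 1 - ml) <= band)
  bandLabels <- labels[rows, , drop = FALSE]
  n1 <- sum(bandLabels == 1L); n2 <- sum(bandLabels == 2L)
  if (n1 > n2) return(2L)
  if (n2 > n1) return(1L)
  if (!is.null(greenChunk)) {
    g <- greenChunk[rows, , drop = FALSE]
    m1 <- mean(g[bandLabels == 1L]); m2 <- mean(g[bandLabels == 2L])
    return(if (m1 <= m2) 1L else 2L)   # darker mean green is the glottis
  }
  1L
}

## 8-connected components of a logical matrix, via the pixel adjacency graph
connectedComponents8 <- function(mask) {
  H <- nrow(mask); T <- ncol(mask)
  idx <- which(mask)
  comp <- matrix(0L, H, T)
  if (length(idx) == 0L) return(comp)
  vid <- matrix(0L, H, T)
  vid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  edges <- integer(0)
  for (shift in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + shift[1]; c2 <- cc + shift[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= T
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- c(edges, rbind(vid[idx[ok]], vid[cbind(r2[ok], c2[ok])]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp[idx] <- igraph::components(g)$membership
  comp
}

#' Grow the glottal mask from the midline seed band
#'
#' Pixels carrying their chunk's glottis label and lying within `seedBand`
#' pixels of the moment line seed an 8-connected flood fill restricted to
#' glottis-labelled pixels; connected components that touch no seed (e.g.
#' saturation-patch debris far from the midline) are rejected.
#'
#' @param labels integer `H_k x T` label matrix (from [labelKymogram()]).
#' @param glottisLabels integer glottis label per chunk.
#' @param chunks list of column spans.
#' @param ml moment-line row.
#' @param seedBand half-height of the seed band in pixels (default 7).
#' @return a [GlottalMask-class].
#' @export
growGlottalMask <- function(labels, glottisLabels, chunks, ml,
                            seedBand = 7L) {
  H <- nrow(labels); T <- ncol(labels)
  glottisPix <- matrix(FALSE, H, T)
  for (ci in seq_along(chunks)) {
    cols <- chunks[[ci]][1]:chunks[[ci]][2]
    glottisPix[, cols] <- labels[, cols, drop = FALSE] == glottisLabels[ci]
  }
  seedRows <- which(abs(seq_len(H) - 1 - ml) <= seedBand)
  seeds <- matrix(FALSE, H, T)
  seeds[seedRows, ] <- glottisPix[seedRows, , drop = FALSE]
  mask <- matrix(FALSE, H, T)
  if (any(seeds)) {
    comp <- connectedComponents8(glottisPix)
    keep <- unique(comp[seeds])
    mask <- matrix(comp %in% keep[keep > 0L], H, T)
  }
  new("GlottalMask", mask = mask, glottisLabel = as.integer(glottisLabels),
      chunks = chunks)
}

#' Extract upper and lower edge traces from a glottal mask
#'
#' Per column with masked pixels: `upper = min masked row - 0.5`,
#' `lower = max masked row + 0.5` (edges sit on pixel boundaries, so a
#' one-pixel-thick mask has width one). Columns without masked pixels are
#' flagged invalid (closed phase).
#'
#' @param m a [GlottalMask-class].
#' @return an [EdgePair-class] (invalid columns carry `NA` traces).
#' @export
edgesFromMask <- function(m) {
  T <- ncol(m@mask)
  upper <- rep(NA_real_, T); lower <- rep(NA_real_, T)
  valid <- rep(FALSE, T)
  anyRow <- colSums(m@mask) > 0L
  for (tcol in which(anyRow)) {
    rows <- which(m@mask[, tcol]) - 1L
    upper[tcol] <- min(rows) - 0.5
    lower[tcol] <- max(rows) + 0.5
    valid[tcol] <- TRUE
  }
  EdgePair(upper, lower, valid)
}

## decrease spar until the spline tracks the raw trace to <= maxRMS pixels
fitSmoothingSpline <- function(x, y, maxRMS = 1) {
  if (length(unique(x)) < 8L) return(y)
  fit <- smooth.spline(x, y)
  yhat <- predict(fit, x)$y
  spar <- fit$spar
  while (sqrt(mean((yhat - y)^2)) > maxRMS && spar > 0.05) {
    spar <- spar - 0.1
    fit <- smooth.spline(x, y, spar = spar)
    yhat <- predict(fit, x)$y
  }
  yhat
}

#' Interpolate closed phases and spline-smooth the edge traces
#'
#' Invalid (closed) columns are filled by linear interpolation between the
#' nearest valid neighbours, with virtual anchors at the moment line just
#' outside both ends; each filled trace is then smoothed with a cubic
#' smoothing spline whose smoothing parameter is decreased until the RMS
#' deviation from the raw trace is at most one pixel. Ordering
#' (`upper <= lower`) is enforced by midpoint clipping and traces are clamped
#' to the image. With no valid columns both traces fall back flat to the
#' moment line; a single valid column yields the linear tent through that
#' point anchored at the moment line at both ends.
#'
#' @param e an [EdgePair-class] from [edgesFromMask()].
#' @param ml moment-line row (anchor for ends and fallback).
#' @param height kymogram height (for clamping); default `ceiling(ml * 2)`.
#' @return an [EdgePair-class] with gap-free traces; validity flags pass
#'   through unchanged.
#' @export
smoothEdges <- function(e, ml, height = NULL) {
  T <- length(e@upper)
  if (is.null(height)) height <- as.integer(ceiling(2 * ml)) + 1L
  vIdx <- which(e@valid)
  if (length(vIdx) == 0L) {
    return(EdgePair(rep(ml, T), rep(ml, T), e@valid))
  }
  fill <- function(vals) {
    xs <- c(0, vIdx, T + 1)
    ys <- c(ml, vals[vIdx], ml)
    approx(xs, ys, xout = seq_len(T))$y
  }
  up <- fitSmoothingSpline(seq_len(T), fill(e@upper))
  lo <- fitSmoothingSpline(seq_len(T), fill(e@lower))
  cross <- up > lo
  if (any(cross)) {
    mid <- (up[cross] + lo[cross]) / 2
    up[cross] <- mid; lo[cross] <- mid
  }
  EdgePair(clamp(up, 0, height - 1), clamp(lo, 0, height - 1), e@valid)
}
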