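#' @include AllClasses.R
NULL

#' External (image) energy field for the snake
#'
#' `E_ext = -|grad(G_sigma * green)|^2` with central differences (step 1,
#' distinct from the clustering feature's step 8) and reflect borders,
#' min-max normalized to `[-1, 0]`; a constant image yields an all-zero
#' field. Normalization makes the field invariant to global contrast
#' scaling. Before normalization the squared gradient is clipped at its
#' `clipQuantile` quantile, so that a handful of extreme values (borders of
#' near-saturated bright patches) cannot crush the force the glottal edges
#' exert on the contour.
#'
#' @param k a [Kymogram-class].
#' @param sigma Gaussian pre-smoothing scale in pixels (0 = none).
#' @param clipQuantile upper quantile at which the squared gradient is
#'   clipped before normalization (1 = plain min-max).
#' @return numeric `H_k x T` matrix in `[-1, 0]`.
#' @export
externalEnergyField <- function(k, sigma = 1.5, clipQuantile = 0.995) {
  G <- k@pixels[, , 2]
  if (sigma > 0) G <- EBImage::gblur(G, sigma = sigma)
  H <- nrow(G); T <- ncol(G)
  gy <- (G[reflectIndex(seq_len(H) + 1L, H), , drop = FALSE] -
         G[reflectIndex(seq_len(H) - 1L, H), , drop = FALSE]) / 2
  gx <- (G[, reflectIndex(seq_len(T) + 1L, T), drop = FALSE] -
         G[, reflectIndex(seq_len(T) - 1L, T), drop = FALSE]) / 2
  raw <- gx^2 + gy^2
  if (clipQuantile < 1) raw <- pmin(raw, quantile(raw, clipQuantile))
  lo <- min(raw); hi <- max(raw)
  if (hi - lo <= 0) return(matrix(0, H, T))
  -(raw - lo) / (hi - lo)
}

## pentadiagonal internal-energy operator with free (open-contour) ends:
## A = alpha * D1' D1 + beta * D2' D2
snakeOperator <- function(T, alpha, beta) {
  if (T < 3L) return(Matrix::Diagonal(T, x = 0))
  D1 <- Matrix::bandSparse(T - 1L, T, k = 0:1,
                           diagonals = list(rep(-1, T - 1L), rep(1, T - 1L)))
  D2 <- Matrix::bandSparse(T - 2L, T, k = 0:2,
                           diagonals = list(rep(1, T - 2L), rep(-2, T - 2L),
                                            rep(1, T - 2L)))
  alpha * Matrix::crossprod(D1) + beta * Matrix::crossprod(D2)
}

#' Discrete internal energy of a contour
#'
#' `alpha * sum(diff(y)^2) + beta * sum(diff(y, differences = 2)^2)` -- the
#' elasticity plus rigidity energy the semi-implicit scheme descends on.
#'
#' @param y contour rows.
#' @param alpha,beta elasticity and rigidity weights.
#' @return scalar energy.
#' @export
internalEnergy <- function(y, alpha, beta) {
  e <- 0
  if (length(y) >= 2L) e <- e + alpha * sum(diff(y)^2)
  if (length(y) >= 3L) e <- e + beta * sum(diff(y, differences = 2L)^2)
  e
}

## row-derivative of the external field, sampled at fractional rows per
## column by linear interpolation
externalForce <- function(dField, y) {
  H <- nrow(dField); T <- ncol(dField)
  yc <- clamp(y, 0, H - 1)
  i0 <- pmin(floor(yc), H - 2)
  frac <- yc - i0
  idx0 <- cbind(i0 + 1L, seq_len(T))
  idx1 <- cbind(i0 + 2L, seq_len(T))
  dField[idx0] * (1 - frac) + dField[idx1] * frac
}

rowDerivative <- function(field) {
  H <- nrow(field)
  (field[reflectIndex(seq_len(H) + 1L, H), , drop = FALSE] -
   field[reflectIndex(seq_len(H) - 1L, H), , drop = FALSE]) / 2
}

#' Evolve one open snake contour over an external energy field
#'
#' Iterates the semi-implicit update
#' `y_new = (A + gamma I)^-1 (gamma y - f_ext(y))` where `A` is the
#' pentadiagonal operator of elasticity (first differences) and rigidity
#' (second differences) with free-end boundary conditions and `f_ext` is the
#' row-derivative of the external field linearly interpolated at each node.
#' After each iteration the contour is clamped to the image and, when an
#' opposing contour is supplied, ordering is enforced by clipping at it.
#' Stops when the mean per-node movement drops below `tol` or after
#' `maxIters` iterations. `(A + gamma I)` is validated as symmetric positive
#' definite by its sparse Cholesky factorization.
#'
#' @param y numeric contour (one row per field column).
#' @param field external energy matrix from [externalEnergyField()].
#' @param params a [SnakeParams-class].
#' @param bound optional opposing contour; `side` tells which side `y` is.
#' @param side `"upper"` or `"lower"`; with a bound, the evolving contour is
#'   kept on its side of it.
#' @return numeric contour, with attribute `iterations`.
#' @export
evolveContour <- function(y, field, params, bound = NULL,
                          side = c("upper", "lower")) {
  side <- match.arg(side)
  T <- ncol(field); H <- nrow(field)
  if (length(y) != T)
    stop("contour length must equal the field width", call. = FALSE)
  M <- snakeOperator(T, params@alpha, params@beta) +
    params@gamma * Matrix::Diagonal(T)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M))  # fails if not SPD
  dF <- rowDerivative(field)
  iters <- 0L
  for (i in seq_len(params@maxIters)) {
    f <- externalForce(dF, y)
    yNew <- as.numeric(Matrix::solve(ch, params@gamma * y - f))
    yNew <- clamp(yNew, 0, H - 1)
    if (!is.null(bound)) {
      if (side == "upper") yNew <- pmin(yNew, bound)
      else yNew <- pmax(yNew, bound)
    }
    iters <- i
    moved <- mean(abs(yNew - y))
    y <- yNew
    if (moved < params@tol) break
  }
  attr(y, "iterations") <- iters
  y
}

#' Refine an edge pair with coupled open snakes
#'
#' Evolves the upper and lower contours against the shared external field of
#' the kymogram; after each joint iteration, crossings are resolved by
#' midpoint clipping. Validity flags from the clustering stage pass through
#' unchanged. The field is computed from the (smoothed) kymogram supplied
#' here -- use the pre-Tukey image, whose gradients are unperturbed by
#' row weighting.
#'
#' @param k a [Kymogram-class] providing the external field.
#' @param e a gap-free [EdgePair-class] (run [smoothEdges()] first).
#' @param params a [SnakeParams-class].
#' @return an [EdgePair-class] with attribute `iterations` (total joint
#'   iterations).
#' @export
refineEdges <- function(k, e, params = SnakeParams()) {
  field <- externalEnergyField(k, params@sigma)
  T <- ncol(field); H <- nrow(field)
  if (length(e@upper) != T)
    stop("edge traces must match the kymogram width", call. = FALSE)
  if (anyNA(e@upper) || anyNA(e@lower))
    stop("edge traces contain gaps; run smoothEdges() first", call. = FALSE)
  M <- snakeOperator(T, params@alpha, params@beta) +
    params@gamma * Matrix::Diagonal(T)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M))
  dF <- rowDerivative(field)
  up <- e@upper; lo <- e@lower
  iters <- 0L
  for (i in seq_len(params@maxIters)) {
    upNew <- clamp(as.numeric(Matrix::solve(ch, params@gamma * up -
                                              externalForce(dF, up))),
                   0, H - 1)
    loNew <- clamp(as.numeric(Matrix::solve(ch, params@gamma * lo -
                                              externalForce(dF, lo))),
                   0, H - 1)
    cross <- upNew > loNew
    if (any(cross)) {
      mid <- (upNew[cross] + loNew[cross]) / 2
      upNew[cross] <- mid; loNew[cross] <- mid
    }
    iters <- i
    moved <- (mean(abs(upNew - up)) + mean(abs(loNew - lo))) / 2
    up <- upNew; lo <- loNew
    if (moved < params@tol) break
  }
  out <- EdgePair(up, lo, e@valid)
  attr(out, "iterations") <- iters
  out
}
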