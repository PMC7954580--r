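#' @include AllClasses.R utils.R
NULL

#' Split kymogram columns into balanced contiguous chunks
#'
#' Columns are divided into `ceil(T / maxFrames)` contiguous spans that cover
#' all columns without overlap, each at most `maxFrames` wide, with sizes
#' differing by at most one (larger spans first).
#'
#' @param T number of kymogram columns, or a [FeatureStack-class] /
#'   [Kymogram-class] whose width is used.
#' @param maxFrames maximum chunk width (default 50).
#' @return list of `c(start, end)` 1-based column spans.
#' @export
chunkKymogram <- function(T, maxFrames = 50L) {
  if (is(T, "FeatureStack")) T <- dim(T@values)[2]
  if (is(T, "Kymogram")) T <- dim(T@pixels)[2]
  T <- as.integer(T); maxFrames <- as.integer(maxFrames)
  if (maxFrames < 1L) stop("maxFrames must be >= 1", call. = FALSE)
  nChunks <- as.integer(ceiling(T / maxFrames))
  base <- T %/% nChunks
  sizes <- base + as.integer(seq_len(nChunks) <= T %% nChunks)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
}

## squared Euclidean distances from N x p points to each of k centroid rows
distSq <- function(points, centroids) {
  d <- matrix(0, nrow(points), nrow(centroids))
  for (j in seq_len(nrow(centroids)))
    d[, j] <- rowSums(sweep(points, 2, centroids[j, ], "-")^2)
  d
}

kmeansPlusPlusInit <- function(points, k) {
  N <- nrow(points)
  idx <- sample.int(N, 1L)
  centroids <- points[idx, , drop = FALSE]
  for (j in seq_len(k - 1L)) {
    d2 <- apply(distSq(points, centroids), 1, min)
    if (sum(d2) <= 0) {
      idx <- sample.int(N, 1L)       # all mass on existing centroids
    } else {
      idx <- sample.int(N, 1L, prob = d2)
    }
    centroids <- rbind(centroids, points[idx, , drop = FALSE])
  }
  centroids
}

lloydIterate <- function(points, centroids, maxIter, tol) {
  N <- nrow(points); k <- nrow(centroids)
  labels <- max.col(-distSq(points, centroids), ties.method = "first")
  for (iter in seq_len(maxIter)) {
    newC <- centroids
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) {
        newC[j, ] <- colMeans(points[members, , drop = FALSE])
      } else {
        # re-seed an emptied centroid at the point farthest from the others
        d2 <- apply(distSq(points, newC[-j, , drop = FALSE]), 1, min)
        newC[j, ] <- points[which.max(d2), ]
      }
    }
    moved <- sqrt(max(rowSums((newC - centroids)^2)))
    centroids <- newC
    labels <- max.col(-distSq(points, centroids), ties.method = "first")
    if (moved < tol) break
  }
  inertia <- sum(distSq(points, centroids)[cbind(seq_len(N), labels)])
  list(labels = labels, centroids = centroids, nIterations = iter,
       inertia = inertia)
}

#' Two-class k-means with k-means++ seeding
#'
#' Alternates nearest-centroid assignment (Euclidean distance) and centroid
#' update (arithmetic mean of member points) until the largest centroid
#' movement falls below `tol` or `maxIter` iterations; seeding follows
#' k-means++ driven by `seed`, with `nstart` restarts keeping the
#' lowest-inertia result. An emptied cluster is re-seeded at the point
#' farthest from the remaining centroids. If all points are identical the
#' fit degenerates to a single cluster (label 1) with zero inertia.
#'
#' @param points `N x p` numeric matrix of feature vectors.
#' @param k number of clusters (default 2).
#' @param seed integer seed driving the restarts.
#' @param nstart number of k-means++ restarts (default 5).
#' @param maxIter iteration cap per restart (default 300).
#' @param tol centroid-movement convergence threshold (default 1e-6).
#' @return list with `labels` (values `1..k`), `centroids` (`k x p`),
#'   `nIterations` and `inertia`.
#' @export
kmeansFit <- function(points, k = 2L, seed = 1L, nstart = 5L,
                      maxIter = 300L, tol = 1e-6) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (N < k) stop("need at least k points", call. = FALSE)
  if (all(abs(sweep(points, 2, points[1, ], "-")) < 1e-15)) {
    return(list(labels = rep(1L, N),
                centroids = matrix(rep(points[1, ], each = k), k),
                nIterations = 0L, inertia = 0))
  }
  seeds <- deriveSeeds(seed, nstart)
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- withSeed(seeds[r], {
      lloydIterate(points, kmeansPlusPlusInit(points, k), maxIter, tol)
    })
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best$labels <- as.integer(best$labels)
  best
}

#' Cluster every chunk of a kymogram into a binary labeled image
#'
#' Each chunk is clustered independently (its own per-chunk normalization is
#' already baked into the [FeatureStack-class]) with its own sub-seed derived
#' from `seed` and the chunk index, so the result does not depend on chunk
#' processing order. Label values 1/2 are chunk-local and carry no
#' cross-chunk meaning; [identifyGlottisLabel()] resolves their semantics per
#' chunk.
#'
#' @param f a [FeatureStack-class].
#' @param chunks list of column spans (defaults to the stack's own chunks).
#' @param seed master seed.
#' @return integer `H_k x T` matrix of labels (1 or 2).
#' @export
labelKymogram <- function(f, chunks = NULL, seed = 1L) {
  if (is.null(chunks)) chunks <- f@chunks
  d <- dim(f@values)
  labels <- matrix(0L, d[1], d[2])
  seeds <- deriveSeeds(seed, length(chunks))
  for (ci in seq_along(chunks)) {
    span <- chunks[[ci]]
    cols <- span[1]:span[2]
    pts <- cbind(as.vector(f@values[, cols, 1]),
                 as.vector(f@values[, cols, 2]),
                 as.vector(f@values[, cols, 3]))
    fit <- kmeansFit(pts, k = 2L, seed = seeds[ci])
    labels[, cols] <- matrix(fit$labels, d[1], length(cols))
  }
  labels
}
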