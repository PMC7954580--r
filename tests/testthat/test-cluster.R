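test_that("chunking is balanced, capped and covering", {
  sizes <- function(ch) vapply(ch, function(s) s[2] - s[1] + 1L, integer(1))

  expect_equal(sizes(chunkKymogram(143L, 50L)), c(48L, 48L, 47L))
  expect_equal(sizes(chunkKymogram(50L, 50L)), 50L)
  expect_equal(sizes(chunkKymogram(51L, 50L)), c(26L, 25L))

  set.seed(19)
  for (T in sample(1:500, 20)) {
    ch <- chunkKymogram(T, 50L)
    sz <- sizes(ch)
    expect_true(all(sz <= 50L))
    expect_true(max(sz) - min(sz) <= 1L)
    covered <- unlist(lapply(ch, function(s) s[1]:s[2]))
    expect_identical(covered, 1:T)         # full cover, no overlap, in order
  }
})

test_that("k-means finds the enumerated optimal 2-partition of separated points", {
  set.seed(42)
  pts <- rbind(matrix(rnorm(9, 0, 0.01), 3),
               matrix(rnorm(9, 1, 0.01), 3))
  oracle <- bruteForceTwoPartition(pts)
  fit <- kmeansFit(pts, seed = 1L)
  expect_true(samePartition(fit$labels, oracle$assign))
  expect_equal(fit$inertia, oracle$sse, tolerance = 1e-9)
})

test_that("identical points collapse to a single zero-inertia cluster", {
  pts <- matrix(1, 10, 3)
  fit <- kmeansFit(pts, seed = 3L)
  expect_true(all(fit$labels == 1L))
  expect_equal(fit$inertia, 0)
})

test_that("Lloyd descent: converged inertia never exceeds an early stop's", {
  set.seed(10)
  pts <- matrix(runif(90), 30, 3)
  oneStep <- kmeansFit(pts, seed = 5L, nstart = 1L, maxIter = 1L)
  full <- kmeansFit(pts, seed = 5L, nstart = 1L)
  expect_lte(full$inertia, oneStep$inertia + 1e-12)
})

test_that("our fit agrees with stats::kmeans on well-separated data", {
  set.seed(23)
  pts <- rbind(matrix(rnorm(150, 0, 0.05), ncol = 3),
               matrix(rnorm(150, 1, 0.05), ncol = 3))
  ours <- kmeansFit(pts, seed = 7L)
  ref <- kmeans(pts, centers = 2L, nstart = 5L)
  expect_true(samePartition(ours$labels, as.integer(ref$cluster)))
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("labeled kymograms are deterministic and chunk-order independent", {
  voc <- syntheticVocalization(31L, "decent",
                               vm = VibrationModel(nFrames = 120L))
  k <- movingAverageRows(voc$kymogram)
  chunks <- chunkKymogram(120L, 50L)
  fs <- buildFeatureStack(k, chunks)

  l1 <- labelKymogram(fs, chunks, seed = 11L)
  l2 <- labelKymogram(fs, chunks, seed = 11L)
  expect_identical(l1, l2)

  # permuting chunk processing order must not change the image
  perm <- chunks[c(3, 1, 2)]
  l3 <- matrix(0L, nrow(l1), ncol(l1))
  seeds <- glottikym:::deriveSeeds(11L, length(chunks))
  for (ci in c(3, 1, 2)) {
    cols <- chunks[[ci]][1]:chunks[[ci]][2]
    pts <- cbind(as.vector(featureValues(fs)[, cols, 1]),
                 as.vector(featureValues(fs)[, cols, 2]),
                 as.vector(featureValues(fs)[, cols, 3]))
    l3[, cols] <- matrix(kmeansFit(pts, seed = seeds[ci])$labels,
                         nrow(l1), length(cols))
  }
  expect_identical(l1, l3)

  # a constant kymogram degenerates to single-label chunks
  lc <- labelKymogram(buildFeatureStack(flatKymogram(T = 60L),
                                        chunkKymogram(60L, 50L)),
                      seed = 2L)
  expect_true(all(lc == 1L))
})

test_that("the glottis cluster recovers the true gap mask on a noiseless kymogram", {
  voc <- noiselessVocalization(seed = 17L)
  res <- runKymogram(voc$kymogram,
                     PipelineConfig(masterSeed = 17L, mode = "cluster_only"))
  truthMask <- outer(0:(nrow(maskMatrix(res$mask)) - 1), seq_along(openFlag(voc$truth)),
                     function(r, tcol)
                       r > upperEdge(voc$truth)[tcol] &
                       r < lowerEdge(voc$truth)[tcol])
  got <- maskMatrix(res$mask)
  # agreement away from boundary-blend pixels: erode truth by one row
  interior <- truthMask &
    rbind(truthMask[-1, ], FALSE) & rbind(FALSE, truthMask[-nrow(truthMask), ])
  expect_gte(mean(got[interior]), 0.995)
  # and nothing far outside the gap is captured
  outside <- outer(0:(nrow(got) - 1), seq_along(openFlag(voc$truth)),
                   function(r, tcol)
                     r < upperEdge(voc$truth)[tcol] - 1 |
                     r > lowerEdge(voc$truth)[tcol] + 1)
  expect_false(any(got[outside]))
})
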