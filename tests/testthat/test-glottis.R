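test_that("moment line matches symmetry, point masses and brute-force summation", {
  expect_equal(momentLine(flatKymogram(H = 21L, T = 5L)), 10)

  # white kymogram with one black row at r = 12
  px <- array(255, dim = c(25L, 6L, 3L))
  px[13, , ] <- 0
  expect_equal(momentLine(Kymogram(px)), 12)

  # an all-white kymogram falls back to the geometric mid-row
  expect_equal(momentLine(Kymogram(array(255, dim = c(21L, 4L, 3L)))), 10)

  # brute-force double loop over the inverted green channel
  k <- randomKymogram(H = 23L, T = 17L, seed = 41L)
  G <- pixels(k)[, , 2]
  num <- 0; den <- 0
  for (r in seq_len(23)) for (tcol in seq_len(17)) {
    num <- num + (255 - G[r, tcol]) * (r - 1)
    den <- den + (255 - G[r, tcol])
  }
  expect_equal(momentLine(k), num / den, tolerance = 1e-9)
})

test_that("the band mode names the tissue; the remaining label is the glottis", {
  # 300 band pixels labeled 1 vs 80 labeled 2 -> glottis is 2
  labels <- matrix(1L, 25L, 20L)
  labels[11:14, 1:20] <- 2L                 # 80 pixels of label 2 in band
  expect_equal(identifyGlottisLabel(labels, ml = 12, band = 12L), 2L)

  # single-label chunk returns the absent label (downstream mask empty)
  expect_equal(identifyGlottisLabel(matrix(1L, 25L, 10L), ml = 12), 2L)
  expect_equal(identifyGlottisLabel(matrix(2L, 25L, 10L), ml = 12), 1L)

  # an exact tie is broken by darker mean green
  labels <- matrix(1L, 5L, 4L)
  labels[, 3:4] <- 2L                       # 10 vs 10 within a +/-2 band
  green <- matrix(200, 5L, 4L); green[, 3:4] <- 30
  expect_equal(identifyGlottisLabel(labels, ml = 2, band = 2L,
                                    greenChunk = green), 2L)
  green2 <- matrix(30, 5L, 4L); green2[, 3:4] <- 200
  expect_equal(identifyGlottisLabel(labels, ml = 2, band = 2L,
                                    greenChunk = green2), 1L)
})

test_that("mask growth keeps only seed-connected glottis-labelled pixels", {
  H <- 31L; T <- 20L
  labels <- matrix(1L, H, T)
  labels[14:18, ] <- 2L                     # glottal band through the middle
  labels[2:4, 5:9] <- 2L                    # disconnected bright-patch debris
  chunks <- list(c(1L, T))
  m <- growGlottalMask(labels, 2L, chunks, ml = 15, seedBand = 7L)
  expect_true(all(maskMatrix(m)[14:18, ]))
  expect_false(any(maskMatrix(m)[2:4, ]))  # unreachable from the seed band

  # the mask never leaves the glottis label
  expect_true(all(labels[maskMatrix(m)] == 2L))

  # no glottis label within the seed band -> empty mask
  far <- matrix(1L, H, T); far[1:2, ] <- 2L
  m2 <- growGlottalMask(far, 2L, chunks, ml = 15, seedBand = 7L)
  expect_false(any(maskMatrix(m2)))

  # widening the seed band can only grow the mask (reachability monotone)
  m3 <- growGlottalMask(labels, 2L, chunks, ml = 15, seedBand = 12L)
  expect_true(all(maskMatrix(m3)[maskMatrix(m)]))
})

test_that("8-connectivity links diagonal runs into one component", {
  H <- 20L; T <- 20L
  labels <- matrix(1L, H, T)
  for (i in 1:10) labels[9 + i, i] <- 2L    # a pure diagonal of label 2
  m <- growGlottalMask(labels, 2L, list(c(1L, T)), ml = 10, seedBand = 7L)
  expect_equal(sum(maskMatrix(m)), 10L)     # the whole diagonal is reached
})

test_that("edges sit on pixel boundaries of the masked extent", {
  mask <- matrix(FALSE, 30L, 3L)
  mask[19:21, 1] <- TRUE                    # rows 18..20 0-based
  m <- new("GlottalMask", mask = mask, glottisLabel = 1L,
           chunks = list(c(1L, 3L)))
  e <- edgesFromMask(m)
  expect_equal(upperEdge(e)[1], 17.5)
  expect_equal(lowerEdge(e)[1], 20.5)
  expect_identical(validColumns(e), c(TRUE, FALSE, FALSE))
  expect_true(is.na(upperEdge(e)[2]))
})

test_that("noiseless cluster edges localize the true edges to a pixel", {
  voc <- noiselessVocalization(seed = 7L)
  res <- runKymogram(voc$kymogram,
                     PipelineConfig(masterSeed = 7L, mode = "cluster_only"))
  raw <- edgesFromMask(res$mask)
  vo <- openFlag(voc$truth) & validColumns(raw)
  errUp <- abs(upperEdge(raw)[vo] - upperEdge(voc$truth)[vo])
  # boundary-blend dilation in mostly-closed onset/offset chunks costs ~2%
  # of columns (one tissue pixel with smeared darkness joins the cluster)
  expect_gte(mean(errUp <= 1), 0.97)
  expect_lte(median(errUp), 0.5)
  # per-column Jaccard of the mask against the true gap on open columns
  H <- nrow(maskMatrix(res$mask))
  jacc <- vapply(which(vo), function(tcol) {
    got <- which(maskMatrix(res$mask)[, tcol]) - 1L
    tru <- which((0:(H - 1)) > upperEdge(voc$truth)[tcol] &
                 (0:(H - 1)) < lowerEdge(voc$truth)[tcol]) - 1L
    if (length(tru) == 0L) return(1)
    length(intersect(got, tru)) / length(union(got, tru))
  }, numeric(1))
  expect_gte(median(jacc), 0.9)
})

test_that("edge smoothing fills gaps, preserves smooth traces and degrades gracefully", {
  # an already-smooth sinusoid stays within 0.5 px
  T <- 200L
  up <- 20 - 4 * abs(sin(2 * pi * (1:T) / 40))
  lo <- 20 + 4 * abs(sin(2 * pi * (1:T) / 40))
  sm <- smoothEdges(EdgePair(up, lo), ml = 20, height = 41L)
  expect_lt(max(abs(upperEdge(sm) - up)), 0.5)
  expect_lt(max(abs(lowerEdge(sm) - lo)), 0.5)

  # all-invalid traces collapse to the moment line
  allBad <- EdgePair(rep(NA_real_, 50), rep(NA_real_, 50), rep(FALSE, 50))
  flat <- smoothEdges(allBad, ml = 13.25, height = 41L)
  expect_true(all(upperEdge(flat) == 13.25) && all(lowerEdge(flat) == 13.25))

  # a single valid column yields the tent through it, anchored at the
  # moment line just outside both ends
  one <- EdgePair(c(NA, 10, NA), c(NA, 26, NA), c(FALSE, TRUE, FALSE))
  t1 <- smoothEdges(one, ml = 18, height = 41L)
  expect_equal(upperEdge(t1), c(18 + (10 - 18) / 2, 10, 18 + (10 - 18) / 2))
  expect_equal(lowerEdge(t1), c(22, 26, 22))

  # validity flags pass through; ordering holds everywhere
  expect_identical(validColumns(t1), c(FALSE, TRUE, FALSE))
  expect_true(all(upperEdge(sm) <= lowerEdge(sm)))
})
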