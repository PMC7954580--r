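test_that("zero amplitude gives a fully closed waveform at the midline", {
  vm <- VibrationModel(maxHalfWidth = 0)
  truth <- edgeWaveform(vm)
  expect_false(any(openFlag(truth)))
  expect_true(all(upperEdge(truth) == vm@centerRow))
  expect_true(all(lowerEdge(truth) == vm@centerRow))
})

test_that("a half-closed quotient opens the gap exactly on the positive sinusoid half", {
  # closedQuotient = 0.5 corresponds to the plain rectified sinusoid
  # (threshold s = 0): open exactly where sin(.) > 0. A generic phase keeps
  # samples off the exact threshold (at phase 0 the 20-sample lattice lands
  # on sin = 0 twice per cycle).
  vm <- VibrationModel(closedQuotient = 0.5, onsetFrames = 0L,
                       offsetFrames = 0L, nFrames = 400L, phase = 0.3)
  truth <- edgeWaveform(vm)
  tIdx <- 0:(vm@nFrames - 1)
  s <- sin(2 * pi * vm@f0 * tIdx / vm@fps + 0.3)
  expect_identical(openFlag(truth), s > 1e-9)
  expect_equal(mean(openFlag(truth)), 0.5, tolerance = 0.01)

  # closedQuotient = 0 leaves the gap open for (almost) the whole cycle,
  # closing only where the sampled sinusoid touches its minimum
  vm0 <- VibrationModel(closedQuotient = 0, onsetFrames = 0L,
                        offsetFrames = 0L, nFrames = 400L)
  expect_gte(mean(openFlag(edgeWaveform(vm0))), 0.95)
})

test_that("the numerically solved threshold reproduces the requested closed quotient", {
  # 40 whole cycles at f0/fps = 1/20 -> 800 frames, no envelope; a generic
  # phase avoids the degenerate case where the closure threshold coincides
  # exactly with a lattice value of the sampled sinusoid
  vm <- VibrationModel(f0 = 200, fps = 4000, nFrames = 800L,
                       closedQuotient = 0.3, onsetFrames = 0L,
                       offsetFrames = 0L, phase = 0.3)
  truth <- edgeWaveform(vm)
  measuredClosed <- mean(!openFlag(truth))
  expect_equal(measuredClosed, 0.3, tolerance = 0.01)
})

test_that("noiseless rendering honors levels, closure and blending exactly", {
  voc <- noiselessVocalization()
  px <- pixels(voc$kymogram)
  app <- voc$truth@appearance
  open <- openFlag(voc$truth)

  # a fully closed column is pure tissue
  cl <- which(!open)[1]
  for (ch in 1:3) expect_true(all(px[, cl, ch] == app@tissueLevel[ch]))

  # interior glottal pixels (fully covered) are pure glottis level
  wide <- which(lowerEdge(voc$truth) - upperEdge(voc$truth) > 4)[1]
  rIn <- ceiling(upperEdge(voc$truth)[wide] + 0.5):
    floor(lowerEdge(voc$truth)[wide] - 0.5)
  for (ch in 1:3)
    expect_true(all(px[rIn + 1L, wide, ch] == app@glottisLevel[ch]))

  # boundary pixel blends linearly by coverage
  u <- upperEdge(voc$truth)[wide]
  rb <- floor(u + 0.5)                      # pixel containing the upper edge
  cov <- (rb + 0.5) - u
  expect_equal(px[rb + 1L, wide, 1],
               app@tissueLevel[1] + cov * (app@glottisLevel[1] -
                                             app@tissueLevel[1]),
               tolerance = 1e-9)
})

test_that("rendering is deterministic under a fixed seed", {
  truth <- edgeWaveform(VibrationModel(nFrames = 80L),
                        appearance = appearanceTier("challenging"),
                        seed = 99L)
  k1 <- renderKymogram(truth)
  k2 <- renderKymogram(truth)
  expect_identical(pixels(k1), pixels(k2))
})

test_that("stored truth and rendered image agree (inverted-green column centroids)", {
  voc <- noiselessVocalization()      # flat illumination
  G <- pixels(voc$kymogram)[, , 2]
  rows <- seq_len(nrow(G)) - 1
  for (tcol in which(openFlag(voc$truth))) {
    w <- 255 - G[, tcol]
    w <- w - min(w)                   # remove the uniform tissue pedestal
    centroid <- sum(w * rows) / sum(w)
    mid <- (upperEdge(voc$truth)[tcol] + lowerEdge(voc$truth)[tcol]) / 2
    expect_lt(abs(centroid - mid), 0.51)
  }
})

test_that("frame-stack rendering reproduces the kymogram and its window bookkeeping", {
  vm <- VibrationModel(nFrames = 40L)
  truth <- edgeWaveform(vm, appearance = noiselessAppearance(), seed = 3L)
  rs <- renderFrameStack(truth, frameShape = c(40L, 60L),
                         cropShape = c(9L, 41L), crossSectionRows = 4L)
  expect_true(all(rs$windows$top == rs$windows$top[1]))   # jitter = 0
  kFromStack <- extractKymogram(rs$stack, rs$windows, 4L)
  kDirect <- renderKymogram(truth)
  expect_equal(pixels(kFromStack), pixels(kDirect), tolerance = 1e-12)

  # jittered windows shift registered frame coordinates by exactly the jitter
  rsj <- renderFrameStack(truth, frameShape = c(40L, 60L),
                          cropShape = c(9L, 41L), crossSectionRows = 4L,
                          jitterPx = 2L)
  e <- EdgePair(upperEdge(truth), lowerEdge(truth))
  reg0 <- registerEdges(e, 4L, rs$windows, frameNumbers(rs$stack))
  regJ <- registerEdges(e, 4L, rsj$windows, frameNumbers(rsj$stack))
  jitterLeft <- rsj$windows$left - rs$windows$left
  expect_equal(regJ$frame_x - reg0$frame_x, rep(jitterLeft, 2))
  # and the jittered stack still reproduces the same kymogram content
  kj <- extractKymogram(rsj$stack, rsj$windows, 4L)
  expect_equal(pixels(kj), pixels(kDirect), tolerance = 1e-12)
})
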