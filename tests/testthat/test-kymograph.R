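test_that("kymogram extraction is the cropped-row identity", {
  # constant white stack -> constant white kymogram of shape (width, T)
  white <- array(255, dim = c(20L, 30L, 3L, 4L))
  st <- FrameStack(white)
  windows <- data.frame(frame_number = 0:3, top = 2L, left = 5L,
                        height = 10L, width = 18L)
  k <- extractKymogram(st, windows, 3L)
  expect_equal(dim(pixels(k)), c(18L, 4L, 3L))
  expect_true(all(pixels(k) == 255))

  # a single-frame stack gives a single-column kymogram equal to that row
  set.seed(2)
  fr <- array(runif(20 * 30 * 3, 0, 255), dim = c(20L, 30L, 3L, 1L))
  st1 <- FrameStack(fr)
  k1 <- extractKymogram(st1, windows[1, ], 3L)
  expect_equal(dim(pixels(k1))[2], 1L)
  expect_equal(pixels(k1)[, 1, ], fr[2L + 3L + 1L, 6L:23L, , 1])

  # a frame without a window is an error naming the frame
  expect_error(extractKymogram(st, windows[1:3, ], 3L), "frame 3")
})

test_that("moving average is the centered 5-point mean with reflect padding", {
  # constant image is unchanged
  k <- flatKymogram(values = c(10, 20, 30))
  expect_equal(pixels(movingAverageRows(k)), pixels(k))

  # a single 255 impulse spreads to 255/5 = 51 at its row
  px <- array(0, dim = c(15L, 4L, 3L))
  px[8, , 1] <- 255
  sm <- movingAverageRows(Kymogram(px))
  expect_equal(sm@pixels[8, 1, 1], 51)
  expect_equal(sm@pixels[7, 1, 1], 51)
  expect_equal(sm@pixels[5, 1, 1], 0)

  # even or non-positive windows are rejected
  expect_error(movingAverageRows(k, 4L), "odd")
})

test_that("smoothing twice equals one pass of the self-convolved kernel", {
  k <- randomKymogram(H = 19L, T = 8L, seed = 31L)
  twice <- movingAverageRows(movingAverageRows(k))

  # independent oracle: direct convolution with the 9-point kernel
  # (1/5 kernel convolved with itself), reflect indexing computed by hand
  kern <- convolve(rep(1 / 5, 5), rev(rep(1 / 5, 5)), type = "open")
  H <- 19L
  reflect <- function(i) {
    p <- 2L * (H - 1L)
    j <- ((i - 1L) %% p + p) %% p
    if (j >= H) p - j + 1L else j + 1L
  }
  for (ch in 1:3) for (tcol in 1:8) for (r in c(1L, 2L, 7L, 18L, 19L)) {
    val <- 0
    for (o in -4:4)
      val <- val + kern[o + 5] * pixels(k)[reflect(r + o), tcol, ch]
    expect_equal(pixels(twice)[r, tcol, ch], val, tolerance = 1e-9)
  }
})

test_that("interior smoothing matches a brute-force 5-point mean", {
  k <- randomKymogram(H = 25L, T = 12L, seed = 5L)
  sm <- movingAverageRows(k)
  set.seed(6)
  for (i in 1:25) {
    r <- sample(3:23, 1); tcol <- sample(1:12, 1); ch <- sample(1:3, 1)
    expect_equal(pixels(sm)[r, tcol, ch],
                 mean(pixels(k)[(r - 2):(r + 2), tcol, ch]),
                 tolerance = 1e-9)
  }
})

test_that("Tukey weighting shrinks toward the channel mean as specified", {
  k <- randomKymogram(H = 31L, T = 10L, seed = 13L)
  center <- 15
  w <- tukeyWeight(k, 15L, alpha = 0.5, center = center)

  # the window center row is unchanged (weight 1)
  expect_equal(pixels(w)[center + 1L, , ], pixels(k)[center + 1L, , ])

  # rows outside the span become exactly the channel mean
  for (ch in 1:3) {
    m <- mean(pixels(k)[, , ch])
    expect_equal(pixels(w)[1:7, , ch],
                 array(m, dim = c(7L, 10L)), tolerance = 1e-9)
    expect_equal(pixels(w)[24:31, , ch],
                 array(m, dim = c(8L, 10L)), tolerance = 1e-9)
  }

  # alpha = 0 is a boxcar: inside the span unchanged, outside the mean
  b <- tukeyWeight(k, 15L, alpha = 0, center = center)
  expect_equal(pixels(b)[9:23, , ], pixels(k)[9:23, , ])
  expect_equal(pixels(b)[1, 1, 1], mean(pixels(k)[, , 1]), tolerance = 1e-9)

  # a window longer than the image is rejected
  expect_error(tukeyWeight(flatKymogram(H = 15L), 17L), "height")
})

test_that("extract-smooth-weight preserves shape and the [0, 255] range", {
  voc <- noiselessVocalization(seed = 21L)
  k <- voc$kymogram
  sm <- movingAverageRows(k)
  w <- tukeyWeight(sm, center = momentLine(sm))
  expect_equal(dim(pixels(w)), dim(pixels(k)))
  expect_true(min(pixels(w)) >= 0 && max(pixels(w)) <= 255)
})
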