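test_that("a numbered PNG sequence reads back identically, ordered by frame number", {
  dir <- withr::local_tempdir()
  white <- array(1, dim = c(16L, 16L, 3L))
  # write deliberately unordered names whose embedded integers define order
  for (n in c(3L, 1L, 10L, 2L, 7L))
    png::writePNG(white, file.path(dir, sprintf("img_%d.png", n)))
  st <- readFrameStack(dir)
  expect_equal(dim(frames(st)), c(16L, 16L, 3L, 5L))
  expect_true(all(frames(st) == 255))
  expect_identical(frameNumbers(st), c(1L, 2L, 3L, 7L, 10L))
})

test_that("frameRange keeps exactly the requested original frame numbers", {
  dir <- withr::local_tempdir()
  set.seed(11)
  for (n in 0:9) {
    img <- array(runif(8 * 8 * 3), dim = c(8L, 8L, 3L))
    png::writePNG(img, file.path(dir, sprintf("f%03d.png", n)))
  }
  st <- readFrameStack(dir, frameRange = c(2L, 4L))
  expect_identical(frameNumbers(st), 2:4)
  expect_equal(dim(frames(st))[4], 3L)
})

test_that("a generator-written AVI round-trips pixelwise", {
  truth <- edgeWaveform(VibrationModel(nFrames = 12L), seed = 5L)
  rs <- renderFrameStack(truth, frameShape = c(32L, 56L),
                         cropShape = c(7L, 41L), crossSectionRows = 3L)
  stack <- FrameStack(round(frames(rs$stack)),
                      frameNumbers = frameNumbers(rs$stack), fps = 4000)
  path <- withr::local_tempfile(fileext = ".avi")
  writeFrameStack(stack, path)
  back <- readFrameStack(path)
  expect_equal(frames(back), frames(stack), ignore_attr = TRUE)
  expect_equal(fps(back), 4000)
})

test_that("non-RGB frames are rejected with the offending file named", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "gray_001.png"))
  expect_error(readFrameStack(dir), "gray_001")
})

test_that("crop-window CSV parsing, bounds validation and empty input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_number,top,left,height,width", "10,5,5,20,30"), path)
  w <- readCropWindows(path, frameDim = c(256L, 256L))
  expect_equal(nrow(w), 1L)
  expect_equal(unlist(w[1, ]),
               c(frame_number = 10, top = 5, left = 5, height = 20,
                 width = 30))

  writeLines(c("frame_number,top,left,height,width", "10,250,5,20,30"), path)
  expect_error(readCropWindows(path, frameDim = c(256L, 256L)), "bounds")

  writeLines("frame_number,top,left,height,width", path)
  expect_equal(nrow(readCropWindows(path, frameDim = c(256L, 256L))), 0L)
})

test_that("edge tables round-trip through CSV to 1e-3", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeEdgeTable(emptyEdgeTable(), path)
  expect_equal(length(readLines(path)), 1L)   # header only
  expect_equal(nrow(readEdgeTable(path)), 0L)

  e <- EdgePair(upper = c(17.12345, 16.5), lower = c(20.98765, 21.5),
                valid = c(TRUE, FALSE))
  windows <- data.frame(frame_number = 0:1, top = 10L, left = 20L,
                        height = 11L, width = 41L)
  tab <- registerEdges(e, 7L, windows, 0:1, "voc1")
  writeEdgeTable(tab, path)
  raw <- readLines(path)
  expect_true(any(grepl("false", raw)) && any(grepl("true", raw)))
  back <- readEdgeTable(path)
  expect_equal(back$kymogram_row, tab$kymogram_row, tolerance = 1e-3)
  expect_equal(back$frame_x, tab$frame_x, tolerance = 1e-3)
  expect_identical(back$closed_flag, tab$closed_flag)
  expect_identical(back$frame_number, tab$frame_number)
})
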