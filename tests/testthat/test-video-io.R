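make_test_loop <- function(h = 24, w = 30, n = 5, fps = 25) {
  frames <- lapply(seq_len(n), function(i)
    (make_gradient_frame(h, w) + i * 11) %% 256)
  cine_loop(frames, frame_rate = fps)
}

test_that("cine_loop validates its frames", {
  expect_error(cine_loop(list()), "at least one frame")
  expect_error(cine_loop(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "frame 2")
  expect_error(cine_loop(list(matrix(300, 2, 2))), "\\[0, 255\\]")
  expect_error(cine_loop(list(matrix(0, 2, 2)), frame_rate = -1),
               "positive")
  lp <- make_test_loop()
  expect_equal(dim(lp), c(24, 30, 5))
  expect_length(lp, 5)
})

test_that("DICOM write/read round-trips bit-exactly in every syntax", {
  lp <- make_test_loop()
  for (ts in c("explicit", "implicit", "rle")) {
    path <- tempfile(fileext = ".dcm")
    write_cine(lp, path, transfer_syntax = ts)
    back <- read_cine(path)
    expect_identical(back$frames, lp$frames, label = ts)
    expect_equal(back$frame_rate, 25, tolerance = 1e-9)
    expect_equal(back$source_format, "dicom")
  }
})

test_that("MONOCHROME1 pixel data is inverted on read", {
  lp <- make_test_loop(n = 2)
  path <- tempfile(fileext = ".dcm")
  lvtdm:::write_dicom_cine(lp, path, photometric = "MONOCHROME1")
  back <- read_cine(path)
  expect_identical(back$frames[[1]], 255L - lp$frames[[1]])
  expect_identical(back$frames[[2]], 255L - lp$frames[[2]])
})

test_that("DICOM writing is deterministic byte for byte", {
  lp <- make_test_loop(n = 3)
  p1 <- tempfile(fileext = ".dcm"); p2 <- tempfile(fileext = ".dcm")
  write_cine(lp, p1); write_cine(lp, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("AVI write/read round-trips exactly and recovers the frame rate", {
  lp <- make_test_loop(h = 17, w = 21, n = 4, fps = 30)  # odd stride
  path <- tempfile(fileext = ".avi")
  write_cine(lp, path)
  back <- read_cine(path)
  expect_identical(back$frames, lp$frames)
  expect_equal(back$frame_rate, 30, tolerance = 1e-6)
  # constant frames survive the container untouched
  const <- cine_loop(rep(list(matrix(137, 16, 16)), 3), frame_rate = 10)
  pc <- tempfile(fileext = ".avi")
  write_cine(const, pc)
  expect_identical(read_cine(pc)$frames, const$frames)
})

test_that("PNG sequences round-trip and a single PNG reads as one frame", {
  lp <- make_test_loop(n = 3)
  d <- tempfile()
  write_cine(lp, d, format = "png-sequence")
  back <- read_cine(d)
  expect_identical(back$frames, lp$frames)
  single <- file.path(d, "frame_0001.png")
  one <- read_cine(single)
  expect_length(one, 1)
  expect_identical(one$frames[[1]], lp$frames[[1]])
})

test_that("unsupported or missing inputs are rejected with diagnostics", {
  expect_error(read_cine(tempfile(fileext = ".avi")), "not found")
  p <- tempfile(fileext = ".mp4"); file.create(p)
  expect_error(read_cine(p), "not supported")
  bad <- tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 50)), bad)
  expect_error(read_cine(bad), "DICOM")
  expect_error(write_cine(list(), tempfile(fileext = ".avi")), "cine_loop")
})

test_that("RLE PackBits compression is exact on pathological frames", {
  # long runs, alternating values, and 128-boundary runs
  f1 <- matrix(0L, 20, 20); f1[, 11:20] <- 255L
  f2 <- matrix(c(0L, 255L), 20, 20)
  f3 <- matrix(rep(c(rep(7L, 129), rep(9L, 127)), length.out = 400), 20, 20)
  lp <- cine_loop(list(f1, f2, f3))
  path <- tempfile(fileext = ".dcm")
  write_cine(lp, path, transfer_syntax = "rle")
  expect_identical(read_cine(path)$frames, lp$frames)
})
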