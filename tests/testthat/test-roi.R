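test_that("full-frame rectangle with no feather gives an all-ones mask", {
  m <- build_roi_mask(roi_geometry("rectangle", c(0, 0, 1, 1),
                                   feather_px = 0), 16, 20)
  expect_equal(m, matrix(1, 16, 20))
})

test_that("degenerate geometry yields an all-zero mask with a warning", {
  g <- roi_geometry("ellipse", c(0.5, 0.5, 0, 0), feather_px = 0)
  expect_warning(m <- build_roi_mask(g, 12, 12), "degenerate")
  expect_equal(m, matrix(0, 12, 12))
})

test_that("feathered half-plane mask ramps linearly across the band", {
  # left half of a 32x32 frame, 4-px feather: the ramp runs along x
  g <- roi_geometry("rectangle", c(0, 0, 0.5, 1), feather_px = 4)
  m <- build_roi_mask(g, 32, 32)
  row <- m[16, ]
  expect_true(all(diff(row[1:16]) <= 1e-12))  # non-increasing toward the edge
  expect_equal(row[17:32], rep(0, 16))        # outside is exactly zero
  # inside, the weight is distance-to-boundary / feather, capped at 1:
  # columns 16, 15, 14, 13 sit 1..4 px from the first outside pixel
  expect_equal(row[16:13], c(1, 2, 3, 4) / 4)
  expect_equal(row[1:12], rep(1, 12))
})

test_that("polygon and ellipse rasterization agree with membership", {
  sq <- roi_geometry("polygon", rbind(c(0.25, 0.25), c(0.75, 0.25),
                                      c(0.75, 0.75), c(0.25, 0.75)),
                     feather_px = 0)
  m <- build_roi_mask(sq, 40, 40)
  expect_equal(m[20, 20], 1)
  expect_equal(m[2, 2], 0)
  el <- roi_geometry("ellipse", c(0.5, 0.5, 0.25, 0.25), feather_px = 0)
  me <- build_roi_mask(el, 40, 40)
  expect_equal(me[20, 20], 1)
  expect_equal(me[20, 5], 0)
})

test_that("blend collapses to pure tone mapping under an all-ones mask", {
  f <- make_gradient_frame() / 255
  cfg <- processing_config(tonemap = tonemap_params(A = 0.7),
                           outside_smoothing_sigma = 0)
  ones <- matrix(1, nrow(f), ncol(f))
  got <- apply_lvtdm_frame(f, ones, cfg)
  expect_equal(got, pmin(1.7 * f / (f + 0.7), 1))
})

test_that("blend collapses to the identity under an all-zeros mask", {
  f <- make_gradient_frame() / 255
  cfg <- processing_config(outside_smoothing_sigma = 0)
  zeros <- matrix(0, nrow(f), ncol(f))
  expect_equal(apply_lvtdm_frame(f, zeros, cfg), f)
})

test_that("outside smoothing matches a direct Gaussian convolution", {
  f <- matrix(0, 24, 24); f[12, 12] <- 1
  cfg <- processing_config(outside_smoothing_sigma = 2)
  zeros <- matrix(0, 24, 24)
  got <- apply_lvtdm_frame(f, zeros, cfg)
  expect_equal(got, gaussian_conv_oracle(f, 2), tolerance = 1e-6)
})

test_that("pixels with zero weight are bit-identical to the input", {
  f <- make_gradient_frame(48, 48) / 255
  cfg <- processing_config(roi = roi_geometry("rectangle", c(0, 0, 1, 0.4),
                                              feather_px = 0),
                           outside_smoothing_sigma = 0)
  mask <- build_roi_mask(cfg$roi, 48, 48)
  got <- apply_lvtdm_frame(f, mask, cfg)
  expect_identical(got[mask == 0], f[mask == 0])
  expect_false(all(got[mask == 1] == f[mask == 1]))
})

test_that("the enhancement is not idempotent", {
  f <- make_gradient_frame() / 255
  cfg <- processing_config(tonemap = tonemap_params(A = 0.6),
                           outside_smoothing_sigma = 0)
  ones <- matrix(1, nrow(f), ncol(f))
  once <- apply_lvtdm_frame(f, ones, cfg)
  twice <- apply_lvtdm_frame(once, ones, cfg)
  expect_gt(max(abs(twice - once)), 1e-3)
})

test_that("frame/mask dimension mismatches are rejected", {
  expect_error(apply_lvtdm_frame(matrix(0, 4, 4), matrix(1, 4, 5)),
               "4 x 5")
})

test_that("video processing preserves count and order and checks drift", {
  f1 <- make_gradient_frame() / 255
  f2 <- 1 - f1 / 2
  cfg <- processing_config(outside_smoothing_sigma = 0)
  out <- apply_lvtdm_video(list(f1, f2), cfg)
  expect_length(out, 2)
  mask <- build_roi_mask(cfg$roi, nrow(f1), ncol(f1))
  expect_equal(out[[1]], apply_lvtdm_frame(f1, mask, cfg))
  expect_equal(out[[2]], apply_lvtdm_frame(f2, mask, cfg))
  # identical frames give identical outputs (determinism)
  rep_out <- apply_lvtdm_video(list(f1, f1, f1), cfg)
  expect_identical(rep_out[[1]], rep_out[[3]])
  expect_error(apply_lvtdm_video(list(), cfg), "non-empty")
  expect_error(apply_lvtdm_video(list(f1, matrix(0, 3, 3)), cfg), "frame 2")
})

test_that("configs round-trip through YAML and JSON files", {
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    txt <- list(tonemap = list(A = 0.6, rescale_display = TRUE),
                roi = list(shape = "rectangle", coords = c(0, 0, 1, 0.4),
                           feather_px = 4),
                smoothing = list(sigma_px = 1.5))
    if (ext == "yaml") yaml::write_yaml(txt, path)
    else jsonlite::write_json(txt, path, auto_unbox = TRUE)
    cfg <- read_processing_config(path)
    expect_equal(cfg$tonemap$A, 0.6)
    expect_equal(cfg$roi$feather_px, 4)
    expect_equal(cfg$outside_smoothing_sigma, 1.5)
  }
})
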