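test_that("an empty frame yields no detections", {
  bg <- matrix(200, 50, 50)
  expect_equal(nrow(detect_flies(bg, bg, segmentation_params())), 0)
  # pure noise is below the threshold floor after opening
  noisy <- bg + matrix(rnorm(2500, 0, 3), 50, 50)
  expect_equal(nrow(detect_flies(noisy, bg, segmentation_params())), 0)
})

test_that("a fly-sized ellipse is detected with sub-pixel accuracy", {
  b <- blob_frame(cx = 30, cy = 25, a = 5, b = 2.5)
  det <- detect_flies(b$frame, matrix(200, 60, 60), segmentation_params())
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 30), 1)
  expect_lt(abs(det$y_px - 25), 1)
  expect_true(det$area >= 8 && det$area <= 200)
  expect_true(det$major >= 4 && det$major <= 20)
  expect_true(det$minor >= 3 && det$minor <= 20)
})

test_that("blobs outside the geometry gates are disregarded", {
  bg <- matrix(200, 80, 80)
  p <- segmentation_params(opening_disk_radius = 0)  # isolate the gates
  tiny <- blob_frame(40, 40, 1.1, 1.1, dims = c(80, 80))   # area ~ 5 px^2
  expect_equal(nrow(detect_flies(tiny$frame, bg, p)), 0)
  big <- blob_frame(40, 40, 11, 9, dims = c(80, 80))       # area ~ 310 px^2
  expect_equal(nrow(detect_flies(big$frame, bg, p)), 0)
  elong <- blob_frame(40, 40, 14, 3, dims = c(80, 80))     # major ~ 28 px
  expect_equal(nrow(detect_flies(elong$frame, bg, p)), 0)
})

test_that("geometry gating matches an independent regionprops oracle", {
  set.seed(20)
  bg <- matrix(200, 64, 64)
  p <- segmentation_params(opening_disk_radius = 0,
                           threshold_method = "fixed",
                           threshold_value = 50)
  n_checked <- 0
  for (i in 1:120) {
    a <- runif(1, 1, 13); b <- runif(1, 1, a)
    blob <- blob_frame(32 + runif(1, -3, 3), 32 + runif(1, -3, 3), a, b,
                       dims = c(64, 64))
    if (!any(blob$mask)) next
    o <- oracle_props(blob$mask)
    inside <- o$major >= 4 && o$major <= 20 && o$minor >= 3 &&
      o$minor <= 20 && o$area >= 8 && o$area <= 200
    det <- detect_flies(blob$frame, bg, p)
    expect_equal(nrow(det) == 1, inside,
                 info = sprintf("a=%.2f b=%.2f area=%d maj=%.2f min=%.2f",
                                a, b, o$area, o$major, o$minor))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("intensity scaling recovers an affine distortion exactly", {
  bg <- outer(seq(150, 250, length.out = 40), rep(1, 40))
  calib <- list(c(x0 = 1, x1 = 10, y0 = 1, y1 = 40))
  fr <- 0.5 * bg + 10
  sc <- scale_to_background(fr, bg, calib)
  expect_equal(sc$a, 2, tolerance = 1e-10)
  expect_equal(sc$b, -20, tolerance = 1e-8)
  expect_equal(sc$image, bg, tolerance = 1e-8)
  # identical frame: identity map
  sc0 <- scale_to_background(bg, bg, calib)
  expect_equal(sc0$a, 1, tolerance = 1e-10)
  expect_equal(sc0$b, 0, tolerance = 1e-8)
})

test_that("degenerate calibration regions are errors", {
  bg <- matrix(200, 20, 20)  # constant: nothing to regress on
  fr <- bg + 5
  expect_error(scale_to_background(fr, bg, list(c(x0 = 1, x1 = 5, y0 = 1,
                                                  y1 = 20))),
               "degenerate")
  bg2 <- outer(1:20, rep(1, 20)) * 5 + 100
  expect_error(scale_to_background(fr[1:10, 1:10], bg2,
                                   list(c(x0 = 1, x1 = 5, y0 = 1, y1 = 5))),
               "dimensions")
  expect_error(scale_to_background(fr, bg2,
                                   list(c(x0 = 2, x1 = 2, y0 = 3, y1 = 3))),
               "fewer than 2")
})

test_that("frame/background dimension mismatch is an input error", {
  expect_error(detect_flies(matrix(0, 5, 5), matrix(0, 6, 6),
                            segmentation_params()),
               "dimensions")
})
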