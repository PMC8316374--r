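test_that("a blank frame yields no detections", {
  st <- image_stack(matrix(100, 32, 32), pixel_size_um = 0.1)
  expect_equal(nrow(detect_spots(st, 1)), 0L)
})

test_that("noiseless spots are localized without bias", {
  img <- spot_frame(data.frame(x = 12.30, y = 7.75), sigma = 1.3)
  st <- image_stack(img, pixel_size_um = 0.1)
  d <- detect_spots(st, 1, params = list(expected_sigma_px = 1.3))
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x_px - 12.30), 0.05)
  expect_lt(abs(d$y_px - 7.75), 0.05)
  expect_equal(d$x_um, d$x_px * 0.1)
})

test_that("a close pair is resolved by the two-Gaussian branch", {
  img <- spot_frame(data.frame(x = c(12, 15), y = c(15, 15)), sigma = 1.0)
  st <- image_stack(img, pixel_size_um = 0.1)
  d <- detect_spots(st, 1, params = list(expected_sigma_px = 1.0))
  expect_equal(nrow(d), 2L)
  d <- d[order(d$x_px), ]
  expect_lt(abs(d$x_px[1L] - 12), 0.2)
  expect_lt(abs(d$x_px[2L] - 15), 0.2)
  expect_lt(max(abs(d$y_px - 15)), 0.2)
})

test_that("localization RMSE stays under 0.2 px at peak SNR 10", {
  set.seed(21)
  A <- amplitude_for_snr(10, background = 100)
  errs <- vapply(1:60, function(i) {
    x0 <- 10 + stats::runif(1); y0 <- 10 + stats::runif(1)
    im <- spot_frame(data.frame(x = x0, y = y0), amplitude = A,
                     sigma = 1.3, shape = c(24L, 24L))
    im <- matrix(stats::rpois(length(im), im), 24L, 24L)
    d <- detect_spots(image_stack(im, 0.1), 1,
                      params = list(expected_sigma_px = 1.3))
    if (nrow(d) == 0L) return(NA_real_)
    j <- which.min((d$x_px - x0)^2 + (d$y_px - y0)^2)
    sqrt((d$x_px[j] - x0)^2 + (d$y_px[j] - y0)^2)
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_lt(sqrt(mean(errs^2)), 0.2)
})

test_that("accumulation thresholding is monotone and honors methods", {
  set.seed(8)
  img <- matrix(stats::rpois(64 * 64, 20), 64, 64)
  img[20:25, 20:25] <- 400
  st <- image_stack(img, pixel_size_um = 0.1)
  m90 <- threshold_accumulations(st, 1, "percentile", 90)$masks[[1L]]
  m99 <- threshold_accumulations(st, 1, "percentile", 99)$masks[[1L]]
  expect_true(all(m99 <= m90))  # raising the level never adds pixels
  full <- threshold_accumulations(st, 1, "absolute", 0)$masks[[1L]]
  expect_true(all(full))
  none <- threshold_accumulations(st, 1, "absolute", 1e6)$masks[[1L]]
  expect_false(any(none))
  zero <- image_stack(matrix(0, 8, 8) + 0, pixel_size_um = 0.1)
  expect_error(threshold_accumulations(zero, 1, "otsu"), "degenerate")
  expect_error(threshold_accumulations(st, 1, "percentile", 0), "level")
})

test_that("accumulations are isolated above a reticular background", {
  # network at ~100 counts, two bright accumulations at 400
  sc <- scene_spec(shape_px = c(64L, 64L), channel_names = c("el", "snx19"),
                   particles = list(), seed = 9,
                   background = list(constant = 20, er_amplitude = 80,
                                     er_n_seeds = 15),
                   noise = list(poisson = FALSE, read_sd = 0))
  mv <- render_movie(sc)
  snx <- mv$stack$data[1L, 2L, , ]
  snx[10:13, 10:13] <- 400
  snx[40:43, 50:53] <- 400
  st <- image_stack(snx, pixel_size_um = 0.1)
  mask <- threshold_accumulations(st, 1, "absolute", 200)$masks[[1L]]
  seg <- segment_objects(mask)
  expect_equal(nrow(seg$objects), 2L)
  expect_equal(sort(seg$objects$area_px), c(16L, 16L))
})

test_that("segment_objects uses 8-connectivity and exact areas", {
  expect_equal(nrow(segment_objects(matrix(FALSE, 5, 5))$objects), 0L)
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  seg <- segment_objects(m)
  expect_equal(nrow(seg$objects), 1L)  # diagonal touch = one object
  expect_equal(seg$objects$area_px, 2L)
  scn <- make_pla_scene(data.frame(x_px = c(10, 30), y_px = c(10, 30),
                                   area_px = c(8L, 12L)))
  seg2 <- segment_objects(scn$image > 0)
  expect_equal(sort(seg2$objects$area_px), c(8L, 12L))
})
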