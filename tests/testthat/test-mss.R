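test_that("a stationary track is degenerate with S = 0", {
  tr <- data.frame(frame = 0:49, x_um = 1, y_um = 2)
  m <- compute_mss(tr, dt = 0.1)
  expect_true(m$degenerate)
  expect_equal(m$S, 0)
  expect_equal(m$gamma, rep(0, 7))
  lab <- classify_motion(m, list(S_low = 0.35, S_high = 0.65))
  expect_equal(lab$label, "confined")
})

test_that("ballistic motion gives gamma_nu = nu and S = 1 exactly", {
  v <- 0.5
  tr <- data.frame(frame = 0:99, x_um = (0:99) * v * 0.1, y_um = 0)
  m <- compute_mss(tr, dt = 0.1)
  expect_equal(m$gamma, 0:6, tolerance = 1e-10)
  expect_equal(m$S, 1, tolerance = 1e-10)
  expect_equal(m$r2[3L], 1, tolerance = 1e-10)
  lab <- classify_motion(m, list(S_low = 0.35, S_high = 0.65))
  expect_equal(lab$label, "directed")
})

test_that("Brownian tracks have mean S near 0.5 and D recovered", {
  set.seed(41)
  Ds <- S <- numeric(60)
  for (i in 1:60) {
    tr <- simulate_trajectory(motion_spec("free", D = 0.05, dt = 0.1,
                                          n_frames = 600))$track
    m <- compute_mss(tr, dt = 0.1)
    S[i] <- m$S; Ds[i] <- m$D_est_um2_s
  }
  expect_gt(mean(S), 0.45)
  expect_lt(mean(S), 0.55)
  expect_lt(abs(mean(Ds) - 0.05) / 0.05, 0.15)
})

test_that("S and the label are scale-invariant", {
  set.seed(42)
  tr <- simulate_trajectory(motion_spec("free", D = 0.05, dt = 0.1,
                                        n_frames = 300))$track
  thr <- list(S_low = 0.35, S_high = 0.65)
  m1 <- classify_motion(compute_mss(tr, dt = 0.1), thr)
  tr2 <- tr; tr2$x_um <- tr$x_um * 37; tr2$y_um <- tr$y_um * 37
  m2 <- classify_motion(compute_mss(tr2, dt = 0.1), thr)
  expect_equal(m1$S, m2$S, tolerance = 1e-10)
  expect_equal(m1$label, m2$label)
})

test_that("calibrated thresholds bracket 0.5 and tighten with length", {
  long <- calibrate_mss_thresholds(2000, 0.1, n_sim = 150, seed = 6)
  expect_lt(long$S_low, 0.5)
  expect_gt(long$S_high, 0.5)
  expect_lt(long$S_high - long$S_low, 0.3)
  short <- calibrate_mss_thresholds(100, 0.1, n_sim = 150, seed = 6)
  expect_gt(short$S_high - short$S_low, long$S_high - long$S_low)
  again <- calibrate_mss_thresholds(100, 0.1, n_sim = 150, seed = 6)
  expect_identical(short[c("S_low", "S_high")],
                   again[c("S_low", "S_high")])
  expect_error(calibrate_mss_thresholds(100, 0.1, n_sim = 50), "n_sim")
})

test_that("short or lag-starved tracks are gated to unclassified", {
  tr <- data.frame(frame = 0:9, x_um = stats::rnorm(10), y_um = 0)
  m <- compute_mss(tr, dt = 0.1)
  lab <- classify_motion(m, list(S_low = 0.35, S_high = 0.65),
                         min_track_len = 20)
  expect_equal(lab$label, "unclassified")
})

test_that("motion summaries report proportions and the pooled ratio", {
  labs <- data.frame(label = c(rep("confined", 3), "free", "directed"))
  s <- summarize_motion(labs)
  expect_equal(s$p_free_directed, 0.4)
  expect_equal(s$ratio_fd_confined, 2 / 3)
  expect_equal(s$p_confined + s$p_free + s$p_directed + s$p_unclassified,
               1, tolerance = 1e-9)
  all_conf <- summarize_motion(data.frame(label = rep("confined", 5)))
  expect_equal(all_conf$p_free_directed, 0)
  expect_equal(all_conf$ratio_fd_confined, 0)
  none_conf <- summarize_motion(data.frame(label = c("free", "directed")))
  expect_true(none_conf$ratio_undefined)
  expect_true(is.na(none_conf$ratio_fd_confined))
  expect_error(summarize_motion(list()), "no labeled tracks")
  two <- summarize_motion(data.frame(label = c("free", "confined")),
                          grouping = c("a", "b"))
  expect_equal(nrow(two), 2L)
})

test_that("tracks partition by accumulation overlap", {
  masks <- lapply(1:10, function(t) {
    m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE; m
  })
  tracks <- rbind(
    data.frame(track_id = "in", frame = 0:9, x_px = 5, y_px = 5),
    data.frame(track_id = "out", frame = 0:9, x_px = 15, y_px = 15),
    data.frame(track_id = "mixed", frame = 0:9,
               x_px = c(rep(5, 6), rep(15, 4)), y_px = 5))
  p <- partition_tracks_by_marker(tracks, masks,
                                  min_overlap_fraction = 0.5)
  expect_setequal(p$plus, c("in", "mixed"))
  expect_setequal(p$minus, "out")
  expect_equal(sort(c(p$plus, p$minus)),
               sort(unique(tracks$track_id)))  # exhaustive and disjoint
  bad <- data.frame(track_id = 1, frame = 99, x_px = 1, y_px = 1)
  expect_error(partition_tracks_by_marker(bad, masks), "frames")
})
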