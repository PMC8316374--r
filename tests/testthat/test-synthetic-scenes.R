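test_that("an empty, noiseless scene renders pure background", {
  sc <- scene_spec(shape_px = c(24L, 24L), particles = list(),
                   channel_names = "el",
                   background = list(constant = 50),
                   noise = list(poisson = FALSE, read_sd = 0), seed = 1)
  mv <- render_movie(sc)
  expect_true(all(mv$stack$data == 50))
})

test_that("a static particle renders at its true pixel, deterministically", {
  p <- list(spec = motion_spec("free", D = 0, dt = 0.1, n_frames = 3),
            origin = c(1.23, 0.77), amplitude = 500)
  sc <- scene_spec(shape_px = c(24L, 24L), pixel_size_um = 0.1,
                   channel_names = "el", particles = list(p),
                   background = list(constant = 10),
                   noise = list(poisson = FALSE, read_sd = 0), seed = 2)
  mv <- render_movie(sc)
  for (t in 1:3) {
    fr <- mv$stack$data[t, 1L, , ]
    peak <- which(fr == max(fr), arr.ind = TRUE)
    expect_equal(unname(peak[1L, 1L]) - 1L, round(7.7))   # y = 0.77 um
    expect_equal(unname(peak[1L, 2L]) - 1L, round(12.3))  # x = 1.23 um
  }
  mv2 <- render_movie(sc)
  expect_identical(mv$stack$data, mv2$stack$data)
  # with noise the render is still seed-reproducible
  sc$noise$poisson <- TRUE
  expect_identical(render_movie(sc)$stack$data,
                   render_movie(sc)$stack$data)
})

test_that("a particle leaving the frame is reported by id and frame", {
  p <- list(spec = motion_spec("directed", D = 0, dt = 0.1, n_frames = 100,
                               v = 5), origin = c(1, 1))
  sc <- scene_spec(shape_px = c(24L, 24L), pixel_size_um = 0.1,
                   channel_names = "el", particles = list(p), seed = 3)
  expect_error(render_movie(sc), "particle 1 leaves the frame")
})

test_that("ground truth closes over the contact plan", {
  parts <- lapply(1:2, function(i) {
    list(spec = motion_spec("free", D = 0, dt = 1, n_frames = 10),
         origin = c(i, 1), amplitude = 400)
  })
  plan <- data.frame(particle = 1:2, start_s = 0, end_s = c(4, 9))
  sc <- scene_spec(shape_px = c(30L, 30L), pixel_size_um = 0.1,
                   particles = parts, contact_plan = plan,
                   noise = list(poisson = FALSE, read_sd = 0), seed = 4)
  mv <- render_movie(sc)
  expect_equal(mv$truth$contacts$start_frame, c(0L, 0L))
  expect_equal(mv$truth$contacts$end_frame, c(4L, 9L))
  # accumulation channel is bright at particle 2 after particle 1 stops
  f8 <- mv$stack$data[8L, 2L, , ]
  expect_gt(f8[11L, 21L], 300)  # particle 2 at (2.0, 1.0) um = px (20, 10)
  expect_lt(f8[11L, 11L], 150)  # particle 1 dwell is over
})

test_that("dispersal scenes plant the requested peripheral fraction", {
  disc <- list(center = c(12, 12), radius = 10)
  for (target in c(0, 0.5, 1)) {
    scn <- make_dispersal_scene(disc, target, n_puncta = 200, seed = 5)
    expect_equal(scn$true_fraction, target)
    # brute-force re-count of placements over the shell regions
    shell_at <- scn$shells$labels[cbind(round(scn$puncta$y_px) + 1L,
                                        round(scn$puncta$x_px) + 1L)]
    expect_equal(mean(shell_at >= 3), scn$true_fraction)
  }
  expect_error(make_dispersal_scene(list(center = c(3, 3), radius = 2.5),
                                    0.5, 10, seed = 1),
               "too small")
})

test_that("PLA scenes render exact areas and count with the size filter", {
  expect_equal(make_pla_scene(data.frame(x_px = numeric(0),
                                         y_px = numeric(0),
                                         area_px = integer(0)))$true_count,
               0L)
  iso <- data.frame(x_px = c(10, 30, 50), y_px = c(10, 30, 50),
                    area_px = 8L)
  scn <- make_pla_scene(iso)
  expect_equal(scn$true_count, 3L)
  expect_false(any(scn$dots$touching))
  expect_equal(sum(scn$image > 0), 24L)
  # two touching 8-px dots plus a sub-threshold 4-px dot
  mix <- data.frame(x_px = c(10, 13, 40), y_px = c(10, 10, 40),
                    area_px = c(8L, 8L, 4L))
  scn2 <- make_pla_scene(mix, min_size_px = 5)
  expect_equal(scn2$true_count, 2L)
  expect_true(all(scn2$dots$touching[1:2]))
  expect_error(make_pla_scene(data.frame(x_px = 1, y_px = 1,
                                         area_px = 0L)), "area")
})
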