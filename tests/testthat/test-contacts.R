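abs_params <- list(method = "absolute", level = 100,
                   el_method = "absolute", el_level = 100)

test_that("the 10 s persistence rule counts endpoint frames inclusively", {
  # at 2.4 s/frame: 4 frames = 9.6 s rejected, 5 frames = 12 s accepted
  st <- dwell_stack(data.frame(start_frame = c(0, 0),
                               end_frame = c(3, 4)), n_frames = 10)
  res <- detect_contacts(st, "snx19", "el",
                         params = c(abs_params, min_duration_s = 10))
  expect_equal(res$accepted_count, 1L)
  expect_equal(sort(res$events$duration_s), c(9.6, 12.0))
  expect_equal(res$events$accepted, res$events$duration_s >= 10)
})

test_that("no accumulations means no events", {
  arr <- array(0, dim = c(5, 2, 16, 16))
  arr[, 1, 4:6, 4:6] <- 400  # EL present, accumulation channel dark
  st <- image_stack(arr, 0.1, 2.4, c("el", "snx19"))
  res <- detect_contacts(st, "snx19", "el", params = abs_params)
  expect_equal(res$accepted_count, 0L)
  expect_equal(nrow(res$events), 0L)
})

test_that("accepted contacts match a rendered dwell plan exactly", {
  parts <- lapply(1:10, function(i) {
    list(spec = motion_spec("confined", D = 0.01, dt = 2.4, n_frames = 25,
                            R_c = 0.2),
         origin = c(1.5 + ((i - 1) %% 5) * 2.2,
                    1.5 + ((i - 1) %/% 5) * 5), amplitude = 400)
  })
  # six dwells >= 10 s (>= 5 frames), four below
  plan <- data.frame(particle = 1:10, start_s = 0,
                     end_s = c(55, 40, 31, 26, 21, 12, 9.4, 7, 4.6, 2.2))
  sc <- scene_spec(shape_px = c(100L, 120L), pixel_size_um = 0.1,
                   particles = parts, contact_plan = plan,
                   background = list(constant = 50, er_amplitude = 100,
                                     er_n_seeds = 25),
                   noise = list(poisson = FALSE, read_sd = 0), seed = 13)
  mv <- render_movie(sc)
  res <- detect_contacts(mv$stack, "snx19", "el",
                         params = list(method = "percentile", level = 99,
                                       min_duration_s = 10))
  true_dwell <- (mv$truth$contacts$end_frame -
                   mv$truth$contacts$start_frame + 1L) * 2.4
  expect_equal(res$accepted_count, sum(true_dwell >= 10))
  expect_true(all(res$events$duration_s[res$events$accepted] >= 10))
})

test_that("accepted count is monotone in the persistence threshold", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 8
    starts <- sample(0:10, n, replace = TRUE)
    lens <- sample(1:12, n, replace = TRUE)
    st <- dwell_stack(data.frame(start_frame = starts,
                                 end_frame = pmin(starts + lens - 1L, 23L)),
                      n_frames = 24)
    counts <- vapply(c(2.4, 7.2, 12, 24, 48), function(md) {
      suppressWarnings(detect_contacts(
        st, "snx19", "el",
        params = c(abs_params, min_duration_s = md)))$accepted_count
    }, integer(1))
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("z-stack contacts require two consecutive slices", {
  mk <- function(slices, nz = 6) {
    arr <- array(0, dim = c(nz, 2, 16, 16))
    arr[, 1, 4:6, 4:6] <- 400
    arr[slices, 2, 4:6, 4:6] <- 400
    image_stack(arr, 0.1, 1, c("el", "snx19"))
  }
  one <- detect_contacts_zstack(mk(3), params = abs_params)
  expect_equal(one$count, 0L)
  two <- detect_contacts_zstack(mk(3:4), params = abs_params)
  expect_equal(two$count, 1L)
  single <- image_stack(array(1, dim = c(1, 2, 8, 8)), 0.1, 0,
                        c("el", "snx19"))
  expect_error(detect_contacts_zstack(single, params = abs_params),
               "detect_contacts")
})

test_that("five planted two-slice contacts are counted as five", {
  arr <- array(0, dim = c(8, 2, 40, 40))
  for (i in 1:5) {
    xs <- (3 + (i - 1) * 7):(5 + (i - 1) * 7)
    z <- i:(i + 1)
    arr[, 1, 4:6, xs] <- 400
    arr[z, 2, 4:6, xs] <- 400
  }
  st <- image_stack(arr, 0.1, 1, c("el", "snx19"))
  res <- detect_contacts_zstack(st, params = abs_params)
  expect_equal(res$count, 5L)
})

test_that("ER association percent is frames-present over frames-followed", {
  mask <- matrix(FALSE, 10, 10); mask[4:6, 4:6] <- TRUE
  masks <- rep(list(mask), 10)
  er_on <- matrix(0, 10, 10); er_on[5, 5] <- 50
  er_off <- matrix(0, 10, 10)
  for (k in c(0, 8, 10)) {
    frames <- c(rep(list(er_on), k), rep(list(er_off), 10 - k))
    s <- score_er_association(masks, frames, er_threshold = 10)
    expect_equal(s$percent, 10 * k)
    expect_equal(s$n_frames_with_er, k)
  }
  # invariant to intensity rescaling above threshold
  frames <- c(rep(list(er_on * 100), 8), rep(list(er_off), 2))
  expect_equal(score_er_association(masks, frames, 10)$percent, 80)
  expect_error(score_er_association(masks[1:9], rep(list(er_on), 10)),
               "same length")
})

test_that("marker overlap subsets reproduce a planted composition", {
  m <- function(rows, cols) {
    mm <- matrix(FALSE, 40, 40); mm[rows, cols] <- TRUE; mm
  }
  masks <- list(LAMP1 = m(1:40, 1:20), RAB5A = m(1:20, 1:40),
                Dextran = m(10:30, 10:30))
  puncta <- data.frame(x_px = c(15, 15, 35, 35, 25),
                       y_px = c(15, 35, 15, 35, 25))
  # planted subsets: all three; LAMP1 only; RAB5A only; none; Dextran only
  res <- classify_marker_overlap(puncta, masks)
  expect_equal(res$per_punctum$subset,
               c("LAMP1+RAB5A+Dextran", "LAMP1", "RAB5A", "none",
                 "Dextran"))
  expect_equal(sum(res$table$percent), 100)
  expect_equal(sum(res$table$count), nrow(puncta))
  empty <- classify_marker_overlap(data.frame(x_px = numeric(0),
                                              y_px = numeric(0)), masks)
  expect_equal(nrow(empty$table), 0L)
})
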