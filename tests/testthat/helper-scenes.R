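# Shared fixture builders. Everything is generated in code; no files.

# Render a still frame with integrated-Gaussian spots at given 0-based
# positions over a constant background.
spot_frame <- function(positions, amplitude = 300, sigma = 1.3,
                       shape = c(32L, 32L), background = 100) {
  img <- matrix(background, shape[1L], shape[2L])
  for (i in seq_len(nrow(positions))) {
    img <- eltrack:::.add_spot(img, positions$x[i], positions$y[i],
                               amplitude, sigma)
  }
  img
}

# Two-channel block stack implementing a dwell plan: each "particle" is a
# static 3x3 block at 400 counts; the EL channel shows it in every frame,
# the accumulation channel only during its dwell interval. Frames and
# intervals are 0-based and inclusive.
dwell_stack <- function(dwells, n_frames, frame_interval_s = 2.4,
                        shape = c(48L, 48L)) {
  n <- nrow(dwells)
  arr <- array(0, dim = c(n_frames, 2L, shape[1L], shape[2L]))
  for (i in seq_len(n)) {
    cx <- 4L + ((i - 1L) %% 6L) * 7L
    cy <- 4L + ((i - 1L) %/% 6L) * 7L
    ys <- (cy - 1L):(cy + 1L); xs <- (cx - 1L):(cx + 1L)
    arr[, 1L, ys, xs] <- 400
    fr <- (dwells$start_frame[i]:dwells$end_frame[i]) + 1L
    arr[fr, 2L, ys, xs] <- 400
  }
  image_stack(arr, pixel_size_um = 0.1,
              frame_interval_s = frame_interval_s,
              channel_names = c("el", "snx19"))
}

# Monte-Carlo MSS slope for a batch of simulated tracks.
sim_S <- function(model, n_rep, n_frames, dt = 0.1, ...) {
  vapply(seq_len(n_rep), function(i) {
    tr <- simulate_trajectory(motion_spec(model, dt = dt,
                                          n_frames = n_frames, ...))$track
    compute_mss(tr, dt = dt)$S
  }, numeric(1))
}
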