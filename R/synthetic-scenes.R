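#' Specify a synthetic two-channel time-lapse scene
#'
#' Bundles everything [render_movie()] needs: frame geometry, optics,
#' particle motion models, a contact plan (which particles carry a
#' co-moving accumulation in the second channel and when), a background
#' model and a noise model. The default acquisition mirrors a typical
#' endolysosome motility recording: 0.1 um pixels, 10 fps.
#'
#' @param shape_px Frame shape `c(height, width)` in px.
#' @param pixel_size_um Pixel size in um.
#' @param psf_sigma_px Gaussian PSF sigma in px (> 0).
#' @param channel_names Channel names; the first channel receives the
#'   particles, the channel named by `accumulation_channel` receives
#'   contact-plan accumulations and the reticular background.
#' @param particles List of particle descriptors, each a list with
#'   `spec` (a [motion_spec()]), `origin` (start position, um) and
#'   optionally `amplitude` (approximate peak intensity, default 300).
#' @param contact_plan Optional data.frame with columns `particle`,
#'   `start_s`, `end_s`: dwell intervals during which the particle also
#'   carries an accumulation in the accumulation channel.
#' @param accumulation_channel Name of the accumulation channel (default
#'   the second channel, if present).
#' @param background List: `constant` offset, `er_amplitude` of the
#'   reticular network (0 disables), `er_n_seeds` Voronoi seed count,
#'   `er_width_px` ridge width.
#' @param noise List: `poisson` (logical; shot noise) and `read_sd`
#'   (Gaussian read noise sd, counts).
#' @param seed Integer seed; fixes the whole rendered output.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape_px = c(128L, 128L), pixel_size_um = 0.1,
                       psf_sigma_px = 1.3,
                       channel_names = c("el", "snx19"),
                       particles = list(), contact_plan = NULL,
                       accumulation_channel = NULL,
                       background = list(constant = 100, er_amplitude = 0,
                                         er_n_seeds = 40, er_width_px = 1),
                       noise = list(poisson = TRUE, read_sd = 0),
                       seed = 1L) {
  if (psf_sigma_px <= 0) stop("'psf_sigma_px' must be > 0")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be > 0")
  bg <- list(constant = 100, er_amplitude = 0, er_n_seeds = 40,
             er_width_px = 1)
  bg[names(background)] <- background
  nz <- list(poisson = TRUE, read_sd = 0)
  nz[names(noise)] <- noise
  if (is.null(accumulation_channel) && length(channel_names) >= 2L)
    accumulation_channel <- channel_names[2L]
  if (!is.null(contact_plan)) {
    stopifnot(all(c("particle", "start_s", "end_s") %in% names(contact_plan)))
  }
  structure(list(shape_px = as.integer(shape_px),
                 pixel_size_um = pixel_size_um,
                 psf_sigma_px = psf_sigma_px,
                 channel_names = channel_names,
                 particles = particles, contact_plan = contact_plan,
                 accumulation_channel = accumulation_channel,
                 background = bg, noise = nz, seed = as.integer(seed)),
            class = "scene_spec")
}

# Add one integrated-Gaussian spot to an image (in place, returned).
# x/y are 0-based pixel coordinates of the true center; the intensity of
# each pixel is the PSF integrated over the pixel area (error-function
# model), so sub-pixel localization on rendered spots is unbiased.
.add_spot <- function(img, x, y, amplitude, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  x0 <- max(0L, floor(x) - r); x1 <- min(w - 1L, ceiling(x) + r)
  y0 <- max(0L, floor(y) - r); y1 <- min(h - 1L, ceiling(y) + r)
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- stats::pnorm((xs + 0.5 - x) / sigma) -
        stats::pnorm((xs - 0.5 - x) / sigma)
  dy <- stats::pnorm((ys + 0.5 - y) / sigma) -
        stats::pnorm((ys - 0.5 - y) / sigma)
  flux <- amplitude * 2 * pi * sigma^2
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + flux * outer(dy, dx)
  img
}

# Reticular (ER-like) background: ridges of a random Voronoi tessellation.
# For each pixel the two smallest distances d1 <= d2 to the seed set are
# tracked; the Voronoi edge set is exactly {d1 = d2}, rendered with a
# Gaussian profile of width 'width' px and blurred by the PSF.
.er_network <- function(shape, n_seeds, amplitude, width, psf_sigma) {
  h <- shape[1L]; w <- shape[2L]
  sx <- stats::runif(n_seeds, 0, w - 1)
  sy <- stats::runif(n_seeds, 0, h - 1)
  px <- rep(0:(w - 1L), each = h)
  py <- rep(0:(h - 1L), times = w)
  d1 <- rep(Inf, h * w); d2 <- rep(Inf, h * w)
  for (i in seq_len(n_seeds)) {
    d <- sqrt((px - sx[i])^2 + (py - sy[i])^2)
    closer <- d < d1
    d2 <- ifelse(closer, d1, pmin(d2, d))
    d1 <- ifelse(closer, d, d1)
  }
  img <- matrix(amplitude * exp(-((d2 - d1)^2) / (2 * width^2)),
                nrow = h, ncol = w)
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = psf_sigma))
}

#' Render a synthetic movie with ground truth
#'
#' Simulates every particle's trajectory, renders each frame as a sum of
#' integrated 2-D Gaussian spots over the background, adds contact-plan
#' accumulations to the accumulation channel during their dwell
#' intervals, applies shot and read noise last, and returns the stack
#' together with a full ground-truth record. Rendering is byte-identical
#' under a fixed scene seed.
#'
#' @param scene A [scene_spec()].
#' @return A list with
#'   \describe{
#'     \item{stack}{an [image_stack()] (integer counts).}
#'     \item{truth}{a list: `positions` (data.frame particle, frame,
#'       x_um, y_um, x_px, y_px - true, noise-free), `labels`
#'       (particle, label), `contacts` (the contact plan with frame
#'       bounds attached), `seed`.}
#'   }
#' @export
render_movie <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  set.seed(scene$seed)
  h <- scene$shape_px[1L]; w <- scene$shape_px[2L]
  np <- length(scene$particles)
  n_frames <- if (np > 0L) scene$particles[[1L]]$spec$n_frames else 1L
  dt <- if (np > 0L) scene$particles[[1L]]$spec$dt else 1
  nc <- length(scene$channel_names)

  # simulate all particles first (shares the scene RNG stream); a
  # particle may instead carry a precomputed 'track' (true positions)
  pos <- vector("list", np)
  labels <- character(np)
  for (i in seq_len(np)) {
    p <- scene$particles[[i]]
    if (p$spec$n_frames != n_frames || p$spec$dt != dt)
      stop("all particles must share n_frames and dt")
    if (!is.null(p$track)) {
      tr <- list(track = p$track, label = p$spec$model)
    } else {
      tr <- simulate_trajectory(p$spec, origin = p$origin)
    }
    pos[[i]] <- tr$track
    labels[i] <- tr$label
    xp <- tr$track$x_true_um / scene$pixel_size_um
    yp <- tr$track$y_true_um / scene$pixel_size_um
    bad <- which(xp < 0 | xp > w - 1 | yp < 0 | yp > h - 1)
    if (length(bad) > 0L)
      stop("particle ", i, " leaves the frame at frame ", bad[1L] - 1L)
  }

  # static backgrounds per channel
  acc_ci <- if (!is.null(scene$accumulation_channel))
    match(scene$accumulation_channel, scene$channel_names) else NA_integer_
  bg <- vector("list", nc)
  for (c in seq_len(nc)) {
    b <- matrix(scene$background$constant, h, w)
    if (!is.na(acc_ci) && c == acc_ci && scene$background$er_amplitude > 0) {
      b <- b + .er_network(c(h, w), scene$background$er_n_seeds,
                           scene$background$er_amplitude,
                           scene$background$er_width_px,
                           scene$psf_sigma_px)
    }
    bg[[c]] <- b
  }

  # contact plan -> frame intervals
  plan <- scene$contact_plan
  if (!is.null(plan) && nrow(plan) > 0L) {
    plan$start_frame <- pmax(0L, as.integer(round(plan$start_s / dt)))
    plan$end_frame <- pmin(n_frames - 1L, as.integer(round(plan$end_s / dt)))
    if (any(plan$start_frame > plan$end_frame))
      stop("contact plan interval outside the movie duration")
  }

  arr <- array(0, dim = c(n_frames, nc, h, w))
  for (t in seq_len(n_frames)) {
    frames <- lapply(bg, identity)
    for (i in seq_len(np)) {
      p <- scene$particles[[i]]
      amp <- if (!is.null(p$amplitude)) p$amplitude else 300
      xp <- pos[[i]]$x_true_um[t] / scene$pixel_size_um
      yp <- pos[[i]]$y_true_um[t] / scene$pixel_size_um
      frames[[1L]] <- .add_spot(frames[[1L]], xp, yp, amp,
                                scene$psf_sigma_px)
      if (!is.null(plan) && !is.na(acc_ci)) {
        rows <- plan$particle == i & plan$start_frame <= t - 1L &
          plan$end_frame >= t - 1L
        if (any(rows)) {
          frames[[acc_ci]] <- .add_spot(frames[[acc_ci]], xp, yp, amp,
                                        scene$psf_sigma_px)
        }
      }
    }
    for (c in seq_len(nc)) {
      f <- frames[[c]]
      if (isTRUE(scene$noise$poisson)) {
        f <- matrix(stats::rpois(length(f), lambda = f), h, w)
      }
      if (scene$noise$read_sd > 0) {
        f <- f + matrix(stats::rnorm(length(f), sd = scene$noise$read_sd),
                        h, w)
      }
      arr[t, c, , ] <- pmax(round(f), 0)
    }
  }

  positions <- do.call(rbind, lapply(seq_len(np), function(i) {
    data.frame(particle = i, frame = pos[[i]]$frame,
               x_um = pos[[i]]$x_true_um, y_um = pos[[i]]$y_true_um,
               x_px = pos[[i]]$x_true_um / scene$pixel_size_um,
               y_px = pos[[i]]$y_true_um / scene$pixel_size_um)
  }))
  stack <- image_stack(arr, pixel_size_um = scene$pixel_size_um,
                       frame_interval_s = if (n_frames > 1L) dt else 0,
                       channel_names = scene$channel_names)
  list(stack = stack,
       truth = list(positions = positions,
                    labels = data.frame(particle = seq_len(np),
                                        label = labels),
                    contacts = plan, seed = scene$seed))
}

#' Standard three-class motility scene
#'
#' Builds the reference synthetic movie used to validate the whole
#' imaging pipeline: equal numbers of confined, free and directed
#' particles in one field of view, imaged at 10 fps with shot noise at a
#' chosen peak SNR over a constant background. Particles are laid out on
#' concentric rings (confined outermost - they stay put; directed
#' innermost - they travel farthest), and each trajectory is
#' rejection-sampled until it stays inside the frame for the whole
#' recording, so rendering never aborts.
#'
#' @param n_per_class Particles per motion class (default 10).
#' @param n_frames Frames (default 600, i.e. 1 min at 10 fps).
#' @param dt Frame interval in s (default 0.1).
#' @param snr Peak signal-to-noise ratio (default 10).
#' @param shape_px Frame shape (default 256 x 256).
#' @param pixel_size_um,psf_sigma_px Optics (defaults 0.1, 1.3).
#' @param seed Integer seed.
#' @param confined,free,directed Named lists of per-class motion
#'   parameters (`D`, plus `R_c` or `v`).
#' @return A [scene_spec()] whose particles carry precomputed tracks.
#' @export
three_class_scene <- function(n_per_class = 10, n_frames = 600, dt = 0.1,
                              snr = 10, shape_px = c(256L, 256L),
                              pixel_size_um = 0.1, psf_sigma_px = 1.3,
                              seed = 1,
                              confined = list(D = 0.05, R_c = 0.25),
                              free = list(D = 0.02),
                              directed = list(D = 0.005, v = 0.13)) {
  set.seed(seed)
  fw <- shape_px[2L] * pixel_size_um
  fh <- shape_px[1L] * pixel_size_um
  ctr <- c(fw, fh) / 2
  ring <- function(radius, n, phase) {
    th <- 2 * pi * (0:(n - 1L)) / n + phase
    cbind(ctr[1L] + radius * cos(th), ctr[2L] + radius * sin(th))
  }
  r_max <- min(ctr) # keep rings inside even for non-square frames
  origins <- rbind(ring(0.86 * r_max, n_per_class, 0),
                   ring(0.55 * r_max, n_per_class, pi / n_per_class),
                   ring(0.16 * r_max, n_per_class, 0))
  specs <- c(
    replicate(n_per_class,
              motion_spec("confined", D = confined$D, dt = dt,
                          n_frames = n_frames, R_c = confined$R_c),
              simplify = FALSE),
    replicate(n_per_class,
              motion_spec("free", D = free$D, dt = dt,
                          n_frames = n_frames), simplify = FALSE),
    replicate(n_per_class,
              motion_spec("directed", D = directed$D, dt = dt,
                          n_frames = n_frames, v = directed$v),
              simplify = FALSE))
  margin <- 2 * pixel_size_um
  amp <- amplitude_for_snr(snr, background = 100)
  particles <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    for (try in 1:50) {
      tr <- simulate_trajectory(specs[[i]], origin = origins[i, ])$track
      ok <- all(tr$x_true_um >= margin & tr$x_true_um <= fw - margin &
                tr$y_true_um >= margin & tr$y_true_um <= fh - margin)
      if (ok) break
    }
    if (!ok) stop("could not keep particle ", i, " inside the frame")
    particles[[i]] <- list(spec = specs[[i]], origin = origins[i, ],
                           track = tr, amplitude = amp)
  }
  scene_spec(shape_px = shape_px, pixel_size_um = pixel_size_um,
             psf_sigma_px = psf_sigma_px, channel_names = "el",
             particles = particles, accumulation_channel = NULL,
             background = list(constant = 100, er_amplitude = 0),
             noise = list(poisson = TRUE, read_sd = 0), seed = seed)
}

#' Amplitude needed for a target peak signal-to-noise ratio
#'
#' For a rendered spot of peak intensity A over background b with shot
#' noise and Gaussian read noise sd r, the peak SNR is
#' A / sqrt(A + b + r^2). Solves for A.
#'
#' @param snr Target peak SNR.
#' @param background Constant background (counts).
#' @param read_sd Read noise sd (counts).
#' @return The amplitude (counts).
#' @export
amplitude_for_snr <- function(snr, background = 100, read_sd = 0) {
  v <- background + read_sd^2
  (snr^2 + snr * sqrt(snr^2 + 4 * v)) / 2
}
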