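#' Specify a stochastic motion model for a simulated endolysosome
#'
#' Describes one particle's kinetics for [simulate_trajectory()]. Three
#' motion classes are supported, mirroring the categories used to describe
#' endolysosome behaviour in live cells: `"confined"` (Brownian motion
#' reflected at the boundary of a disc), `"free"` (unrestricted Brownian
#' motion) and `"directed"` (Brownian motion plus a constant-velocity drift
#' in a fixed, randomly drawn direction).
#'
#' @param model One of `"confined"`, `"free"`, `"directed"`.
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @param dt Frame interval in seconds (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param v Drift speed in um/s; required (> 0) when `model = "directed"`.
#' @param R_c Confinement radius in um; required (> 0) when
#'   `model = "confined"`.
#' @param loc_noise_sigma Localization noise standard deviation in um,
#'   added independently per frame and axis to the observed positions.
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(model = c("free", "confined", "directed"),
                        D, dt, n_frames,
                        v = NULL, R_c = NULL, loc_noise_sigma = 0) {
  model <- match.arg(model)
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0)
    stop("invalid motion spec: 'D' must be a single number >= 0")
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("invalid motion spec: 'dt' must be a single number > 0")
  if (!is.numeric(n_frames) || length(n_frames) != 1L || is.na(n_frames) ||
      n_frames < 2 || n_frames != round(n_frames))
    stop("invalid motion spec: 'n_frames' must be an integer >= 2")
  if (!is.numeric(loc_noise_sigma) || length(loc_noise_sigma) != 1L ||
      is.na(loc_noise_sigma) || loc_noise_sigma < 0)
    stop("invalid motion spec: 'loc_noise_sigma' must be >= 0")
  if (model == "directed") {
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("invalid motion spec: 'v' must be > 0 for directed motion")
  } else {
    v <- NULL
  }
  if (model == "confined") {
    if (is.null(R_c) || !is.numeric(R_c) || length(R_c) != 1L ||
        is.na(R_c) || R_c <= 0)
      stop("invalid motion spec: 'R_c' must be > 0 for confined motion")
  } else {
    R_c <- NULL
  }
  structure(
    list(model = model, D = D, dt = dt, n_frames = as.integer(n_frames),
         v = v, R_c = R_c, loc_noise_sigma = loc_noise_sigma),
    class = "motion_spec")
}

# Reflect radial excursions beyond R_c back into the disc. A point at
# radius r > R_c maps to radius 2*R_c - r (mirror at the circular wall);
# repeated until inside, which terminates because each pass shrinks the
# excess. Steps are assumed small relative to R_c, as in any sensible
# discretisation of reflected Brownian motion.
.reflect_disc <- function(xy, R_c) {
  r <- sqrt(sum(xy^2))
  while (r > R_c) {
    xy <- xy * ((2 * R_c - r) / r)
    r <- abs(2 * R_c - r)
  }
  xy
}

#' Simulate one trajectory under a motion model
#'
#' Generates a single 2-D trajectory according to a [motion_spec()].
#' Brownian increments per axis are N(0, 2*D*dt); directed motion adds a
#' constant drift `v*dt` along a direction drawn uniformly once per track;
#' confined motion reflects the Brownian path at the boundary of a disc of
#' radius `R_c` centred at the start position. Localization noise
#' N(0, loc_noise_sigma^2) is added per frame and axis after reflection, so
#' observed positions of a confined particle may slightly exceed `R_c`
#' while the true positions never do.
#'
#' @param spec A [motion_spec()].
#' @param seed Optional integer seed; fixing it makes the output
#'   reproducible.
#' @param origin Numeric length-2 start position in um (default `c(0, 0)`).
#' @return A list with elements
#'   \describe{
#'     \item{track}{data.frame with columns `frame` (0-based), `t_s`,
#'       `x_um`, `y_um` (observed, i.e. noise-added, positions) and
#'       `x_true_um`, `y_true_um` (noise-free positions).}
#'     \item{label}{the true motion class, equal to `spec$model`.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
simulate_trajectory <- function(spec, seed = NULL, origin = c(0, 0)) {
  if (!inherits(spec, "motion_spec")) stop("'spec' must be a motion_spec")
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_frames
  step_sd <- sqrt(2 * spec$D * spec$dt)
  inc <- matrix(stats::rnorm(2 * (n - 1L), sd = step_sd), ncol = 2L)
  pos <- matrix(0, nrow = n, ncol = 2L)
  if (spec$model == "free") {
    pos[-1L, ] <- apply(inc, 2L, cumsum)
  } else if (spec$model == "directed") {
    theta <- stats::runif(1L, 0, 2 * pi)
    drift <- spec$v * spec$dt * c(cos(theta), sin(theta))
    inc <- sweep(inc, 2L, drift, "+")
    pos[-1L, ] <- apply(inc, 2L, cumsum)
  } else { # confined: reflected Brownian in a disc centred at the origin
    for (i in 2:n) {
      pos[i, ] <- .reflect_disc(pos[i - 1L, ] + inc[i - 1L, ], spec$R_c)
    }
  }
  pos <- sweep(pos, 2L, origin, "+")
  obs <- pos
  if (spec$loc_noise_sigma > 0) {
    obs <- obs + matrix(stats::rnorm(2 * n, sd = spec$loc_noise_sigma),
                        ncol = 2L)
  }
  track <- data.frame(
    frame = 0:(n - 1L),
    t_s = (0:(n - 1L)) * spec$dt,
    x_um = obs[, 1L], y_um = obs[, 2L],
    x_true_um = pos[, 1L], y_true_um = pos[, 2L])
  list(track = track, label = spec$model, spec = spec)
}
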