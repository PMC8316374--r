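#' Moment scaling spectrum (MSS) analysis of a trajectory
#'
#' Computes displacement moments \eqn{\mu_\nu(\delta)} of orders
#' \eqn{\nu = 0..6} over time lags \eqn{\delta = k \cdot dt}, their scaling
#' exponents \eqn{\gamma_\nu} (slope of \eqn{\log \mu_\nu} versus
#' \eqn{\log \delta}), and the MSS slope \eqn{S} (slope of
#' \eqn{\gamma_\nu} versus \eqn{\nu}, anchored through
#' \eqn{(\nu = 0, \gamma = 0)} since \eqn{\mu_0 \equiv 1}). For Brownian
#' motion the expectation is \eqn{\gamma_\nu = \nu/2} and \eqn{S = 0.5};
#' for ballistic motion \eqn{\gamma_\nu = \nu} and \eqn{S = 1}; a stalled
#' particle gives \eqn{S = 0}.
#'
#' @param track A data.frame with columns `x_um`, `y_um` and (optionally)
#'   `frame`; frames must be strictly increasing. Missing frames (gaps from
#'   gap-closed linking) are handled by pairing positions at the requested
#'   frame lag only where both endpoints exist.
#' @param dt Frame interval in seconds.
#' @param max_lag_fraction Largest lag used, as a fraction of the track's
#'   frame span (default 0.25; long lags have few pairs and high variance).
#' @param track_id Identifier copied into the result.
#' @return An object of class `mss_result`: a list with `track_id`,
#'   `n_frames`, `nu`, `lags_s`, `moments` (lag x order matrix), `gamma`,
#'   `r2` (per-order coefficient of determination of the log-log fit),
#'   `S`, `D_est_um2_s` (from the order-2 intercept, \eqn{\mu_2 = 4D\delta}
#'   for Brownian motion), `n_lags_used`, `degenerate` (TRUE for a
#'   perfectly stationary track, reported with `S = 0`), and `label`
#'   (`NA` until [classify_motion()] is applied).
#' @export
compute_mss <- function(track, dt, max_lag_fraction = 0.25, track_id = NA) {
  if (!is.data.frame(track) || !all(c("x_um", "y_um") %in% names(track)))
    stop("'track' must be a data.frame with columns x_um, y_um")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single number > 0")
  frames <- if ("frame" %in% names(track)) as.integer(track$frame)
            else seq_len(nrow(track)) - 1L
  if (any(diff(frames) <= 0L)) stop("track frames must be strictly increasing")
  nu <- 0:6
  n <- nrow(track)
  span <- frames[n] - frames[1L]
  res <- list(track_id = track_id, n_frames = n, nu = nu,
              lags_s = numeric(0),
              moments = matrix(numeric(0), ncol = 7L,
                               dimnames = list(NULL, paste0("mu_", nu))),
              gamma = rep(NA_real_, 7L), r2 = rep(NA_real_, 7L),
              S = NA_real_, D_est_um2_s = NA_real_,
              n_lags_used = 0L, degenerate = FALSE, label = NA_character_)
  class(res) <- "mss_result"
  K <- floor(max_lag_fraction * span)
  if (K < 1L) return(res)

  # position lookup indexed by frame offset; NA rows mark gap frames
  pos <- matrix(NA_real_, nrow = span + 1L, ncol = 2L)
  pos[frames - frames[1L] + 1L, ] <- cbind(track$x_um, track$y_um)

  mom <- matrix(NA_real_, nrow = K, ncol = 7L,
                dimnames = list(NULL, paste0("mu_", nu)))
  for (k in seq_len(K)) {
    i1 <- seq_len(span + 1L - k)
    d2 <- (pos[i1 + k, 1L] - pos[i1, 1L])^2 + (pos[i1 + k, 2L] - pos[i1, 2L])^2
    d <- sqrt(d2[!is.na(d2)])
    if (length(d) == 0L) next
    mom[k, ] <- vapply(nu, function(v) mean(d^v), numeric(1))
  }
  lags <- seq_len(K) * dt
  keep <- !is.na(mom[, 1L])
  res$lags_s <- lags
  res$moments <- mom

  # stationary (all displacements zero at every lag): S defined as 0
  if (all(mom[keep, "mu_2"] == 0)) {
    res$degenerate <- TRUE
    res$gamma <- rep(0, 7L)
    res$S <- 0
    res$n_lags_used <- sum(keep)
    return(res)
  }

  # per-order log-log fits; lags with a zero moment carry no log information
  gamma <- numeric(7L); r2 <- rep(NA_real_, 7L)
  gamma[1L] <- 0; r2[1L] <- 1  # mu_0 = 1 identically
  usable <- keep & mom[, "mu_2"] > 0
  if (sum(usable) < 3L) { res$n_lags_used <- sum(usable); return(res) }
  lx <- log(lags[usable])
  for (j in 2:7) {
    ly <- log(mom[usable, j])
    fit <- stats::lm.fit(cbind(1, lx), ly)
    gamma[j] <- fit$coefficients[2L]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((ly - mean(ly))^2)
    r2[j] <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    if (j == 3L) { # nu = 2: Brownian intercept log(4D)
      res$D_est_um2_s <- exp(fit$coefficients[1L]) / 4
    }
  }
  res$gamma <- gamma
  res$r2 <- r2
  res$S <- sum(nu * gamma) / sum(nu^2)  # least squares through (0, 0)
  res$n_lags_used <- sum(usable)
  res
}

#' @export
print.mss_result <- function(x, ...) {
  cat("MSS result for track", x$track_id, "-", x$n_frames, "frames\n")
  cat("  S =", format(x$S, digits = 4),
      " gamma_2 =", format(x$gamma[3L], digits = 4),
      " D_est =", format(x$D_est_um2_s, digits = 4), "um^2/s\n")
  cat("  label:", ifelse(is.na(x$label), "<unlabeled>", x$label), "\n")
  invisible(x)
}

#' Calibrate MSS classification thresholds by Brownian simulation
#'
#' The boundaries between confined, free and directed motion are not fixed
#' constants: the sampling distribution of the MSS slope S for a genuinely
#' Brownian track depends on track length, frame interval and localization
#' noise. This calibrator simulates `n_sim` free (Brownian) tracks under
#' the acquisition at hand and returns the 2.5th and 97.5th percentiles of
#' their S distribution as `S_low` / `S_high`, so that a free track is
#' misclassified at most ~5% of the time by construction.
#'
#' @param track_len Track length in frames.
#' @param dt Frame interval in seconds.
#' @param loc_noise Localization noise sd in um (default 0).
#' @param n_sim Number of simulated tracks (>= 100; default 500).
#' @param seed Integer seed for reproducibility.
#' @param D Reference diffusion coefficient in um^2/s (default 0.05). With
#'   zero localization noise S is scale-invariant and D is immaterial;
#'   with noise the ratio of step size to noise matters, so D should match
#'   the data's scale.
#' @param max_lag_fraction Passed to [compute_mss()].
#' @param min_R2 Fit-quality gate bundled with the thresholds (default
#'   0.8); see [classify_motion()].
#' @return A list with `S_low`, `S_high`, `min_R2`, and the simulated `S`
#'   values (`S_sim`).
#' @export
calibrate_mss_thresholds <- function(track_len, dt, loc_noise = 0,
                                     n_sim = 500, seed = 1, D = 0.05,
                                     max_lag_fraction = 0.25, min_R2 = 0.8) {
  if (n_sim < 100) stop("'n_sim' must be >= 100")
  set.seed(seed)
  spec <- motion_spec("free", D = D, dt = dt, n_frames = track_len,
                      loc_noise_sigma = loc_noise)
  S <- vapply(seq_len(n_sim), function(i) {
    tr <- simulate_trajectory(spec)$track
    compute_mss(tr, dt = dt, max_lag_fraction = max_lag_fraction)$S
  }, numeric(1))
  q <- stats::quantile(S, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(S_low = q[1L], S_high = q[2L], min_R2 = min_R2, S_sim = S)
}

#' Classify the motion type of a trajectory from its MSS slope
#'
#' Applies the three-way decision rule: `confined` if `S < S_low`,
#' `directed` if `S > S_high`, `free` otherwise. A track is `unclassified`
#' when its MSS could not be estimated reliably: fewer than `min_track_len`
#' frames, fewer than 3 usable lags, a non-finite slope, or a poor
#' moment-scaling fit. The fit-quality gate uses the order-2 log-log
#' R^2 and is applied only when the provisional call is free or directed:
#' those calls assert a power-law scaling, which must actually fit. The
#' spectrum of a confined particle is flat by construction, so R^2 is an
#' ill-posed score precisely when the confined call is clearest and is not
#' used to veto it.
#'
#' @param mss An `mss_result` from [compute_mss()].
#' @param thresholds A list with `S_low`, `S_high`, `min_R2`, e.g. from
#'   [calibrate_mss_thresholds()].
#' @param min_track_len Minimum frames for a classifiable track
#'   (default 20).
#' @return The `mss_result` with its `label` field set to one of
#'   `"confined"`, `"free"`, `"directed"`, `"unclassified"`.
#' @export
classify_motion <- function(mss, thresholds, min_track_len = 20) {
  stopifnot(inherits(mss, "mss_result"))
  if (!all(c("S_low", "S_high") %in% names(thresholds)))
    stop("'thresholds' must contain S_low and S_high")
  min_R2 <- if (!is.null(thresholds$min_R2)) thresholds$min_R2 else 0.8
  lab <- "unclassified"
  if (mss$degenerate) {
    lab <- "confined"  # perfectly stationary particle
  } else if (mss$n_frames >= min_track_len && mss$n_lags_used >= 3L &&
             is.finite(mss$S)) {
    provisional <- if (mss$S < thresholds$S_low) "confined"
                   else if (mss$S > thresholds$S_high) "directed"
                   else "free"
    if (provisional == "confined" ||
        (is.finite(mss$r2[3L]) && mss$r2[3L] >= min_R2)) {
      lab <- provisional
    }
  }
  mss$label <- lab
  mss
}

#' MSS-classify every track in a linked-track table
#'
#' Runs [compute_mss()] and [classify_motion()] on each track of a
#' data.frame of linked trajectories and returns one row per track.
#'
#' @param tracks A data.frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um` (e.g. [link_detections()] output with calibration).
#' @param dt Frame interval in seconds.
#' @param thresholds Classification thresholds (see
#'   [calibrate_mss_thresholds()]).
#' @param min_track_len,max_lag_fraction Passed through.
#' @return A data.frame: `track_id`, `n_frames`, `S`,
#'   `gamma_1`..`gamma_6`, `D_est_um2_s`, `label`.
#' @export
analyze_tracks <- function(tracks, dt, thresholds, min_track_len = 20,
                           max_lag_fraction = 0.25) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    m <- compute_mss(tr, dt = dt, max_lag_fraction = max_lag_fraction,
                     track_id = id)
    m <- classify_motion(m, thresholds, min_track_len = min_track_len)
    g <- m$gamma[2:7]
    df <- data.frame(track_id = id, n_frames = m$n_frames, S = m$S,
                     t(g), D_est_um2_s = m$D_est_um2_s, label = m$label)
    names(df)[4:9] <- paste0("gamma_", 1:6)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate labeled MSS results into a motility summary
#'
#' Produces per-group counts and proportions of the four motion labels,
#' the pooled proportion of free-plus-directed tracks (the "motile"
#' fraction reported for endolysosome populations), and the ratio of
#' free-plus-directed to confined counts.
#'
#' @param results A list of labeled `mss_result` objects, or a data.frame
#'   with a `label` column (and optionally `group`).
#' @param grouping Optional vector assigning each result to a group
#'   (condition, cell, ...). Default: a single group `"all"`.
#' @return A data.frame with one row per group: counts `n_confined`,
#'   `n_free`, `n_directed`, `n_unclassified`, `n_total`, proportions
#'   `p_confined`, `p_free`, `p_directed`, `p_unclassified`,
#'   `p_free_directed`, and `ratio_fd_confined` (`NA` with a warning flag
#'   when the confined count is 0).
#' @export
summarize_motion <- function(results, grouping = NULL) {
  labels <- if (is.data.frame(results)) {
    if (!"label" %in% names(results)) stop("data.frame must have a 'label' column")
    as.character(results$label)
  } else {
    vapply(results, function(r) r$label, character(1))
  }
  if (length(labels) == 0L) stop("no labeled tracks to summarize")
  if (is.null(grouping)) {
    grouping <- if (is.data.frame(results) && "group" %in% names(results))
      as.character(results$group) else rep("all", length(labels))
  }
  if (length(grouping) != length(labels))
    stop("'grouping' must have one entry per result")
  lv <- c("confined", "free", "directed", "unclassified")
  if (!all(labels %in% lv)) stop("unknown motion label(s)")
  out <- lapply(split(labels, grouping), function(ls) {
    n <- table(factor(ls, levels = lv))
    tot <- length(ls)
    p <- as.numeric(n) / tot
    fd <- p[2L] + p[3L]
    ratio <- if (n[1L] > 0L) (n[2L] + n[3L]) / n[1L] else NA_real_
    data.frame(n_confined = as.integer(n[1L]), n_free = as.integer(n[2L]),
               n_directed = as.integer(n[3L]),
               n_unclassified = as.integer(n[4L]), n_total = tot,
               p_confined = p[1L], p_free = p[2L], p_directed = p[3L],
               p_unclassified = p[4L], p_free_directed = fd,
               ratio_fd_confined = ratio,
               ratio_undefined = n[1L] == 0L)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(group = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Partition tracks by presence of a marker accumulation
#'
#' Splits trajectories into marker-positive ("+") and marker-negative
#' ("-") groups according to whether a track's position falls inside a
#' per-frame accumulation mask in at least `min_overlap_fraction` of its
#' frames. Used to compare the motility of endolysosomes with and without
#' a visible ER-protein accumulation.
#'
#' @param tracks A data.frame of linked tracks with columns `track_id`,
#'   `frame` (0-based), `x_px`, `y_px`.
#' @param masks A list of logical matrices (one per frame, y-by-x), or a
#'   3-D logical array indexed (frame, y, x). Must cover every frame
#'   referenced by the tracks.
#' @param min_overlap_fraction Fraction of a track's frames that must lie
#'   inside a mask for the "+" call (default 0.5).
#' @return A list with elements `plus` and `minus`, each a vector of
#'   track ids, and `overlap_fraction`, a named vector of the per-track
#'   fractions. The partition is exhaustive and disjoint.
#' @export
partition_tracks_by_marker <- function(tracks, masks,
                                       min_overlap_fraction = 0.5) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x_px", "y_px") %in% names(tracks)))
  if (is.array(masks) && length(dim(masks)) == 3L) {
    masks <- lapply(seq_len(dim(masks)[1L]), function(t) masks[t, , ])
  }
  n_frames <- length(masks)
  if (any(tracks$frame < 0L | tracks$frame >= n_frames))
    stop("tracks reference frames not covered by the masks")
  dims <- dim(masks[[1L]])
  inside <- logical(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    m <- masks[[tracks$frame[i] + 1L]]
    yy <- round(tracks$y_px[i]) + 1L
    xx <- round(tracks$x_px[i]) + 1L
    inside[i] <- yy >= 1L && yy <= dims[1L] && xx >= 1L && xx <= dims[2L] &&
      isTRUE(m[yy, xx])
  }
  frac <- tapply(inside, tracks$track_id, mean)
  plus <- names(frac)[frac >= min_overlap_fraction]
  minus <- setdiff(names(frac), plus)
  list(plus = plus, minus = minus,
       overlap_fraction = stats::setNames(as.numeric(frac), names(frac)))
}
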