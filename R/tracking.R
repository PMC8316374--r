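#' Link per-frame detections into trajectories
#'
#' Frame-to-frame linking by optimal (Hungarian) assignment minimizing
#' summed squared displacement, with gap closing: a track that misses up
#' to `max_gap_frames` consecutive frames may be resumed, with the
#' allowed displacement growing proportionally to the gap. Every
#' detection is used at most once; tracks shorter than `min_track_len`
#' points are discarded.
#'
#' @param detections A data.frame from [detect_spots()] (columns `frame`,
#'   `x_px`, `y_px`; optionally `channel`), sorted by frame.
#' @param max_disp_px Maximum displacement between consecutive frames in
#'   px (default 5; at 0.1 um/px and 10 fps this caps speeds near
#'   5 um/s, comfortably above reported directed endolysosome speeds).
#' @param max_gap_frames Maximum number of missed frames bridged by gap
#'   closing (default 0).
#' @param min_track_len Minimum number of points per reported track
#'   (default 20 frames, about 2 s at 10 fps; moment-scaling fits are
#'   unstable on shorter tracks).
#' @param pixel_size_um,frame_interval_s Optional calibration; when given,
#'   `x_um`, `y_um` and `time_s` columns are added.
#' @return A data.frame with columns `track_id`, `frame`, `x_px`, `y_px`
#'   (plus calibrated columns when requested), ordered by track then
#'   frame. Zero rows when nothing links.
#' @export
link_detections <- function(detections, max_disp_px = 5,
                            max_gap_frames = 0, min_track_len = 20,
                            pixel_size_um = NULL,
                            frame_interval_s = NULL) {
  stopifnot(is.data.frame(detections))
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0))
  if (nrow(detections) == 0L) return(empty)
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  if (max_disp_px <= 0) stop("'max_disp_px' must be > 0")
  if (max_gap_frames < 0) stop("'max_gap_frames' must be >= 0")
  key <- paste(detections$frame,
               if ("channel" %in% names(detections)) detections$channel else "",
               detections$x_px, detections$y_px)
  if (anyDuplicated(key))
    stop("duplicate detection (same frame, channel and coordinates)")
  det <- detections[order(detections$frame), , drop = FALSE]
  det$.row <- seq_len(nrow(det))

  BIG <- 1e12
  tracks <- list()   # each: list(rows, last_frame, x, y, open)
  open_idx <- integer(0)
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    # retire tracks that can no longer be resumed
    if (length(open_idx) > 0L) {
      last <- vapply(tracks[open_idx], `[[`, numeric(1), "last_frame")
      open_idx <- open_idx[f - last <= max_gap_frames + 1L]
    }
    if (length(open_idx) > 0L && length(rows) > 0L) {
      last <- vapply(tracks[open_idx], `[[`, numeric(1), "last_frame")
      tx <- vapply(tracks[open_idx], `[[`, numeric(1), "x")
      ty <- vapply(tracks[open_idx], `[[`, numeric(1), "y")
      gap <- f - last               # 1 = consecutive frames
      d2 <- outer(tx, det$x_px[rows], "-")^2 +
            outer(ty, det$y_px[rows], "-")^2
      lim2 <- (max_disp_px * gap)^2
      cost <- d2
      cost[d2 > lim2] <- BIG
      n <- max(nrow(cost), ncol(cost))
      sq <- matrix(BIG, n, n)
      sq[seq_len(nrow(cost)), seq_len(ncol(cost))] <- cost
      sol <- as.integer(clue::solve_LSAP(sq))
      taken <- logical(length(rows))
      for (i in seq_along(open_idx)) {
        j <- sol[i]
        if (j <= length(rows) && cost[i, j] < BIG) {
          ti <- open_idx[i]
          r <- rows[j]
          tracks[[ti]]$rows <- c(tracks[[ti]]$rows, det$.row[r])
          tracks[[ti]]$last_frame <- f
          tracks[[ti]]$x <- det$x_px[r]
          tracks[[ti]]$y <- det$y_px[r]
          taken[j] <- TRUE
        }
      }
      rows <- rows[!taken]
    }
    for (r in rows) {  # unmatched detections seed new tracks
      tracks[[length(tracks) + 1L]] <- list(rows = det$.row[r],
                                            last_frame = f,
                                            x = det$x_px[r],
                                            y = det$y_px[r])
      open_idx <- c(open_idx, length(tracks))
    }
  }
  keep <- vapply(tracks, function(tr) length(tr$rows) >= min_track_len,
                 logical(1))
  tracks <- tracks[keep]
  if (length(tracks) == 0L) return(empty)
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    rws <- tracks[[i]]$rows
    data.frame(track_id = i, frame = det$frame[rws],
               x_px = det$x_px[rws], y_px = det$y_px[rws])
  }))
  if (!is.null(pixel_size_um)) {
    out$x_um <- out$x_px * pixel_size_um
    out$y_um <- out$y_px * pixel_size_um
  }
  if (!is.null(frame_interval_s)) out$time_s <- out$frame * frame_interval_s
  rownames(out) <- NULL
  out
}
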