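# Link per-plane co-occurrence objects into events along an axis (time
# or z). 'objects' is a list (one per plane) of lists of pixel-index
# vectors (the EL object footprints in contact in that plane). Identity
# across planes follows footprint overlap (>= 1 shared pixel); an event
# may survive up to 'max_gap' planes without a match. Returns a
# data.frame with start/end plane indices (1-based).
.link_overlap_events <- function(objects, max_gap = 0L) {
  events <- list()   # each: list(start, end, last_px, open)
  open_idx <- integer(0)
  for (t in seq_along(objects)) {
    obs <- objects[[t]]
    if (length(open_idx) > 0L) {
      last_end <- vapply(events[open_idx], `[[`, numeric(1), "end")
      open_idx <- open_idx[t - last_end <= max_gap + 1L]
    }
    matched_obj <- logical(length(obs))
    if (length(open_idx) > 0L && length(obs) > 0L) {
      ov <- matrix(0L, length(open_idx), length(obs))
      for (i in seq_along(open_idx)) {
        for (j in seq_along(obs)) {
          ov[i, j] <- length(intersect(events[[open_idx[i]]]$last_px,
                                       obs[[j]]))
        }
      }
      # greedy largest-overlap matching
      while (TRUE) {
        m <- which.max(ov)
        if (length(m) == 0L || ov[m] == 0L) break
        i <- (m - 1L) %% nrow(ov) + 1L
        j <- (m - 1L) %/% nrow(ov) + 1L
        ei <- open_idx[i]
        events[[ei]]$end <- t
        events[[ei]]$last_px <- obs[[j]]
        matched_obj[j] <- TRUE
        ov[i, ] <- 0L; ov[, j] <- 0L
      }
    }
    for (j in which(!matched_obj)) {
      events[[length(events) + 1L]] <- list(start = t, end = t,
                                            last_px = obs[[j]])
      open_idx <- c(open_idx, length(events))
    }
  }
  if (length(events) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = vapply(events, `[[`, numeric(1), "start"),
             end = vapply(events, `[[`, numeric(1), "end"))
}

# Per-plane contact objects: EL connected components sharing >= 1 pixel
# with the accumulation mask.
.contact_objects <- function(snx_mask, el_mask) {
  lab <- .label8(el_mask * 1)
  ids <- setdiff(unique(lab[snx_mask & lab > 0L]), 0L)
  lapply(ids, function(id) which(lab == id))
}

#' Call persistent accumulation-EL contact events in a recording
#'
#' Per frame, thresholds the accumulation channel (bright ER-protein
#' puncta standing out above the reticular signal) and the EL channel,
#' overlays them, and treats each EL object sharing at least one pixel
#' with the accumulation mask as co-occurring. Co-occurrences are linked
#' across frames by EL footprint overlap into events; an event is an
#' accepted (true) contact when its duration
#' `(end - start + 1) * frame_interval_s` reaches `min_duration_s`
#' (default 10 s).
#'
#' @param stack An [image_stack()] with the accumulation and EL channels.
#' @param snx_channel,el_channel Channel names or indices.
#' @param params List: `method` and `level` for the accumulation
#'   threshold, `el_method`/`el_level` for the EL channel (defaults
#'   `"otsu"`), `min_duration_s` (default 10), `max_gap_frames` (default
#'   0: no dropout tolerance within an event).
#' @param cell_id Identifier for the recording (one cell per recording).
#' @return A list: `events` (data.frame `cell_id`, `event_id`,
#'   `start_frame`, `end_frame` (0-based), `duration_s`, `accepted`) and
#'   `accepted_count`.
#' @export
detect_contacts <- function(stack, snx_channel = "snx19",
                            el_channel = "el", params = list(),
                            cell_id = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  p <- list(method = "percentile", level = 99, el_method = "otsu",
            el_level = NA, min_duration_s = 10, max_gap_frames = 0)
  p[names(params)] <- params
  dt <- stack$frame_interval_s
  if (dt <= 0) stop("stack must have frame_interval_s > 0")
  n_frames <- dim(stack$data)[1L]
  if (p$min_duration_s > n_frames * dt)
    warning("min_duration_s (", p$min_duration_s, " s) exceeds the ",
            "recording length (", n_frames * dt, " s)")
  snx <- threshold_accumulations(stack, snx_channel, method = p$method,
                                 level = p$level)
  el <- threshold_accumulations(stack, el_channel, method = p$el_method,
                                level = if (is.na(p$el_level)) 99
                                        else p$el_level)
  objects <- lapply(seq_len(n_frames), function(t) {
    .contact_objects(snx$masks[[t]], el$masks[[t]])
  })
  ev <- .link_overlap_events(objects, max_gap = p$max_gap_frames)
  if (nrow(ev) == 0L) {
    events <- data.frame(cell_id = integer(0), event_id = integer(0),
                         start_frame = integer(0), end_frame = integer(0),
                         duration_s = numeric(0), accepted = logical(0))
    return(list(events = events, accepted_count = 0L))
  }
  events <- data.frame(cell_id = cell_id, event_id = seq_len(nrow(ev)),
                       start_frame = ev$start - 1L, end_frame = ev$end - 1L,
                       duration_s = (ev$end - ev$start + 1L) * dt)
  events$accepted <- events$duration_s >= p$min_duration_s
  list(events = events, accepted_count = sum(events$accepted))
}

#' Count contacts in a fixed-cell z-stack
#'
#' Same overlap logic as [detect_contacts()], with persistence measured
#' across z instead of time: a contact must appear in at least
#' `min_consecutive_z` consecutive slices (default 2) to be counted.
#'
#' @param stack An [image_stack()] whose first axis is z.
#' @param snx_channel,el_channel Channel names or indices.
#' @param params List: `method`/`level`, `el_method`/`el_level`,
#'   `min_consecutive_z` (default 2).
#' @param cell_id Identifier for the cell.
#' @return A list: `events` (data.frame with `start_z`, `end_z`,
#'   `n_slices`, `accepted`) and `count` of accepted contacts.
#' @export
detect_contacts_zstack <- function(stack, snx_channel = "snx19",
                                   el_channel = "el", params = list(),
                                   cell_id = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$data)[1L]
  if (nz < 2L)
    stop("single-slice stack: use detect_contacts() for time series")
  p <- list(method = "percentile", level = 99, el_method = "otsu",
            el_level = NA, min_consecutive_z = 2)
  p[names(params)] <- params
  snx <- threshold_accumulations(stack, snx_channel, method = p$method,
                                 level = p$level)
  el <- threshold_accumulations(stack, el_channel, method = p$el_method,
                                level = if (is.na(p$el_level)) 99
                                        else p$el_level)
  objects <- lapply(seq_len(nz), function(z) {
    .contact_objects(snx$masks[[z]], el$masks[[z]])
  })
  ev <- .link_overlap_events(objects, max_gap = 0L)
  if (nrow(ev) == 0L) {
    return(list(events = data.frame(cell_id = integer(0),
                                    start_z = integer(0),
                                    end_z = integer(0),
                                    n_slices = integer(0),
                                    accepted = logical(0)),
                count = 0L))
  }
  events <- data.frame(cell_id = cell_id, start_z = ev$start - 1L,
                       end_z = ev$end - 1L,
                       n_slices = ev$end - ev$start + 1L)
  events$accepted <- events$n_slices >= p$min_consecutive_z
  list(events = events, count = sum(events$accepted))
}

#' Score ER association of one endolysosome over followed frames
#'
#' For an EL followed over `n` consecutive frames (default 10), scores
#' each frame for the presence of thresholded ER signal inside the EL
#' mask and reports `100 * frames_with_ER / frames_followed` - the
#' percentage of time the EL is associated with the ER.
#'
#' @param el_masks List of per-frame logical EL masks (default length
#'   10).
#' @param er_frames List of per-frame ER intensity matrices (same length
#'   and shape).
#' @param er_threshold ER intensity threshold; pixels strictly above it
#'   count as ER signal.
#' @param el_id Identifier copied to the result.
#' @return A data.frame row: `el_id`, `n_frames_followed`,
#'   `n_frames_with_er`, `percent`.
#' @export
score_er_association <- function(el_masks, er_frames, er_threshold = 0,
                                 el_id = NA) {
  if (length(el_masks) != length(er_frames))
    stop("el_masks and er_frames must have the same length")
  n <- length(el_masks)
  if (n == 0L) stop("no frames to score")
  hit <- vapply(seq_len(n), function(i) {
    if (!all(dim(el_masks[[i]]) == dim(er_frames[[i]])))
      stop("mask/frame shape mismatch at frame ", i)
    any(er_frames[[i]][el_masks[[i]]] > er_threshold)
  }, logical(1))
  data.frame(el_id = el_id, n_frames_followed = n,
             n_frames_with_er = sum(hit), percent = 100 * sum(hit) / n)
}

#' Classify puncta by the subset of markers they overlap
#'
#' Labels each punctum with the exact subset of marker masks containing
#' its position (>= 1 shared pixel) and tabulates counts and percentages
#' per subset, including the empty subset - the composition behind a
#' marker co-occurrence (Venn) diagram.
#'
#' @param puncta A data.frame with `x_px`, `y_px` (0-based).
#' @param marker_masks Named list of logical matrices, all of the same
#'   shape and aligned to the puncta frame.
#' @return A list: `per_punctum` (data.frame with a `subset` string per
#'   punctum, markers joined by `+`, `"none"` for the empty subset) and
#'   `table` (data.frame `subset`, `count`, `percent`; percentages sum
#'   to 100).
#' @export
classify_marker_overlap <- function(puncta, marker_masks) {
  stopifnot(is.data.frame(puncta),
            all(c("x_px", "y_px") %in% names(puncta)))
  if (is.null(names(marker_masks)) || any(names(marker_masks) == ""))
    stop("'marker_masks' must be a named list")
  dims <- dim(marker_masks[[1L]])
  if (!all(vapply(marker_masks, function(m) all(dim(m) == dims),
                  logical(1))))
    stop("all marker masks must share the same shape")
  mk <- names(marker_masks)
  n <- nrow(puncta)
  if (n == 0L) {
    return(list(per_punctum = data.frame(subset = character(0)),
                table = data.frame(subset = character(0),
                                   count = integer(0),
                                   percent = numeric(0))))
  }
  subset <- vapply(seq_len(n), function(i) {
    yy <- round(puncta$y_px[i]) + 1L
    xx <- round(puncta$x_px[i]) + 1L
    inb <- yy >= 1L && yy <= dims[1L] && xx >= 1L && xx <= dims[2L]
    hits <- if (inb) mk[vapply(marker_masks,
                               function(m) isTRUE(m[yy, xx]),
                               logical(1))] else character(0)
    if (length(hits) == 0L) "none" else paste(hits, collapse = "+")
  }, character(1))
  tab <- as.data.frame(table(subset), stringsAsFactors = FALSE)
  names(tab) <- c("subset", "count")
  tab$percent <- 100 * tab$count / n
  list(per_punctum = data.frame(subset = subset), table = tab)
}
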