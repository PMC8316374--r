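#' Match reconstructed tracks to ground-truth particles
#'
#' Assigns every track point to the nearest true particle position in
#' its frame and scores each track's purity (fraction of its points
#' belonging to its modal particle). Used to validate detection +
#' linking against a synthetic scene's ground truth.
#'
#' @param tracks Linked tracks (`track_id`, `frame`, `x_px`, `y_px`).
#' @param truth_positions Ground-truth positions from [render_movie()]
#'   (`particle`, `frame`, `x_px`, `y_px`).
#' @return A data.frame: `track_id`, `particle` (modal true particle),
#'   `purity`, `n_points`.
#' @export
match_tracks_to_truth <- function(tracks, truth_positions) {
  stopifnot(is.data.frame(tracks), is.data.frame(truth_positions))
  by_frame <- split(truth_positions, truth_positions$frame)
  nearest <- integer(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    tp <- by_frame[[as.character(tracks$frame[i])]]
    d <- (tp$x_px - tracks$x_px[i])^2 + (tp$y_px - tracks$y_px[i])^2
    nearest[i] <- tp$particle[which.min(d)]
  }
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    sel <- nearest[tracks$track_id == id]
    tab <- table(sel)
    data.frame(track_id = id,
               particle = as.integer(names(tab)[which.max(tab)]),
               purity = max(tab) / length(sel), n_points = length(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
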