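#' Run the full motility pipeline on a recording
#'
#' Convenience wrapper chaining spot detection, trajectory linking,
#' simulation-calibrated MSS thresholding and motion classification, and
#' the motility summary, with all tunables taken from a configuration
#' list (see [default_config()]).
#'
#' @param stack An [image_stack()] time series.
#' @param channel Channel to track.
#' @param config Configuration list; missing entries fall back to
#'   [default_config()].
#' @param thresholds Optional precomputed MSS thresholds; when `NULL`
#'   they are calibrated for this acquisition (recording length, frame
#'   interval) with seed `config$seed`.
#' @return A list: `detections`, `tracks`, `mss` (per-track results with
#'   labels), `summary` (from [summarize_motion()]), `thresholds`.
#' @export
run_motility_pipeline <- function(stack, channel = 1L,
                                  config = default_config(),
                                  thresholds = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  config <- .merge_config(default_config(), config)
  dt <- stack$frame_interval_s
  if (dt <= 0) stop("stack must have frame_interval_s > 0")
  det <- detect_spots(stack, channel, params = config$detector)
  tracks <- link_detections(det,
                            max_disp_px = config$linker$max_disp_px,
                            max_gap_frames = config$linker$max_gap_frames,
                            min_track_len = config$linker$min_track_len,
                            pixel_size_um = stack$pixel_size_um,
                            frame_interval_s = dt)
  if (nrow(tracks) == 0L) {
    return(list(detections = det, tracks = tracks, mss = NULL,
                summary = NULL, thresholds = thresholds))
  }
  if (is.null(thresholds)) {
    thresholds <- calibrate_mss_thresholds(
      track_len = dim(stack$data)[1L], dt = dt,
      n_sim = config$mss$calibration_n_sim, seed = config$seed,
      min_R2 = config$mss$min_R2,
      max_lag_fraction = config$mss$max_lag_fraction)
  }
  mss <- analyze_tracks(tracks, dt = dt, thresholds = thresholds,
                        min_track_len = config$linker$min_track_len,
                        max_lag_fraction = config$mss$max_lag_fraction)
  list(detections = det, tracks = tracks, mss = mss,
       summary = summarize_motion(mss), thresholds = thresholds)
}
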