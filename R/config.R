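#' Default pipeline configuration
#'
#' All tunables of the pipeline in one nested list. Defaults follow the
#' quantification constants of the underlying assays where one exists:
#' 10 s contact persistence, shells of 2 um with 5 shells and shells 3-5
#' peripheral, 30 nm EM apposition cutoff, 5 px minimum PLA dot size,
#' 10-frame association scoring at 2.4 s per frame. Detector, linker and
#' MSS constants have no published values and are calibratable choices.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    acquisition = list(
      pixel_size_um = 0.1,      # fixture default; real data carries its own
      psf_sigma_px = 1.3,
      frame_interval_s = 0.1    # 10 fps motility acquisition
    ),
    detector = list(
      min_amplitude = NA_real_, # NA = auto: 5 x robust background sd
      expected_sigma_px = 1.3,
      max_fit_residual = 0.15
    ),
    linker = list(
      max_disp_px = 5,
      max_gap_frames = 0,
      min_track_len = 20
    ),
    mss = list(
      max_lag_fraction = 0.25,
      min_R2 = 0.8,
      calibration_n_sim = 500,
      min_overlap_fraction = 0.5
    ),
    contacts = list(
      min_duration_s = 10,
      max_gap_frames = 0,
      min_consecutive_z = 2
    ),
    association = list(
      n_frames_followed = 10,
      frame_interval_s = 2.4
    ),
    shells = list(
      step_um = 2,
      n_shells = 5,
      peripheral_from = 3,      # shells 3..n_shells are "peripheral"
      signal_measure = "intensity"  # or "area"
    ),
    em = list(
      cutoff_nm = 30,
      resample_step_nm = 5,
      section_thickness_nm = 50
    ),
    pla = list(
      threshold = NA_real_,     # NA = Otsu fallback
      min_size_px = 5
    ),
    seed = 1,
    output_dir = "."
  )
}

# Recursively merge user values over defaults, rejecting unknown keys and
# type mismatches. 'path' tracks the key path for error messages.
.merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", paste(path, collapse = "."),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1L]), collapse = "."), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      v <- user[[k]]
      kp <- paste(c(path, k), collapse = ".")
      if (is.numeric(defaults[[k]]) && !is.numeric(v) && !is.na(v))
        stop("config key '", kp, "' must be numeric")
      if (is.character(defaults[[k]]) && !is.character(v))
        stop("config key '", kp, "' must be a string")
      if (length(v) != 1L && !is.null(v))
        stop("config key '", kp, "' must be a scalar")
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a (possibly partial) YAML file and merges it over
#' [default_config()]. Unknown keys are rejected by name; scalar type
#' mismatches are reported per key. An empty or absent body yields the
#' pure defaults.
#'
#' @param path Path to a YAML file.
#' @return The resolved configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  .merge_config(default_config(), user)
}

#' Write a resolved configuration next to a run's outputs
#'
#' @param config A configuration list.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
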