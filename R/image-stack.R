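#' Calibrated multi-channel image stack
#'
#' Container for a T x C x Y x X intensity array with its spatial and
#' temporal calibration. All package operations that consume images take
#' an `image_stack`. Intensities must be finite and non-negative.
#'
#' @param data Numeric array indexed (t, c, y, x). A 2-D matrix is
#'   promoted to a 1x1xYxX stack, a 3-D (c, y, x) array to 1xCxYxX.
#' @param pixel_size_um Pixel size in um (> 0).
#' @param frame_interval_s Frame interval in seconds; must be > 0 when
#'   the stack has more than one frame, may be 0 for stills.
#' @param channel_names Character vector naming the channels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_s = 0,
                        channel_names = NULL) {
  if (is.matrix(data)) dim(data) <- c(1L, 1L, dim(data))
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L)
    stop("'data' must be a (t, c, y, x) array")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single number > 0")
  if (dim(data)[1L] > 1L && (!is.numeric(frame_interval_s) ||
                             frame_interval_s <= 0))
    stop("'frame_interval_s' must be > 0 for a multi-frame stack")
  nc <- dim(data)[2L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("'channel_names' length must equal the number of channels")
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frame(s), %d channel(s), %d x %d px\n",
              d[1L], d[2L], d[4L], d[3L]))
  cat(sprintf("  pixel size %g um, frame interval %g s\n",
              x$pixel_size_um, x$frame_interval_s))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

# Resolve a channel given by name or index to an index.
.channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) stop("unknown channel: ", channel)
    return(i)
  }
  if (channel < 1L || channel > dim(stack$data)[2L])
    stop("channel index out of range: ", channel)
  as.integer(channel)
}

# Extract one frame of one channel as a y-by-x matrix.
get_frame <- function(stack, frame, channel = 1L) {
  ci <- .channel_index(stack, channel)
  stack$data[frame, ci, , , drop = TRUE]
}

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major, channel-fastest (page = (t-1)*C + c).
#' Intensities are stored as 16-bit unsigned integers; values are rounded
#' and clamped to 0..65535. Calibration, channel names and an optional
#' seed go to `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param seed Optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  vals <- pmin(pmax(round(stack$data), 0), 65535)
  pages <- vector("list", d[1L] * d[2L])
  for (t in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    pages[[(t - 1L) * d[2L] + c]] <- vals[t, c, , , drop = TRUE] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(pixel_size_um = stack$pixel_size_um,
                  frame_interval_s = stack$frame_interval_s,
                  channel_names = as.list(stack$channel_names),
                  n_frames = d[1L], n_channels = d[2L])
  if (!is.null(seed)) sidecar$seed <- seed
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Reads a TIFF written by [write_stack()] (or any grayscale multi-page
#' TIFF) and normalizes axes to (t, c, y, x). Calibration comes from the
#' `<path>.json` sidecar when present; otherwise `pixel_size_um` (and
#' `frame_interval_s` for movies) must be supplied explicitly - there are
#' no silent defaults.
#'
#' @param path TIFF path.
#' @param pixel_size_um,frame_interval_s Calibration overrides; required
#'   when no sidecar exists.
#' @param n_channels Number of channels (pages are frame-major,
#'   channel-fastest). Defaults to the sidecar value or 1.
#' @param channel_names Optional channel names override.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       n_channels = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  if (is.null(pixel_size_um)) pixel_size_um <- sidecar$pixel_size_um
  if (is.null(frame_interval_s)) frame_interval_s <- sidecar$frame_interval_s
  if (is.null(n_channels)) n_channels <- sidecar$n_channels
  if (is.null(channel_names)) channel_names <- sidecar$channel_names
  if (is.null(pixel_size_um))
    stop("calibration missing: supply 'pixel_size_um' or provide a ",
         "sidecar (", sidecar_path, ")")
  if (is.null(n_channels)) n_channels <- 1L
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("only single-sample (grayscale) TIFF pages are supported")
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0L)
    stop("page count ", n_pages, " is not a multiple of n_channels ",
         n_channels)
  n_frames <- n_pages %/% n_channels
  if (is.null(frame_interval_s)) {
    if (n_frames > 1L)
      stop("calibration missing: supply 'frame_interval_s' for a ",
           "multi-frame stack")
    frame_interval_s <- 0
  }
  dy <- nrow(pages[[1L]]); dx <- ncol(pages[[1L]])
  arr <- array(0, dim = c(n_frames, n_channels, dy, dx))
  for (t in seq_len(n_frames)) for (c in seq_len(n_channels)) {
    arr[t, c, , ] <- pages[[(t - 1L) * n_channels + c]]
  }
  image_stack(arr, pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              channel_names = unlist(channel_names))
}
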