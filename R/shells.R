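#' Partition a cell mask into concentric shells
#'
#' Emulates iterative inward erosion of a traced cell outline: the
#' Euclidean distance transform from the mask boundary is banded into
#' `n_shells` shells of width `step_um`. Shell `n_shells` is the
#' outermost band (touching the outline), shell 1 the innermost
#' (perinuclear) region, which absorbs all remaining interior. The
#' distance transform gives sub-pixel-accurate bands independent of any
#' structuring-element shape.
#'
#' @param cell_mask Logical (or 0/1) matrix; must be a single connected
#'   component.
#' @param pixel_size_um Pixel size in um.
#' @param step_um Shell width in um (default 2).
#' @param n_shells Number of shells (default 5).
#' @return An object of class `shell_map`: list with `labels` (integer
#'   matrix, 0 outside the cell, 1..n_shells inside), `step_um`,
#'   `n_shells`, `pixel_size_um`, and `flags` (character vector; contains
#'   `"thin_cell"` when the innermost shell is empty, i.e. the cell is
#'   too thin for the full shell count).
#' @export
build_shells <- function(cell_mask, pixel_size_um, step_um = 2,
                         n_shells = 5) {
  if (is.logical(cell_mask)) cell_mask <- cell_mask * 1
  stopifnot(is.matrix(cell_mask))
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be > 0")
  if (sum(cell_mask) == 0) stop("empty cell mask")
  ncomp <- max(.label8(cell_mask))
  if (ncomp > 1L)
    stop("cell mask has ", ncomp, " connected components; expected 1")
  d_um <- as.matrix(EBImage::distmap(cell_mask)) * pixel_size_um
  labels <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  inside <- cell_mask > 0
  # shell k covers boundary distance ((n-k)*step, (n-k+1)*step]; shell 1
  # absorbs everything deeper
  band <- pmin(ceiling(d_um / step_um), n_shells)
  labels[inside] <- n_shells + 1L - band[inside]
  flags <- character(0)
  if (!any(labels == 1L)) flags <- c(flags, "thin_cell")
  empty_shells <- setdiff(seq_len(n_shells), unique(labels[inside]))
  if (length(empty_shells) > 0L)
    flags <- unique(c(flags, "thin_cell"))
  structure(list(labels = labels, step_um = step_um,
                 n_shells = as.integer(n_shells),
                 pixel_size_um = pixel_size_um,
                 empty_shells = empty_shells, flags = flags),
            class = "shell_map")
}

#' Peripheral signal fraction over a shell map
#'
#' Sums thresholded intensity per shell and reports the fraction of
#' signal in the peripheral shells (by default shells 3..5 of 5) relative
#' to the whole cell - the peripheral dispersal statistic for
#' endolysosome positioning.
#'
#' @param image Intensity matrix, same shape as the shell map.
#' @param shells A `shell_map` from [build_shells()].
#' @param background_threshold Intensities at or below this value are
#'   treated as background and excluded (default 0).
#' @param peripheral_from First shell counted as peripheral (default 3).
#' @param measure `"intensity"` (sum of thresholded intensity, default)
#'   or `"area"` (count of above-threshold pixels).
#' @param cell_id Identifier copied to the result.
#' @return A data.frame row: `cell_id`, `signal_shell1..n`,
#'   `total_signal`, `peripheral_signal`, `fraction`, `flags`
#'   (semicolon-joined QC flags inherited from the shell map).
#' @export
peripheral_fraction <- function(image, shells, background_threshold = 0,
                                peripheral_from = 3,
                                measure = c("intensity", "area"),
                                cell_id = NA) {
  measure <- match.arg(measure)
  stopifnot(inherits(shells, "shell_map"))
  if (!all(dim(image) == dim(shells$labels)))
    stop("image and shell map shapes differ")
  n <- shells$n_shells
  sig <- image
  sig[sig <= background_threshold] <- 0
  if (measure == "area") sig <- (sig > 0) * 1
  per_shell <- vapply(seq_len(n), function(k) sum(sig[shells$labels == k]),
                      numeric(1))
  total <- sum(per_shell)
  if (total <= 0) stop("total signal is zero; fraction undefined")
  peripheral <- sum(per_shell[peripheral_from:n])
  out <- data.frame(cell_id = cell_id, t(per_shell), total_signal = total,
                    peripheral_signal = peripheral,
                    fraction = peripheral / total,
                    flags = paste(shells$flags, collapse = ";"))
  names(out)[2:(n + 1L)] <- paste0("signal_shell", seq_len(n))
  out
}

#' Rasterize a polygon (or disc) to a cell mask
#'
#' Helper to turn a traced outline in um into a pixel mask: a pixel
#' belongs to the mask when its center lies inside the polygon.
#'
#' @param outline Either a two-column matrix of polygon vertices (um,
#'   closed implicitly) or a list `list(center = c(x, y), radius = r)`
#'   describing a disc (um).
#' @param shape_px Output shape `c(height, width)` in px.
#' @param pixel_size_um Pixel size in um.
#' @return A logical matrix.
#' @export
rasterize_outline <- function(outline, shape_px, pixel_size_um) {
  h <- shape_px[1L]; w <- shape_px[2L]
  cx <- rep((0:(w - 1L)) * pixel_size_um, each = h)
  cy <- rep((0:(h - 1L)) * pixel_size_um, times = w)
  if (is.list(outline) && !is.null(outline$radius)) {
    inside <- (cx - outline$center[1L])^2 + (cy - outline$center[2L])^2 <=
      outline$radius^2
  } else {
    outline <- as.matrix(outline)
    if (nrow(outline) < 3L) stop("outline polygon needs >= 3 vertices")
    inside <- pracma::inpolygon(cx, cy, outline[, 1L], outline[, 2L],
                                boundary = TRUE)
  }
  matrix(inside, nrow = h, ncol = w)
}
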