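#' Count proximity-ligation dots with watershed splitting and a size
#' filter
#'
#' Binarizes the PLA channel at a threshold, splits touching dots with a
#' distance-transform watershed, labels the resulting objects and
#' retains those of at least `min_size_px` pixels.
#'
#' @param image Intensity matrix.
#' @param threshold_level Absolute intensity threshold (pixels strictly
#'   above it are foreground). `NA` (default) falls back to Otsu's
#'   threshold.
#' @param min_size_px Minimum dot area in px (default 5).
#' @param watershed_tolerance Height tolerance of the watershed on the
#'   distance map (default 0.3 px; small enough to split dots whose
#'   footprints merely touch).
#' @return A list: `dots` (data.frame `dot_id`, `centroid_x_px`,
#'   `centroid_y_px` (0-based), `area_px`) and `labels` (integer matrix
#'   of retained dots). An all-zero or all-background image yields an
#'   empty table.
#' @export
count_dots <- function(image, threshold_level = NA, min_size_px = 5,
                       watershed_tolerance = 0.3) {
  stopifnot(is.matrix(image))
  empty <- list(dots = data.frame(dot_id = integer(0),
                                  centroid_x_px = numeric(0),
                                  centroid_y_px = numeric(0),
                                  area_px = integer(0)),
                labels = matrix(0L, nrow(image), ncol(image)))
  if (all(image <= 0)) return(empty)
  if (is.na(threshold_level)) {
    rng <- range(image)
    if (rng[2L] <= rng[1L]) return(empty)
    threshold_level <- EBImage::otsu(EBImage::Image(image / rng[2L]),
                                     range = c(0, 1)) * rng[2L]
  }
  binary <- (image > threshold_level) * 1
  if (sum(binary) == 0) return(empty)
  dm <- EBImage::distmap(binary)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  n <- max(lab)
  if (n == 0L) return(empty)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[idx]
  area <- tabulate(l, nbins = n)
  keep <- which(area >= min_size_px)
  if (length(keep) == 0L) return(empty)
  out_lab <- matrix(0L, nrow(image), ncol(image))
  cx <- tapply(idx[, 2L] - 1L, l, mean)
  cy <- tapply(idx[, 1L] - 1L, l, mean)
  dots <- data.frame(dot_id = seq_along(keep),
                     centroid_x_px = as.numeric(cx[as.character(keep)]),
                     centroid_y_px = as.numeric(cy[as.character(keep)]),
                     area_px = area[keep])
  for (i in seq_along(keep)) out_lab[lab == keep[i]] <- i
  list(dots = dots, labels = out_lab)
}

#' Assign counted dots to cells
#'
#' With full cell masks, dots are assigned by containment (a dot whose
#' centroid lies in no cell is flagged unassigned). With only nuclei,
#' each dot goes to the cell with the nearest nucleus centroid - a
#' generalized Voronoi assignment; distance ties break to the lower cell
#' id.
#'
#' @param dots The `dots` data.frame from [count_dots()].
#' @param cells Either a cell label image (integer matrix, 0 =
#'   background) used for containment, or `NULL`.
#' @param nuclei A nucleus label image used for nearest-nucleus
#'   assignment when `cells` is `NULL`.
#' @return A list: `dots` (input plus a `cell_id` column; `NA` =
#'   unassigned) and `per_cell` (data.frame `cell_id`, `n_dots`; one row
#'   per cell present in the label image, including zero-count cells).
#' @export
assign_dots_to_cells <- function(dots, cells = NULL, nuclei = NULL) {
  stopifnot(is.data.frame(dots))
  if (is.null(cells) && is.null(nuclei))
    stop("no cells: provide 'cells' masks or a 'nuclei' label image")
  if (!is.null(cells)) {
    lab <- cells
    if (max(lab) == 0L) stop("no cells in the label image")
    cell_id <- vapply(seq_len(nrow(dots)), function(i) {
      yy <- round(dots$centroid_y_px[i]) + 1L
      xx <- round(dots$centroid_x_px[i]) + 1L
      v <- if (yy >= 1L && yy <= nrow(lab) && xx >= 1L && xx <= ncol(lab))
        lab[yy, xx] else 0L
      if (v == 0L) NA_integer_ else as.integer(v)
    }, integer(1))
    all_cells <- sort(setdiff(unique(as.vector(lab)), 0L))
  } else {
    lab <- nuclei
    n <- max(lab)
    if (n == 0L) stop("no cells in the nuclei label image")
    idx <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[idx]
    ncx <- tapply(idx[, 2L] - 1L, l, mean)
    ncy <- tapply(idx[, 1L] - 1L, l, mean)
    ids <- as.integer(names(ncx))
    cell_id <- vapply(seq_len(nrow(dots)), function(i) {
      d <- (as.numeric(ncx) - dots$centroid_x_px[i])^2 +
           (as.numeric(ncy) - dots$centroid_y_px[i])^2
      ids[which.min(d)]  # which.min takes the first = lowest cell id
    }, integer(1))
    all_cells <- sort(ids)
  }
  dots$cell_id <- if (nrow(dots) > 0L) cell_id else integer(0)
  counts <- vapply(all_cells, function(cid) {
    sum(!is.na(dots$cell_id) & dots$cell_id == cid)
  }, integer(1))
  list(dots = dots,
       per_cell = data.frame(cell_id = all_cells, n_dots = counts))
}
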