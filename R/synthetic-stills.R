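#' Synthetic dispersal still with a planted peripheral fraction
#'
#' Places `n_puncta` diffraction-limited puncta inside a cell outline so
#' that a chosen fraction of them (to 1/n granularity) falls in the
#' peripheral shell region (shells `peripheral_from`..`n_shells`) and the
#' rest in the inner region. Puncta are drawn uniformly over the pixels
#' of each region and jittered within their pixel, so the recorded true
#' fraction - computed from the actual placement, not the target - is
#' exactly `round(target * n) / n`.
#'
#' @param outline Outline in um: polygon matrix or disc list (see
#'   [rasterize_outline()]).
#' @param target_peripheral_fraction Desired peripheral fraction in
#'   `[0, 1]`.
#' @param n_puncta Number of puncta.
#' @param seed Integer seed.
#' @param pixel_size_um,psf_sigma_px Optics (defaults 0.1 um/px, 1.3 px).
#' @param step_um,n_shells,peripheral_from Shell geometry (defaults 2 um,
#'   5 shells, peripheral from shell 3).
#' @param amplitude Spot peak intensity (counts).
#' @param background Constant background (counts).
#' @param shape_px Optional frame shape; default fits the outline with a
#'   small margin.
#' @return A list: `image` (matrix), `mask`, `shells` (a `shell_map`),
#'   `puncta` (data.frame `x_px`, `y_px`, `region`, 0-based),
#'   `true_fraction`.
#' @export
make_dispersal_scene <- function(outline, target_peripheral_fraction,
                                 n_puncta, seed = 1,
                                 pixel_size_um = 0.1, psf_sigma_px = 1.3,
                                 step_um = 2, n_shells = 5,
                                 peripheral_from = 3,
                                 amplitude = 300, background = 10,
                                 shape_px = NULL) {
  if (target_peripheral_fraction < 0 || target_peripheral_fraction > 1)
    stop("'target_peripheral_fraction' must be in [0, 1]")
  set.seed(seed)
  if (is.null(shape_px)) {
    if (is.list(outline) && !is.null(outline$radius)) {
      ext <- c(outline$center[2L] + outline$radius,
               outline$center[1L] + outline$radius)
    } else {
      ext <- c(max(outline[, 2L]), max(outline[, 1L]))
    }
    shape_px <- ceiling(ext / pixel_size_um) + 6L
  }
  mask <- rasterize_outline(outline, shape_px, pixel_size_um)
  shells <- build_shells(mask, pixel_size_um, step_um, n_shells)
  outer_px <- which(shells$labels >= peripheral_from)
  inner_px <- which(shells$labels >= 1L & shells$labels < peripheral_from)
  if (length(inner_px) == 0L || length(outer_px) == 0L)
    stop("outline too small to contain ", n_shells, " shells at step ",
         step_um, " um")
  n_outer <- round(target_peripheral_fraction * n_puncta)
  pick <- c(sample(outer_px, n_outer, replace = TRUE),
            sample(inner_px, n_puncta - n_outer, replace = TRUE))
  region <- rep(c("peripheral", "inner"), c(n_outer, n_puncta - n_outer))
  h <- nrow(mask)
  x <- ((pick - 1L) %/% h)          # 0-based column
  y <- ((pick - 1L) %% h)           # 0-based row
  # jitter strictly within the pixel so the true region is unambiguous
  x <- x + stats::runif(n_puncta, -0.49, 0.49)
  y <- y + stats::runif(n_puncta, -0.49, 0.49)
  img <- matrix(background, h, ncol(mask))
  for (i in seq_len(n_puncta)) {
    img <- .add_spot(img, x[i], y[i], amplitude, psf_sigma_px)
  }
  list(image = img, mask = mask, shells = shells,
       puncta = data.frame(x_px = x, y_px = y, region = region),
       true_fraction = n_outer / n_puncta)
}

#' Synthetic proximity-ligation-assay (PLA) image with known dots
#'
#' Renders each requested dot as a filled blob of exactly the requested
#' pixel area (the `area_px` pixels nearest the center, ties broken
#' deterministically). Touching blobs are permitted and flagged in the
#' ground truth; the true countable-dot number applies the minimum-size
#' filter to the planted areas.
#'
#' @param dot_spec A data.frame with columns `x_px`, `y_px` (0-based
#'   centers) and `area_px` (>= 1).
#' @param shape_px Frame shape `c(height, width)` (default 64 x 64).
#' @param intensity Foreground intensity (default 1000).
#' @param min_size_px Size filter used for the true count (default 5).
#' @return A list: `image` (matrix), `dots` (data.frame `dot_id`, `x_px`,
#'   `y_px`, `area_px`, `touching`), `true_count`.
#' @export
make_pla_scene <- function(dot_spec, shape_px = c(64L, 64L),
                           intensity = 1000, min_size_px = 5) {
  stopifnot(is.data.frame(dot_spec),
            all(c("x_px", "y_px", "area_px") %in% names(dot_spec)))
  n <- nrow(dot_spec)
  h <- shape_px[1L]; w <- shape_px[2L]
  img <- matrix(0, h, w)
  if (n == 0L) {
    return(list(image = img,
                dots = data.frame(dot_id = integer(0), x_px = numeric(0),
                                  y_px = numeric(0), area_px = integer(0),
                                  touching = logical(0)),
                true_count = 0L))
  }
  if (any(dot_spec$area_px < 1))
    stop("dot area must be >= 1 px")
  if (any(dot_spec$x_px < 0 | dot_spec$x_px > w - 1 |
          dot_spec$y_px < 0 | dot_spec$y_px > h - 1))
    stop("dot center outside the frame")
  gx <- rep(0:(w - 1L), each = h)
  gy <- rep(0:(h - 1L), times = w)
  pix_sets <- vector("list", n)
  for (i in seq_len(n)) {
    d <- (gx - dot_spec$x_px[i])^2 + (gy - dot_spec$y_px[i])^2
    ord <- order(d, gy, gx)[seq_len(dot_spec$area_px[i])]
    pix_sets[[i]] <- ord
    img[ord] <- intensity
  }
  # touching = the 8-dilated footprint of one dot meets another dot
  touching <- logical(n)
  for (i in seq_len(n)) {
    xi <- gx[pix_sets[[i]]]; yi <- gy[pix_sets[[i]]]
    others <- unlist(pix_sets[-i])
    if (length(others) == 0L) next
    xo <- gx[others]; yo <- gy[others]
    touching[i] <- any(outer(xi, xo, function(a, b) abs(a - b)) <= 1 &
                       outer(yi, yo, function(a, b) abs(a - b)) <= 1)
  }
  list(image = img,
       dots = data.frame(dot_id = seq_len(n), x_px = dot_spec$x_px,
                         y_px = dot_spec$y_px,
                         area_px = dot_spec$area_px, touching = touching),
       true_count = sum(dot_spec$area_px >= min_size_px))
}
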