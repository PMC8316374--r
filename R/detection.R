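# 8-connected labeling. EBImage::bwlabel is 4-connected; labels touching
# diagonally are merged with a union-find pass over the four diagonal
# offsets.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  h <- nrow(lab); w <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    dy <- off[1L]; dx <- off[2L]
    ys <- seq_len(h - 1L)
    xs <- if (dx > 0L) seq_len(w - 1L) else 2:w
    a <- lab[ys, xs, drop = FALSE]
    b <- lab[ys + dy, xs + dx, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

# Integrated 2-D Gaussian model over pixels (0-based coordinates xs, ys).
.ig_model <- function(xs, ys, x0, y0, A, b, sigma) {
  dx <- stats::pnorm((xs + 0.5 - x0) / sigma) -
        stats::pnorm((xs - 0.5 - x0) / sigma)
  dy <- stats::pnorm((ys + 0.5 - y0) / sigma) -
        stats::pnorm((ys - 0.5 - y0) / sigma)
  b + A * 2 * pi * sigma^2 * dy * dx
}

# Fit 1 or 2 integrated Gaussians to a window. 'win' is a data.frame with
# xs, ys (0-based) and z. Returns a list of fits (x, y, A, b, sigma,
# residual) or NULL if the fit fails to converge.
.fit_gaussians <- function(win, starts, sigma0, shared_b = NULL) {
  k <- nrow(starts)
  b0 <- if (is.null(shared_b)) stats::median(win$z) else shared_b
  a0 <- pmax(max(win$z) - b0, 1e-3)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- try({
    if (k == 1L) {
      minpack.lm::nlsLM(
        z ~ .ig_model(xs, ys, x0, y0, A, b, s),
        data = win,
        start = list(x0 = starts$x[1L], y0 = starts$y[1L],
                     A = a0, b = b0, s = sigma0),
        lower = c(min(win$xs) - 1, min(win$ys) - 1, 0, 0, 0.3),
        upper = c(max(win$xs) + 1, max(win$ys) + 1, Inf, Inf, 4 * sigma0),
        control = ctrl)
    } else {
      minpack.lm::nlsLM(
        z ~ .ig_model(xs, ys, x1, y1, A1, 0, s) +
            .ig_model(xs, ys, x2, y2, A2, b, s),
        data = win,
        start = list(x1 = starts$x[1L], y1 = starts$y[1L],
                     x2 = starts$x[2L], y2 = starts$y[2L],
                     A1 = a0, A2 = a0, b = b0, s = sigma0),
        lower = c(rep(c(min(win$xs) - 1, min(win$ys) - 1), 2L),
                  0, 0, 0, 0.3),
        upper = c(rep(c(max(win$xs) + 1, max(win$ys) + 1), 2L),
                  Inf, Inf, Inf, 4 * sigma0),
        control = ctrl)
    }
  }, silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  if (k == 1L) {
    list(list(x = cf[["x0"]], y = cf[["y0"]], A = cf[["A"]], b = cf[["b"]],
              sigma = cf[["s"]], residual = rmse / max(cf[["A"]], 1e-9)))
  } else {
    lapply(1:2, function(i) {
      list(x = cf[[paste0("x", i)]], y = cf[[paste0("y", i)]],
           A = cf[[paste0("A", i)]], b = cf[["b"]], sigma = cf[["s"]],
           residual = rmse / max(cf[[paste0("A", i)]], 1e-9))
    })
  }
}

#' Detect fluorescent puncta with sub-pixel centers
#'
#' Band-pass filters each frame (difference of Gaussians at the expected
#' spot scale), finds local maxima above an amplitude threshold, and fits
#' an integrated 2-D Gaussian to a window around each candidate. When the
#' single-Gaussian fit leaves a relative residual above
#' `max_fit_residual` and a secondary intensity maximum exists in the
#' window, a two-Gaussian fit resolves the pair. Only converged fits are
#' returned; coordinates are 0-based with pixel centers at integers.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param params List of detector settings: `min_amplitude` (counts above
#'   local background; `NA` = 5 x the frame's robust background sd),
#'   `expected_sigma_px` (PSF sigma used for filtering and fit
#'   initialization), `max_fit_residual` (relative RMSE triggering the
#'   two-Gaussian branch and rejecting bad fits).
#' @param frames Optional subset of frames (0-based). Default: all.
#' @return A data.frame with columns `frame`, `channel`, `x_px`, `y_px`,
#'   `x_um`, `y_um`, `amplitude`, `sigma_px`, `background`, `residual`.
#'   Empty (0 rows) when nothing is found.
#' @export
detect_spots <- function(stack, channel = 1L,
                         params = list(), frames = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  p <- list(min_amplitude = NA_real_, expected_sigma_px = 1.3,
            max_fit_residual = 0.15)
  p[names(params)] <- params
  if (!is.na(p$min_amplitude) && p$min_amplitude <= 0)
    stop("'min_amplitude' must be positive")
  if (p$expected_sigma_px <= 0) stop("'expected_sigma_px' must be positive")
  ci <- .channel_index(stack, channel)
  d <- dim(stack$data)
  if (is.null(frames)) frames <- 0:(d[1L] - 1L)
  sigma <- p$expected_sigma_px
  hw <- max(3L, ceiling(3 * sigma))  # fit window half-width

  # attenuation of a unit-amplitude spot through the DoG filter, so the
  # candidate threshold can be stated in amplitude units
  pr <- max(2L * hw, ceiling(10 * sigma), 20L)
  probe <- matrix(0, 2L * pr + 1L, 2L * pr + 1L)
  probe <- .add_spot(probe, pr, pr, 1, sigma)
  dog_probe <- as.matrix(EBImage::gblur(EBImage::Image(probe), sigma)) -
    as.matrix(EBImage::gblur(EBImage::Image(probe), 2.5 * sigma))
  dog_gain <- max(dog_probe)

  out <- vector("list", length(frames))
  empty <- data.frame(frame = integer(0), channel = character(0),
                      x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      amplitude = numeric(0), sigma_px = numeric(0),
                      background = numeric(0), residual = numeric(0))
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    img <- get_frame(stack, t + 1L, ci)
    if (any(!is.finite(img))) stop("non-finite pixels in frame ", t)
    h <- nrow(img); w <- ncol(img)
    min_amp <- if (is.na(p$min_amplitude)) {
      5 * stats::mad(img)
    } else p$min_amplitude
    if (min_amp <= 0) min_amp <- 5 * stats::sd(img)
    ei <- EBImage::Image(img)
    dog <- as.matrix(EBImage::gblur(ei, sigma)) -
      as.matrix(EBImage::gblur(ei, 2.5 * sigma))
    mx <- as.matrix(EBImage::dilate(dog, EBImage::makeBrush(3L, "box")))
    cand <- which(dog >= mx - 1e-12 & dog > dog_gain * min_amp,
                  arr.ind = TRUE)
    if (nrow(cand) == 0L) { out[[fi]] <- empty; next }
    # 0-based candidate coordinates, brightest first
    cy <- cand[, 1L] - 1L; cx <- cand[, 2L] - 1L
    ord <- order(dog[cand], decreasing = TRUE)
    cy <- cy[ord]; cx <- cx[ord]

    dets <- list()
    for (i in seq_along(cx)) {
      x0 <- max(0L, cx[i] - hw); x1 <- min(w - 1L, cx[i] + hw)
      y0 <- max(0L, cy[i] - hw); y1 <- min(h - 1L, cy[i] + hw)
      g <- expand.grid(ys = y0:y1, xs = x0:x1)
      g$z <- as.vector(img[(y0:y1) + 1L, (x0:x1) + 1L])
      fits <- .fit_gaussians(g, data.frame(x = cx[i], y = cy[i]), sigma)
      if (is.null(fits)) next
      if (fits[[1L]]$residual > p$max_fit_residual) {
        # secondary maximum in the window (excluding the primary)?
        starts2 <- NULL
        sec <- which(dog[(y0:y1) + 1L, (x0:x1) + 1L] ==
                       mx[(y0:y1) + 1L, (x0:x1) + 1L], arr.ind = TRUE)
        if (nrow(sec) > 0L) {
          sx <- sec[, 2L] - 1L + x0; sy <- sec[, 1L] - 1L + y0
          far <- (sx - cx[i])^2 + (sy - cy[i])^2 > 1
          if (any(far)) {
            sx <- sx[far]; sy <- sy[far]
            j <- which.max(dog[cbind(sy + 1L, sx + 1L)])
            starts2 <- data.frame(x = c(cx[i], sx[j]), y = c(cy[i], sy[j]))
          }
        }
        if (is.null(starts2)) {
          # merged pair with a single maximum: split the start positions
          # along the window's principal intensity axis
          zb <- pmax(g$z - stats::median(g$z), 0)
          if (sum(zb) > 0) {
            mx0 <- sum(g$xs * zb) / sum(zb)
            my0 <- sum(g$ys * zb) / sum(zb)
            cxx <- sum((g$xs - mx0)^2 * zb) / sum(zb)
            cyy <- sum((g$ys - my0)^2 * zb) / sum(zb)
            cxy <- sum((g$xs - mx0) * (g$ys - my0) * zb) / sum(zb)
            ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L))$vectors[, 1L]
            off <- 1.5 * ev
            starts2 <- data.frame(x = mx0 + c(off[1L], -off[1L]),
                                  y = my0 + c(off[2L], -off[2L]))
          }
        }
        if (!is.null(starts2)) {
          two <- .fit_gaussians(g, starts2, sigma)
          if (!is.null(two) &&
              two[[1L]]$residual < fits[[1L]]$residual) fits <- two
        }
      }
      for (f in fits) {
        if (!all(is.finite(c(f$x, f$y, f$A))) || f$A < min_amp / 2) next
        if (f$x < 0 || f$x > w - 1 || f$y < 0 || f$y > h - 1) next
        if (f$residual > p$max_fit_residual) next
        dets[[length(dets) + 1L]] <- f
      }
    }
    if (length(dets) == 0L) { out[[fi]] <- empty; next }
    df <- data.frame(
      frame = t, channel = stack$channel_names[ci],
      x_px = vapply(dets, `[[`, numeric(1), "x"),
      y_px = vapply(dets, `[[`, numeric(1), "y"),
      amplitude = vapply(dets, `[[`, numeric(1), "A"),
      sigma_px = vapply(dets, `[[`, numeric(1), "sigma"),
      background = vapply(dets, `[[`, numeric(1), "b"),
      residual = vapply(dets, `[[`, numeric(1), "residual"))
    # deduplicate fits closer than 1 px, keeping the better residual
    df <- df[order(df$residual), ]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!keep[i]) next
      if (i < nrow(df)) {
        ii <- (i + 1L):nrow(df)
        close <- (df$x_px[ii] - df$x_px[i])^2 +
          (df$y_px[ii] - df$y_px[i])^2 < 1
        keep[ii][close] <- FALSE
      }
    }
    df <- df[keep, ]
    df$x_um <- df$x_px * stack$pixel_size_um
    df$y_um <- df$y_px * stack$pixel_size_um
    out[[fi]] <- df[, names(empty)]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Threshold bright accumulations above a structured background
#'
#' Produces per-frame binary masks of regions brighter than a chosen
#' level, used to isolate high-intensity ER-protein accumulations from
#' the dimmer reticular ER signal. The default method takes a percentile
#' of the intensity distribution of the structured (above-background)
#' region of each frame, after removing the smooth background with a
#' morphological opening.
#'
#' @param stack An [image_stack()] (or a single matrix, treated as one
#'   frame).
#' @param channel Channel name or index.
#' @param method `"percentile"` (default), `"otsu"` or `"absolute"`.
#' @param level Percentile in (0, 100) for `"percentile"`; absolute
#'   intensity (>= 0) for `"absolute"`; ignored for `"otsu"`.
#' @param bg_radius Radius (px) of the opening brush used to estimate the
#'   smooth background for the percentile method (default 5).
#' @param frames Optional 0-based frame subset.
#' @return An object of class `accumulation_mask`: a list with `masks`
#'   (list of logical y-by-x matrices, one per requested frame), `frames`,
#'   `channel`, `method`, `level`.
#' @export
threshold_accumulations <- function(stack, channel = 1L,
                                    method = c("percentile", "otsu",
                                               "absolute"),
                                    level = 99, bg_radius = 5,
                                    frames = NULL) {
  method <- match.arg(method)
  if (is.matrix(stack)) stack <- image_stack(stack, pixel_size_um = 1)
  stopifnot(inherits(stack, "image_stack"))
  if (method == "percentile" && (level <= 0 || level >= 100))
    stop("'level' must be in (0, 100) for the percentile method")
  if (method == "absolute" && level < 0)
    stop("'level' must be >= 0 for the absolute method")
  ci <- .channel_index(stack, channel)
  d <- dim(stack$data)
  if (is.null(frames)) frames <- 0:(d[1L] - 1L)
  brush_size <- 2L * as.integer(bg_radius) + 1L
  masks <- lapply(frames, function(t) {
    img <- get_frame(stack, t + 1L, ci)
    thr <- switch(method,
      absolute = level,
      otsu = {
        rng <- range(img)
        if (rng[2L] <= rng[1L])
          stop("degenerate threshold: frame ", t, " is uniform; ",
               "otsu is undefined")
        lv <- EBImage::otsu(EBImage::Image(img / rng[2L]),
                            range = c(0, 1)) * rng[2L]
        lv
      },
      percentile = {
        bg <- as.matrix(EBImage::opening(
          EBImage::Image(img), EBImage::makeBrush(brush_size, "disc")))
        structured <- img[img - bg > 1e-9 & img > 0]
        if (length(structured) == 0L) structured <- img[img > 0]
        if (length(structured) == 0L) return(matrix(FALSE, d[3L], d[4L]))
        stats::quantile(structured, level / 100, names = FALSE)
      })
    if (method == "absolute" && level == 0) img >= 0 else img > thr
  })
  structure(list(masks = masks, frames = frames,
                 channel = stack$channel_names[ci],
                 method = method, level = level),
            class = "accumulation_mask")
}

#' Label connected objects in a binary mask
#'
#' 8-connected component labeling with an object table.
#'
#' @param mask A logical (or 0/1) matrix.
#' @return A list with `labels` (integer matrix, 0 = background) and
#'   `objects` (data.frame `label`, `area_px`, `centroid_x_px`,
#'   `centroid_y_px`, 0-based, sorted by label).
#' @export
segment_objects <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1
  stopifnot(is.matrix(mask))
  lab <- .label8(mask)
  n <- max(lab)
  if (n == 0L) {
    return(list(labels = lab,
                objects = data.frame(label = integer(0),
                                     area_px = integer(0),
                                     centroid_x_px = numeric(0),
                                     centroid_y_px = numeric(0))))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[idx]
  area <- tabulate(l, nbins = n)
  cx <- tapply(idx[, 2L] - 1L, l, mean)
  cy <- tapply(idx[, 1L] - 1L, l, mean)
  list(labels = lab,
       objects = data.frame(label = seq_len(n), area_px = area,
                            centroid_x_px = as.numeric(cx),
                            centroid_y_px = as.numeric(cy)))
}
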