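#' @keywords internal
# Minimum distance from points to a polyline segment set.
# pts: n x 2; segs: list of m x 2 polyline matrices. Returns n distances.
.dist_to_polylines <- function(pts, polylines) {
  n <- nrow(pts)
  dmin <- rep(Inf, n)
  for (pl in polylines) {
    pl <- as.matrix(pl)
    if (nrow(pl) == 1L) {
      d <- sqrt((pts[, 1L] - pl[1L, 1L])^2 + (pts[, 2L] - pl[1L, 2L])^2)
      dmin <- pmin(dmin, d)
      next
    }
    for (s in seq_len(nrow(pl) - 1L)) {
      p <- pl[s, ]; q <- pl[s + 1L, ]
      v <- q - p
      L2 <- sum(v^2)
      if (L2 == 0) stop("zero-length polyline segment")
      t <- ((pts[, 1L] - p[1L]) * v[1L] + (pts[, 2L] - p[2L]) * v[2L]) / L2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((pts[, 1L] - p[1L] - t * v[1L])^2 +
                (pts[, 2L] - p[2L] - t * v[2L])^2)
      dmin <- pmin(dmin, d)
    }
  }
  dmin
}

# TRUE when the closed polygon self-intersects (non-adjacent edges cross).
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), ]
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]   # edge n is adjacent to edge 1
    if (length(js) == 0L) next
    d1 <- cross(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L],
                a[js, 1L], a[js, 2L])
    d2 <- cross(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L],
                b[js, 1L], b[js, 2L])
    d3 <- cross(a[js, 1L], a[js, 2L], b[js, 1L], b[js, 2L],
                rep(a[i, 1L], length(js)), rep(a[i, 2L], length(js)))
    d4 <- cross(a[js, 1L], a[js, 2L], b[js, 1L], b[js, 2L],
                rep(b[i, 1L], length(js)), rep(b[i, 2L], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Resample a closed polygon boundary at arc spacing <= step.
# Returns list(pts = n x 2 samples in boundary order, perimeter).
.resample_polygon <- function(poly, step) {
  n <- nrow(poly)
  nxt <- poly[c(2:n, 1L), ]
  elen <- sqrt(rowSums((nxt - poly)^2))
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    k <- max(1L, ceiling(elen[i] / step))
    f <- (0:(k - 1L)) / k
    pts[[i]] <- cbind(poly[i, 1L] + f * (nxt[i, 1L] - poly[i, 1L]),
                      poly[i, 2L] + f * (nxt[i, 2L] - poly[i, 2L]))
  }
  list(pts = do.call(rbind, pts), perimeter = sum(elen))
}

#' Measure EL perimeter and ER contact length in one EM section
#'
#' Resamples the endolysosome (EL) boundary polygon at steps of at most
#' `resample_step_nm`, computes each boundary sample's minimum distance
#' to the ER polylines (curve to curve, matching membrane-to-membrane
#' apposition), and sums the boundary arc length lying within
#' `cutoff_nm`. Partially inside arcs are counted fractionally by linear
#' interpolation of the distance at the crossing. The perimeter is the
#' exact polygon perimeter.
#'
#' @param el_polygon Closed, simple polygon (n x 2 matrix, nm; >= 3
#'   vertices; do not repeat the first vertex).
#' @param er_polylines List of polylines (m x 2 matrices, nm); may be
#'   empty (contact length 0).
#' @param cutoff_nm Apposition cutoff in nm (default 30).
#' @param resample_step_nm Boundary resampling step in nm (default 5).
#' @return Named numeric vector `c(perimeter_nm, contact_nm)`.
#' @export
measure_section <- function(el_polygon, er_polylines, cutoff_nm = 30,
                            resample_step_nm = 5) {
  el_polygon <- as.matrix(el_polygon)
  if (nrow(el_polygon) < 3L) stop("EL polygon needs >= 3 vertices")
  if (cutoff_nm <= 0) stop("'cutoff_nm' must be > 0")
  if (any(!is.finite(el_polygon))) stop("non-finite polygon coordinates")
  if (.polygon_self_intersects(el_polygon))
    stop("EL polygon is self-intersecting")
  rs <- .resample_polygon(el_polygon, resample_step_nm)
  if (length(er_polylines) == 0L) {
    return(c(perimeter_nm = rs$perimeter, contact_nm = 0))
  }
  pts <- rs$pts
  n <- nrow(pts)
  d <- .dist_to_polylines(pts, er_polylines)
  nxt <- c(2:n, 1L)
  ds <- sqrt((pts[nxt, 1L] - pts[, 1L])^2 + (pts[nxt, 2L] - pts[, 2L])^2)
  d2 <- d[nxt]
  inside1 <- d <= cutoff_nm
  inside2 <- d2 <= cutoff_nm
  frac <- numeric(n)
  frac[inside1 & inside2] <- 1
  cross <- xor(inside1, inside2)
  if (any(cross)) {
    di <- ifelse(inside1[cross], d[cross], d2[cross])
    do <- ifelse(inside1[cross], d2[cross], d[cross])
    frac[cross] <- (cutoff_nm - di) / (do - di)
  }
  contact <- min(sum(frac * ds), rs$perimeter)
  c(perimeter_nm = rs$perimeter, contact_nm = contact)
}

#' Aggregate per-section measurements for one EL
#'
#' Sums perimeters and contact lengths across all sections capturing the
#' same endolysosome, then divides - percentages are never averaged
#' across sections.
#'
#' @param sections A data.frame with columns `perimeter_nm` and
#'   `contact_nm` (one row per section), e.g. rows of
#'   [measure_section()] output.
#' @param el_id Identifier copied to the result.
#' @return A data.frame row: `el_id`, `n_sections`, `perimeter_nm`
#'   (summed), `contact_nm` (summed), `percent`.
#' @export
el_contact_percent <- function(sections, el_id = NA) {
  stopifnot(is.data.frame(sections),
            all(c("perimeter_nm", "contact_nm") %in% names(sections)))
  if (nrow(sections) == 0L) stop("no sections for EL ", el_id)
  P <- sum(sections$perimeter_nm)
  C <- sum(sections$contact_nm)
  if (P <= 0) stop("zero summed perimeter for EL ", el_id)
  data.frame(el_id = el_id, n_sections = nrow(sections),
             perimeter_nm = P, contact_nm = C, percent = 100 * C / P)
}

#' Per-cell mean of EL contact percentages
#'
#' @param em_results A data.frame with a `percent` column (one row per
#'   EL), e.g. stacked [el_contact_percent()] rows.
#' @param cell A vector assigning each EL to a cell; `NA` (unassigned)
#'   is an error.
#' @return A data.frame: `cell_id`, `n_el`, `mean_percent` (unweighted
#'   mean over the cell's ELs).
#' @export
per_cell_mean <- function(em_results, cell) {
  stopifnot(is.data.frame(em_results), "percent" %in% names(em_results))
  if (length(cell) != nrow(em_results))
    stop("'cell' must assign every EL")
  if (any(is.na(cell))) stop("unassigned EL (NA cell id)")
  agg <- tapply(em_results$percent, cell, mean)
  out <- data.frame(cell_id = names(agg), n_el = as.integer(table(cell)),
                    mean_percent = as.numeric(agg))
  rownames(out) <- NULL
  out
}

#' Measure an EM contour set end to end
#'
#' Convenience wrapper: runs [measure_section()] on every (section, EL)
#' combination of a contour table, aggregates with
#' [el_contact_percent()], and returns one row per EL.
#'
#' @param contours A contour data.frame in the exchange schema
#'   (`section_id`, `object_type` in `{EL, ER}`, `object_id`,
#'   `vertex_index`, `x_nm`, `y_nm`, `closed`).
#' @param cutoff_nm,resample_step_nm Passed to [measure_section()].
#' @return A data.frame with one [el_contact_percent()] row per EL id.
#' @export
measure_contour_set <- function(contours, cutoff_nm = 30,
                                resample_step_nm = 5) {
  req <- c("section_id", "object_type", "object_id", "vertex_index",
           "x_nm", "y_nm", "closed")
  stopifnot(is.data.frame(contours), all(req %in% names(contours)))
  el_ids <- sort(unique(contours$object_id[contours$object_type == "EL"]))
  rows <- lapply(el_ids, function(id) {
    sel <- contours$object_type == "EL" & contours$object_id == id
    secs <- sort(unique(contours$section_id[sel]))
    meas <- do.call(rbind, lapply(secs, function(s) {
      poly <- contours[sel & contours$section_id == s, ]
      poly <- poly[order(poly$vertex_index), c("x_nm", "y_nm")]
      er_rows <- contours[contours$object_type == "ER" &
                            contours$section_id == s, ]
      ers <- lapply(split(er_rows, er_rows$object_id), function(e) {
        as.matrix(e[order(e$vertex_index), c("x_nm", "y_nm")])
      })
      as.data.frame(t(measure_section(as.matrix(poly), ers, cutoff_nm,
                                      resample_step_nm)))
    }))
    el_contact_percent(meas, el_id = id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
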