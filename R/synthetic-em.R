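# Union length of angular intervals on the circle, in radians.
# 'ints' is a 2-column matrix of (start, end) with end >= start; intervals
# may extend beyond [0, 2pi) and are wrapped.
.arc_union <- function(ints) {
  if (nrow(ints) == 0L) return(0)
  pieces <- list()
  for (i in seq_len(nrow(ints))) {
    a <- ints[i, 1L]; b <- ints[i, 2L]
    if (b - a >= 2 * pi) return(2 * pi)
    a <- a %% (2 * pi); b <- a + (ints[i, 2L] - ints[i, 1L])
    if (b <= 2 * pi) {
      pieces[[length(pieces) + 1L]] <- c(a, b)
    } else {
      pieces[[length(pieces) + 1L]] <- c(a, 2 * pi)
      pieces[[length(pieces) + 1L]] <- c(0, b - 2 * pi)
    }
  }
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1L]), , drop = FALSE]
  total <- 0; cur <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], m[i, 2L])
    } else {
      total <- total + (cur[2L] - cur[1L]); cur <- m[i, ]
    }
  }
  total + (cur[2L] - cur[1L])
}

#' Closed-form percent of a circle within a cutoff of straight lines
#'
#' For a circle of radius `R` and a set of infinite straight lines, the
#' set of boundary points within `cutoff` of a line at distance `d` from
#' the center is determined by `cos(a) in [(d - cutoff)/R,
#' (d + cutoff)/R]` for the angle `a` between the boundary point and the
#' perpendicular from the center to the line. The union of the resulting
#' arcs over all lines, divided by the full circle, gives the analytic
#' contact fraction.
#'
#' @param radius Circle radius (nm).
#' @param lines List of lines, each a list `list(point = c(x, y),
#'   dir = c(dx, dy))` through `point` with direction `dir`, relative to
#'   a circle centred at the origin.
#' @param cutoff Distance cutoff (nm).
#' @return Percent of the circle boundary within `cutoff` of any line.
#' @export
circle_line_contact_percent <- function(radius, lines, cutoff) {
  if (length(lines) == 0L) return(0)
  ints <- list()
  for (ln in lines) {
    u <- ln$dir / sqrt(sum(ln$dir^2))
    nrm <- c(-u[2L], u[1L])
    s <- sum((ln$point) * nrm)      # signed distance of line from origin
    d <- abs(s)
    phi0 <- if (d > 0) atan2(sign(s) * nrm[2L], sign(s) * nrm[1L])
            else atan2(nrm[2L], nrm[1L])
    lo <- (d - cutoff) / radius
    hi <- (d + cutoff) / radius
    if (lo > 1 || hi < -1) next
    lo_c <- max(lo, -1); hi_c <- min(hi, 1)
    a1 <- acos(hi_c); a2 <- acos(lo_c)   # 0 <= a1 <= a2 <= pi
    ints[[length(ints) + 1L]] <- c(phi0 + a1, phi0 + a2)
    ints[[length(ints) + 1L]] <- c(phi0 - a2, phi0 - a1)
    if (d == 0) {  # line through the center: the opposite side too
      ints[[length(ints) + 1L]] <- c(phi0 + pi + a1, phi0 + pi + a2)
      ints[[length(ints) + 1L]] <- c(phi0 + pi - a2, phi0 + pi - a1)
    }
  }
  if (length(ints) == 0L) return(0)
  100 * .arc_union(do.call(rbind, ints)) / (2 * pi)
}

#' Build a synthetic EM section geometry with an analytic contact percent
#'
#' Produces a traced-contour table (the flat exchange schema used for
#' hand-traced EM data) for one endolysosome plus ER elements, and - for
#' circle-and-straight-line geometries - the closed-form percentage of
#' the EL boundary within the cutoff of the ER, against which the
#' measurement pipeline can be validated.
#'
#' @param el Either `list(center = c(x, y), radius = r)` (nm; polygonized
#'   circle) or a polygon matrix (nm).
#' @param er List of ER elements: polyline matrices (m x 2, nm). A
#'   one-row matrix is invalid; segments must have positive length.
#' @param cutoff_nm Apposition cutoff used for the analytic percent
#'   (default 30).
#' @param section_id Section identifier (default 1).
#' @param el_id,circle_vertices Object id for the EL and number of
#'   vertices used to polygonize a circle (default 720).
#' @return A list: `contours` (exchange-schema data.frame),
#'   `analytic_percent` (closed form for circle + straight 2-point
#'   lines, otherwise `NA`), `el`, `er`.
#' @export
make_em_scene <- function(el, er = list(), cutoff_nm = 30, section_id = 1L,
                          el_id = 1L, circle_vertices = 720L) {
  is_circle <- is.list(el) && !is.null(el$radius)
  if (is_circle) {
    if (el$radius <= 0) stop("circle radius must be > 0")
    th <- 2 * pi * (0:(circle_vertices - 1L)) / circle_vertices
    poly <- cbind(el$center[1L] + el$radius * cos(th),
                  el$center[2L] + el$radius * sin(th))
  } else {
    poly <- as.matrix(el)
    if (nrow(poly) < 3L) stop("EL polygon needs >= 3 vertices")
  }
  for (pl in er) {
    pl <- as.matrix(pl)
    if (nrow(pl) >= 2L) {
      seg <- diff(pl)
      if (any(rowSums(seg^2) == 0)) stop("zero-length polyline segment")
    } else stop("ER polyline needs >= 2 vertices")
  }
  rows <- list(data.frame(section_id = section_id, object_type = "EL",
                          object_id = el_id,
                          vertex_index = seq_len(nrow(poly)) - 1L,
                          x_nm = poly[, 1L], y_nm = poly[, 2L],
                          closed = 1L))
  for (i in seq_along(er)) {
    pl <- as.matrix(er[[i]])
    rows[[length(rows) + 1L]] <-
      data.frame(section_id = section_id, object_type = "ER",
                 object_id = i, vertex_index = seq_len(nrow(pl)) - 1L,
                 x_nm = pl[, 1L], y_nm = pl[, 2L], closed = 0L)
  }
  analytic <- NA_real_
  straight <- all(vapply(er, function(pl) nrow(as.matrix(pl)) == 2L,
                         logical(1)))
  if (is_circle && straight) {
    lines <- lapply(er, function(pl) {
      pl <- as.matrix(pl)
      list(point = pl[1L, ] - el$center, dir = pl[2L, ] - pl[1L, ])
    })
    analytic <- circle_line_contact_percent(el$radius, lines, cutoff_nm)
  }
  if (is_circle && length(er) == 0L) analytic <- 0
  list(contours = do.call(rbind, rows), analytic_percent = analytic,
       el = el, er = er)
}

#' Write / read EM contour tables
#'
#' The exchange schema is a flat CSV with columns `section_id`,
#' `object_type` (`EL`/`ER`), `object_id`, `vertex_index`, `x_nm`,
#' `y_nm`, `closed` (0/1), so traces exported from any annotation tool
#' can be analyzed.
#'
#' @param contours A contour data.frame.
#' @param path CSV path.
#' @return `write_em_contours`: `path`, invisibly. `read_em_contours`:
#'   the contour data.frame.
#' @export
write_em_contours <- function(contours, path) {
  utils::write.csv(contours, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_em_contours
#' @export
read_em_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("section_id", "object_type", "object_id", "vertex_index",
           "x_nm", "y_nm", "closed")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L)
    stop("contour table missing column(s): ",
         paste(missing, collapse = ", "))
  df
}
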