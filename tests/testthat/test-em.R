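# dense point-sampling oracle: fraction of circle boundary within the
# cutoff of a set of polylines
circle_sampling_oracle <- function(radius, polylines, cutoff,
                                   n = 2e5) {
  th <- 2 * pi * (0:(n - 1)) / n
  pts <- cbind(radius * cos(th), radius * sin(th))
  d <- eltrack:::.dist_to_polylines(pts, polylines)
  100 * mean(d <= cutoff)
}

square_el <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))

test_that("no ER means zero contact at full perimeter", {
  m <- measure_section(square_el, list())
  expect_equal(unname(m["perimeter_nm"]), 4000)
  expect_equal(unname(m["contact_nm"]), 0)
})

test_that("an ER segment coincident with one side contacts that side", {
  er <- list(rbind(c(0, 0), c(1000, 0)))
  m <- measure_section(square_el, er, cutoff_nm = 30)
  # the full side, plus up to the 30 nm cutoff around each corner
  expect_gte(unname(m["contact_nm"]), 1000)
  expect_lte(unname(m["contact_nm"]), 1000 + 2 * 30 + 5)
})

test_that("tangent-line geometry matches closed form and sampling", {
  R <- 250; cutoff <- 30
  er <- list(rbind(c(-5000, R), c(5000, R)))  # tangent at (0, R)
  sc <- make_em_scene(list(center = c(0, 0), radius = R), er,
                      cutoff_nm = cutoff)
  closed_form <- 100 * acos((R - cutoff) / R) / pi
  expect_equal(sc$analytic_percent, closed_form, tolerance = 1e-9)
  oracle <- circle_sampling_oracle(R, er, cutoff)
  res <- measure_contour_set(sc$contours, cutoff_nm = cutoff)
  expect_lt(abs(res$percent - oracle) / oracle, 0.01)
  expect_lt(abs(res$percent - closed_form) / closed_form, 0.01)
})

test_that("a line through the center matches the sampling oracle", {
  R <- 250
  er <- list(rbind(c(-5000, 0), c(5000, 0)))
  sc <- make_em_scene(list(center = c(0, 0), radius = R), er)
  oracle <- circle_sampling_oracle(R, er, 30)
  expect_equal(sc$analytic_percent, oracle, tolerance = 0.01)
  res <- measure_contour_set(sc$contours)
  expect_lt(abs(res$percent - oracle) / oracle, 0.01)
})

test_that("per-EL aggregation sums before dividing", {
  secs <- data.frame(perimeter_nm = c(1000, 3000),
                     contact_nm = c(100, 0))
  row <- el_contact_percent(secs, el_id = "el1")
  expect_equal(row$percent, 2.5)   # 100/4000 x 100, not mean(10%, 0%)
  full <- el_contact_percent(data.frame(perimeter_nm = 500,
                                        contact_nm = 500))
  expect_equal(full$percent, 100)
  expect_error(el_contact_percent(data.frame(perimeter_nm = 0,
                                             contact_nm = 0)), "zero")
})

test_that("per-cell means are unweighted and order-invariant", {
  res <- data.frame(el_id = 1:4, percent = c(2, 4, 10, 20))
  cells <- c("a", "a", "b", "b")
  pc <- per_cell_mean(res, cells)
  expect_equal(pc$mean_percent[pc$cell_id == "a"], 3)
  expect_equal(pc$mean_percent[pc$cell_id == "b"], 15)
  perm <- sample(4)
  pc2 <- per_cell_mean(res[perm, ], cells[perm])
  expect_equal(pc2[order(pc2$cell_id), ], pc[order(pc$cell_id), ])
  expect_error(per_cell_mean(res, c("a", NA, "b", "b")), "unassigned")
})

test_that("measurements are invariant under rigid motion", {
  R <- 250
  er <- list(rbind(c(-2000, 180), c(2000, 180)))
  sc <- make_em_scene(list(center = c(0, 0), radius = R), er)
  base <- measure_contour_set(sc$contours)$percent
  th <- 0.71; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(12345, -6789)
  moved <- sc$contours
  xy <- as.matrix(moved[, c("x_nm", "y_nm")]) %*% t(rot)
  moved$x_nm <- xy[, 1] + shift[1]; moved$y_nm <- xy[, 2] + shift[2]
  expect_equal(measure_contour_set(moved)$percent, base,
               tolerance = 1e-6)
})

test_that("contact length grows with cutoff and converges under refinement", {
  R <- 250
  er <- list(rbind(c(-2000, 180), c(2000, 180)))
  poly <- make_em_scene(list(center = c(0, 0), radius = R), er)$contours
  poly <- as.matrix(poly[poly$object_type == "EL", c("x_nm", "y_nm")])
  cuts <- c(10, 20, 30, 50, 80)
  lens <- vapply(cuts, function(co) {
    unname(measure_section(poly, er, cutoff_nm = co)["contact_nm"])
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
  c5 <- unname(measure_section(poly, er, resample_step_nm = 5)["contact_nm"])
  c2.5 <- unname(measure_section(poly, er,
                                 resample_step_nm = 2.5)["contact_nm"])
  expect_lt(abs(c5 - c2.5) / c2.5, 0.005)
})

test_that("degenerate geometry is rejected", {
  bowtie <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(measure_section(bowtie, list()), "self-intersecting")
  er0 <- list(rbind(c(5, 5), c(5, 5)))
  expect_error(measure_section(square_el, er0), "zero-length")
  expect_error(make_em_scene(square_el, er0), "zero-length")
})

test_that("contour tables round-trip through CSV", {
  sc <- make_em_scene(list(center = c(0, 0), radius = 250),
                      list(rbind(c(-500, 200), c(500, 200))))
  path <- tempfile(fileext = ".csv")
  write_em_contours(sc$contours, path)
  back <- read_em_contours(path)
  expect_equal(back, sc$contours, tolerance = 1e-12)
  expect_equal(measure_contour_set(back)$percent,
               measure_contour_set(sc$contours)$percent)
})
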