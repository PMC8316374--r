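disc_mask <- function(radius_um, pixel_size_um = 0.1, pad_um = 1.5) {
  c0 <- radius_um + pad_um
  side <- ceiling(2 * c0 / pixel_size_um)
  rasterize_outline(list(center = c(c0, c0), radius = radius_um),
                    c(side, side), pixel_size_um)
}

test_that("shells tile the mask exactly and band by boundary distance", {
  mask <- disc_mask(10)
  sh <- build_shells(mask, 0.1)
  expect_true(all((sh$labels > 0) == mask))       # exact partition
  expect_setequal(unique(sh$labels[mask]), 1:5)
  expect_length(sh$flags, 0)
  # shell 5 spans boundary distance (0, 2] um
  d_um <- as.matrix(EBImage::distmap(mask * 1)) * 0.1
  in5 <- sh$labels == 5L
  expect_lte(max(d_um[in5]), 2 + 1e-9)
  expect_true(all(d_um[mask & !in5] > 2))
})

test_that("a thin cell is flagged, not rejected", {
  sh <- build_shells(disc_mask(3), 0.1)
  expect_true("thin_cell" %in% sh$flags)
  expect_true(all(c(1L, 2L) %in% sh$empty_shells))
  two <- matrix(FALSE, 20, 20); two[2:4, 2:4] <- TRUE; two[15:17, 15:17] <- TRUE
  expect_error(build_shells(two, 0.1), "connected components")
  expect_error(build_shells(matrix(FALSE, 5, 5), 0.1), "empty")
})

test_that("a uniform disc of radius 10 um has peripheral fraction 0.84", {
  mask <- disc_mask(10)
  sh <- build_shells(mask, 0.1)
  img <- matrix(0, nrow(mask), ncol(mask)); img[mask] <- 1
  pf <- peripheral_fraction(img, sh)
  expect_equal(pf$fraction, 0.84, tolerance = 0.01)
  expect_equal(pf$total_signal, sum(mask))
})

test_that("extreme signal placements give fractions 0 and 1", {
  mask <- disc_mask(10)
  sh <- build_shells(mask, 0.1)
  ctr <- matrix(0, nrow(mask), ncol(mask))
  ctr[round(nrow(mask) / 2), round(ncol(mask) / 2)] <- 100
  expect_equal(peripheral_fraction(ctr, sh)$fraction, 0)
  edge <- matrix(0, nrow(mask), ncol(mask))
  edge[sh$labels == 5L] <- 100
  expect_equal(peripheral_fraction(edge, sh)$fraction, 1)
  expect_error(peripheral_fraction(ctr * 0, sh), "zero")
})

test_that("planted peripheral fractions are recovered within 0.03", {
  disc <- list(center = c(12, 12), radius = 10)
  for (target in c(0.1, 0.5, 0.9)) {
    scn <- make_dispersal_scene(disc, target, n_puncta = 200,
                                seed = 100 + target * 10)
    pf <- peripheral_fraction(scn$image, scn$shells,
                              background_threshold = 20)
    expect_lt(abs(pf$fraction - scn$true_fraction), 0.03)
  }
})

test_that("the fraction is invariant under scene rotation", {
  disc <- list(center = c(12, 12), radius = 10)
  scn <- make_dispersal_scene(disc, 0.4, n_puncta = 150, seed = 55)
  pf <- peripheral_fraction(scn$image, scn$shells,
                            background_threshold = 20)
  rot <- function(m) t(m)[, nrow(m):1]   # 90 degrees
  img_r <- rot(scn$image)
  mask_r <- rot(scn$mask)
  sh_r <- build_shells(mask_r, 0.1)
  pf_r <- peripheral_fraction(img_r, sh_r, background_threshold = 20)
  expect_lt(abs(pf$fraction - pf_r$fraction), 0.01)
})
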