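grid_centered <- function(n, spacing)
  list(u = (seq_len(n) - 1 - (n - 1) / 2) * spacing,
       v = (seq_len(n) - 1 - (n - 1) / 2) * spacing)

test_that("an axis-aligned square rasterizes to an exact pixel tiling", {
  sq <- roi_polygon(rbind(c(-0.5, -0.5), c(0.5, -0.5),
                          c(0.5, 0.5), c(-0.5, 0.5)))
  g <- grid_centered(20, 0.1)  # centres at +/-0.05 .. +/-0.95
  mask <- rasterize_roi(sq, g)
  expect_equal(sum(mask), 100L)
  expect_equal(mask_area(mask, 0.1), 1.0)
})

test_that("rasterized area of a triangle matches the shoelace area", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  g <- grid_centered(120, 0.02)
  mask <- rasterize_roi(roi_polygon(tri), g)
  a <- mask_area(mask, 0.02)
  # the half-open pixel-centre rule sits exactly at the 2 % bound here
  expect_lte(abs(a - shoelace(tri)) / shoelace(tri), 0.02 + 1e-12)
})

test_that("invalid polygons are rejected", {
  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(roi_polygon(bowtie), "self-intersecting")
  degenerate <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_error(roi_polygon(degenerate), "zero area")
})

test_that("pixel centres on a polygon edge count as inside", {
  sq <- roi_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- list(u = c(0, 0.5, 1), v = c(0, 0.5, 1))  # corners/edges/centre
  expect_true(all(rasterize_roi(sq, g)))
})

test_that("bi-threshold keeps the closed [-700, 700] HU interval", {
  img <- matrix(c(-1000, -700, 0, 700, 800), nrow = 5)
  roi <- matrix(TRUE, 5, 1)
  expect_equal(as.vector(mucosa_mask(img, roi)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(mucosa_mask(img, matrix(FALSE, 5, 1))))
  air <- matrix(-1000, 4, 4)
  expect_false(any(mucosa_mask(air, matrix(TRUE, 4, 4))))
  expect_error(mucosa_mask(img, matrix(TRUE, 2, 2)), "shapes differ")
  expect_error(threshold_spec(0, 0), "lo < hi")
})

test_that("mask areas count pixels times pixel area and scale quadratically", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE
  expect_equal(mask_area(mask, 0.1), 1.0)
  expect_equal(mask_area(matrix(FALSE, 5, 5), 0.1), 0.0)
  expect_equal(mask_area(mask, 0.2), 4 * mask_area(mask, 0.1))
  expect_equal(mask_area(mask, c(0.1, 0.3)), 3.0)
})

make_annulus_slice <- function(R, r, spacing, n,
                               hu = c(air = -1000, mucosa = 0)) {
  g <- grid_centered(n, spacing)
  rho <- sqrt(outer(g$u^2, g$v^2, "+"))
  img <- matrix(hu[["air"]], n, n)
  img[rho <= R] <- hu[["mucosa"]]
  img[rho <= r] <- hu[["air"]]
  list(img = img, grid = g)
}

test_that("annulus slice measurement recovers the analytic fraction", {
  sp <- 0.02
  n <- 220
  sl <- make_annulus_slice(2, 1, sp, n)
  ang <- seq(0, 2 * pi, length.out = 181)[-181]
  poly <- roi_polygon(cbind(2 * cos(ang), 2 * sin(ang)))
  m <- measure_slice(sl$img, poly, sl$grid, sp)
  expect_lt(abs(m$fraction - 0.75), 0.02)
  # and agrees closely with the exact pixel-count oracle
  expect_lt(abs(m$fraction - pixel_count_annulus_fraction(2, 1, sp)), 0.01)
})

test_that("all-tissue and all-air ROIs give fractions 1 and 0", {
  g <- grid_centered(50, 0.05)
  sq <- roi_polygon(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)))
  tissue <- matrix(40, 50, 50)
  air <- matrix(-1000, 50, 50)
  expect_equal(measure_slice(tissue, sq, g, 0.05)$fraction, 1.0)
  expect_equal(measure_slice(air, sq, g, 0.05)$fraction, 0.0)
})

test_that("degenerate ROI (no pixel centre inside) errors", {
  g <- grid_centered(10, 1)  # coarse grid, tiny polygon between centres
  tiny <- roi_polygon(rbind(c(0.1, 0.1), c(0.2, 0.1), c(0.2, 0.2),
                            c(0.1, 0.2)))
  expect_error(measure_slice(matrix(0, 10, 10), tiny, g, 1),
               "degenerate ROI")
})

test_that("mucosa and non-mucosa areas partition the ROI exactly", {
  set.seed(5)
  sp <- 0.05
  n <- 60
  g <- grid_centered(n, sp)
  img <- matrix(runif(n * n, -1500, 1500), n, n)
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  poly <- roi_polygon(cbind(1.2 * cos(ang), 1.2 * sin(ang)))
  roi <- rasterize_roi(poly, g)
  th <- threshold_spec()
  muc <- mucosa_mask(img, roi, th)
  non <- roi & !(img >= th$lo & img <= th$hi)
  expect_identical(sum(muc) + sum(non), sum(roi))
  expect_equal(mask_area(muc, sp) + mask_area(non, sp), mask_area(roi, sp))
})

test_that("fraction is invariant to whole-pixel in-plane shifts", {
  set.seed(9)
  sp <- 0.05
  n <- 80
  img <- matrix(runif(n * n, -1200, 1200), n, n)
  ang <- seq(0, 2 * pi, length.out = 61)[-61]
  base <- cbind(1.1 * cos(ang), 1.1 * sin(ang))
  g <- grid_centered(n, sp)
  f0 <- measure_slice(img, roi_polygon(base), g, sp)$fraction
  for (shift_px in list(c(3, 0), c(0, -4), c(5, 2))) {
    sh <- shift_px * sp
    poly <- roi_polygon(sweep(base, 2, -sh))
    img_sh <- img
    # shift the image content by the same whole-pixel amount
    img_sh <- matrix(-2000, n, n)
    xs <- seq_len(n) - shift_px[1]; ys <- seq_len(n) - shift_px[2]
    ok_x <- xs >= 1 & xs <= n; ok_y <- ys >= 1 & ys <= n
    img_sh[which(ok_x), which(ok_y)] <- img[xs[ok_x], ys[ok_y]]
    f1 <- measure_slice(img_sh, roi_polygon(sweep(base, 2, -sh)), g,
                        sp)$fraction
    expect_equal(f1, f0, tolerance = 1e-12)
  }
})

test_that("fraction converges to the analytic annulus value at fine pixels", {
  sp <- 0.005  # 5 um pixels
  n <- 2 * ceiling(2.1 / sp)
  sl <- make_annulus_slice(2, 1, sp, n)
  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  poly <- roi_polygon(cbind(2 * cos(ang), 2 * sin(ang)))
  m <- measure_slice(sl$img, poly, sl$grid, sp)
  expect_lt(abs(m$fraction - 0.75), 0.005)
})
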