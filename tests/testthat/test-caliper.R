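test_that("sampling interval is half the smallest voxel dimension", {
  expect_identical(sampling_interval(c(0.8, 0.8, 1.0)), 0.4)
  expect_identical(sampling_interval(c(1, 1, 1)), 0.5)
  expect_identical(sampling_interval(c(0.6, 0.8, 1.25)), 0.3)
  expect_error(sampling_interval(c(0.8, 0)), "")
})

test_that("splines of straight paths have equal arc and chord length", {
  sp3 <- fit_spline(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), c(1, 1, 1))
  expect_equal(sp3$arc_length_mm, sp3$euclidean_length_mm,
               tolerance = 1e-6)
  sp2 <- fit_spline(rbind(c(0, 0, 0), c(3, 4, 0)), c(1, 1, 1))
  expect_equal(sp2$arc_length_mm, 5, tolerance = 1e-6)
  expect_equal(sp2$euclidean_length_mm, 5, tolerance = 1e-6)
  expect_error(fit_spline(rbind(c(1, 1, 1), c(1, 1, 1)), c(1, 1, 1)),
               "degenerate")
})

test_that("spline arc length of a sinusoid matches the quadrature oracle", {
  L <- 40; A <- 3
  tt <- seq(0, 1, length.out = 60)
  path <- cbind(tt * L, A * sin(2 * pi * tt), 0)
  # independent oracle: numerical quadrature on the continuous curve
  oracle <- stats::integrate(function(t)
    sqrt(L^2 + (A * 2 * pi * cos(2 * pi * t))^2), 0, 1,
    rel.tol = 1e-10)$value
  sp <- fit_spline(path, c(1, 1, 1))
  expect_lt(abs(sp$arc_length_mm - oracle) / oracle, 0.01)
})

test_that("perpendicular patches reproduce axial slices for axial tangents", {
  dims <- c(21, 21, 9)
  f <- function(x, y, z) 2 * x + 10 * y - 3 * z
  arr <- array(0, dims)
  for (k in 1:dims[3]) arr[, , k] <-
      outer(1:dims[1], 1:dims[2], function(i, j) f(i - 1, j - 1, k - 1))
  vol <- image_volume(arr, spacing = c(1, 1, 1))
  p <- extract_patch(vol, point = c(10, 10, 4), tangent = c(0, 0, 1),
                     pitch = 1, max_extent = 10)
  hn <- (nrow(p$hu) - 1) / 2
  crop <- arr[(10 - hn):(10 + hn) + 1, (10 - hn):(10 + hn) + 1, 5]
  expect_equal(p$hu, crop, ignore_attr = TRUE, tolerance = 1e-9)

  # constant volume -> constant patch
  cv <- image_volume(array(-123, dims), c(1, 1, 1))
  pc <- extract_patch(cv, c(10, 10, 4), c(0.6, 0, 0.8), pitch = 0.5)
  expect_true(all(abs(pc$hu[pc$inside] + 123) < 1e-9))

  expect_error(extract_patch(vol, c(100, 0, 0), c(0, 0, 1)), "outside")
})

test_that("patch physical extent never exceeds the 40 mm frame", {
  cv <- image_volume(array(0, c(30, 30, 30)), c(1, 1, 1))
  for (pitch in c(0.3, 0.4, 0.5, 0.7)) {
    p <- extract_patch(cv, c(15, 15, 15), c(0, 0, 1), pitch = pitch)
    expect_lte(p$extent_mm, 40)
  }
})

# analytic perpendicular patch built directly from the radial wall model:
# dark lumen, Gaussian wall with its inner half-maximum at radius r_b(theta)
analytic_patch <- function(r_fun, pitch = 0.25, half_mm = 10,
                           sigma = 0.5, lumen = -1000, peak = 0,
                           background = -850) {
  g <- seq(-half_mm, half_mm, by = pitch)
  off <- sigma * sqrt(2 * log(2))
  hu <- outer(g, g, function(x, y) {
    th <- atan2(y, x)
    rho <- sqrt(x^2 + y^2) - (r_fun(th) + off)
    ifelse(rho <= 0, lumen + (peak - lumen) * exp(-rho^2 / (2 * sigma^2)),
           background + (peak - background) * exp(-rho^2 / (2 * sigma^2)))
  })
  structure(list(hu = hu, inside = matrix(TRUE, length(g), length(g)),
                 pitch_mm = pitch, extent_mm = 2 * half_mm,
                 centre = c(0, 0, 0), u = c(1, 0, 0), v = c(0, 1, 0),
                 tangent = c(0, 0, 1), source_spacing = c(0, 0, 0)),
            class = "perpendicular_patch")
}

test_that("FWHM caliper recovers circular and elliptical lumen diameters", {
  circ <- measure_fwhm_ellipse(analytic_patch(function(th) 3))
  expect_true(circ$valid)
  expect_lt(abs(circ$diameter_mm - 6), max(0.5 * 0.25, 0.03 * 6))
  expect_lt(abs(circ$minor_radius_mm - circ$major_radius_mm), 0.15)

  rb <- function(th) 1 / sqrt((cos(th) / 2)^2 + (sin(th) / 4.5)^2)
  ell <- measure_fwhm_ellipse(analytic_patch(rb))
  expect_true(ell$valid)
  d_true <- 2 * sqrt(2 * 4.5)
  expect_lt(abs(ell$diameter_mm - d_true) / d_true, 0.03)
  expect_lt(abs(ell$minor_radius_mm - 2) / 2, 0.08)
  expect_lt(abs(ell$major_radius_mm - 4.5) / 4.5, 0.08)
})

test_that("caliper rejects patches without a wall or a dark core", {
  flat <- analytic_patch(function(th) 1e6)  # wall far outside the frame
  expect_false(measure_fwhm_ellipse(flat)$valid)
  bright <- analytic_patch(function(th) 3, lumen = -400, background = -400)
  expect_false(measure_fwhm_ellipse(bright)$valid)
})

test_that("measured diameter is monotone in true lumen radius", {
  d <- vapply(c(1.5, 2, 2.5, 3, 4), function(r)
    measure_fwhm_ellipse(analytic_patch(function(th) r))$diameter_mm, 0)
  expect_true(all(diff(d) > 0))
})

test_that("segment measurement recovers a cone's analytic mean diameter", {
  ph <- fixture("cone", function()
    tube_phantom(3, c(0.8, 0.8, 0.8), L = 40, r1 = 2))
  g <- graph_from_mask(ph$mask)
  sp <- fit_spline(g$paths[[1]], g$spacing, g$origin)
  m <- measure_segment(ph$volume, sp)
  expect_true(m$valid)
  expect_lt(abs(m$mean_diameter_mm - ph$truth$mean_diameter_mm) /
              ph$truth$mean_diameter_mm, 0.05)
})

test_that("samples outside the volume are flagged, mean over the rest", {
  ph <- fixture("cyl_r3", function() tube_phantom(3, c(0.8, 0.8, 1.0)))
  # straight path that runs past the superior volume face
  path <- cbind(9, 9, 0:119)
  sp <- fit_spline(path, ph$volume$spacing, ph$volume$origin)
  m <- measure_segment(ph$volume, sp)
  expect_true(any(!m$samples$in_volume))
  expect_false(all(m$samples$in_volume))
  expect_true(all(!m$samples$valid[!m$samples$in_volume]))
})
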