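test_that("truth table is analytic for simple geometries", {
  ph <- fixture("cyl_r3", function() tube_phantom(3, c(0.8, 0.8, 1.0)))
  expect_equal(ph$truth$mean_diameter_mm, 6)
  expect_equal(ph$truth$tortuosity, 1)
  expect_equal(ph$truth$arc_length_mm, 40, tolerance = 1e-9)

  # sinusoidal branch: tortuosity from an independent quadrature oracle
  ph2 <- tube_phantom(2, c(1, 1, 1), L = 30, amplitude = 2, cycles = 1)
  oracle <- stats::integrate(function(t)
    sqrt(30^2 + (2 * 2 * pi * cos(2 * pi * t))^2), 0, 1,
    rel.tol = 1e-10)$value / 30
  expect_gt(ph2$truth$tortuosity, 1)
  expect_equal(ph2$truth$tortuosity, oracle, tolerance = 1e-5)

  # two-generation tree with child radii 0.75 x parent: tapering 25%
  br <- list(phantom_branch(1, NA, c(0, 0, 30), c(0, 0, 5), r0 = 3),
             phantom_branch(2, 1, c(0, 0, 5), c(14, 0, -8), r0 = 2.25),
             phantom_branch(3, 1, c(0, 0, 5), c(-14, 0, -8), r0 = 2.25))
  tr <- rasterize_phantom(phantom_spec(br, spacing = c(1, 1, 1)))$truth
  expect_equal(tr$tapering_vs_parent_pct[2:3], c(25, 25))
  expect_true(is.na(tr$tapering_vs_parent_pct[1]))
})

test_that("rasterization is deterministic, including seeded noise", {
  br <- list(phantom_branch(1, NA, c(0, 0, 20), c(0, 0, -5), r0 = 2.5))
  spec <- phantom_spec(br, spacing = c(1, 1, 1), noise_sd_hu = 15, seed = 42)
  a <- rasterize_phantom(spec)
  b <- rasterize_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  # noise is actually present
  spec0 <- phantom_spec(br, spacing = c(1, 1, 1), noise_sd_hu = 0)
  c0 <- rasterize_phantom(spec0)
  expect_gt(sd(a$volume$data - c0$volume$data), 5)
})

test_that("declared-tree validation catches malformed phantoms", {
  expect_error(phantom_spec(list(
    phantom_branch(1, NA, c(0, 0, 0), c(0, 0, 10), r0 = 2))),
    "superior to inferior")
  expect_error(phantom_spec(list(
    phantom_branch(1, NA, c(0, 0, 10), c(0, 0, 0), r0 = 2),
    phantom_branch(2, 1, c(3, 0, 0), c(3, 0, -10), r0 = 1))),
    "does not start at the end")
  # lumen exits an explicitly small grid
  spec <- phantom_spec(list(
    phantom_branch(1, NA, c(0, 0, 10), c(0, 0, -10), r0 = 3)),
    spacing = c(1, 1, 1), dims = c(5L, 5L, 30L), origin = c(-2, -2, -12))
  expect_error(rasterize_phantom(spec), "exits")
})

test_that("overlapping unrelated branches are reported as a pair", {
  br <- list(
    phantom_branch(1, NA, c(0, 0, 30), c(0, 0, 10), r0 = 3),
    phantom_branch(2, 1, c(0, 0, 10), c(15, 0, 0), r0 = 2),
    phantom_branch(3, 2, c(15, 0, 0), c(2, 0, 18), r0 = 2.5))
  expect_error(rasterize_phantom(phantom_spec(br, spacing = c(1, 1, 1))),
               "1 and 3")
})

test_that("mask volume scales quadratically with radius", {
  m1 <- tube_phantom(2, c(0.8, 0.8, 0.8))$mask
  m2 <- tube_phantom(4, c(0.8, 0.8, 0.8))$mask
  ratio <- sum(m2$data) / sum(m1$data)
  # capsule volume: pi r^2 L + 4/3 pi r^3; expected ratio for L = 40
  expected <- (16 * 40 + 4 / 3 * 64) / (4 * 40 + 4 / 3 * 8)
  expect_lt(abs(ratio - expected) / expected, 0.1)
})

test_that("standard cohort is reproducible and parameters are recorded", {
  c1 <- standard_cohort(3, seed = 11, max_generation = 3)
  c2 <- standard_cohort(3, seed = 11, max_generation = 3)
  expect_identical(length(c1), 3L)
  expect_true(all(vapply(c1, function(x) x$taper, 0) >= 0.20))
  expect_true(all(vapply(c1, function(x) x$taper, 0) <= 0.30))
  expect_true(all(vapply(c1, function(x) x$amplitude_ratio, 0) <= 0.03))
  # distinct cases, identical across same-seed calls
  expect_false(identical(c1[[1]]$taper, c1[[2]]$taper))
  v1 <- rasterize_phantom(c1[[1]]$spec)
  v2 <- rasterize_phantom(c2[[1]]$spec)
  expect_identical(v1$volume$data, v2$volume$data)

  # truth-level parameter recovery and arc >= euclid everywhere
  tr <- v1$truth
  expect_true(all(tr$arc_length_mm >= tr$euclidean_length_mm - 1e-9))
  expect_equal(median(tr$tapering_vs_parent_pct, na.rm = TRUE),
               100 * c1[[1]]$taper, tolerance = 1e-6)
  amp_t <- unique(round(tr$tortuosity[tr$amplitude_mm > 0], 6))
  expect_length(amp_t, 1L)  # one shared analytic tortuosity by design
})
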