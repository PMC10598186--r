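test_that("NIfTI round trip preserves data, spacing and origin", {
  vol <- image_volume(array(rnorm(6 * 5 * 4, -800, 100), dim = c(6, 5, 4)),
                      spacing = c(0.8, 0.8, 1.0), origin = c(-3, 2, 10))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- load_volume(f)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)

  mdat <- rbinom(120, 1, 0.4)
  mdat[1] <- 1
  msk <- binary_mask(array(mdat, dim = c(6, 5, 4)),
                     spacing = c(0.8, 0.8, 1.0), origin = c(-3, 2, 10))
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(msk, fm)
  back_m <- load_mask(fm, back)
  expect_identical(back_m$data, msk$data)
})

test_that("volumes are reoriented to RAS on load", {
  # write an LAS image by hand: first axis flipped
  a <- array(as.double(1:24), dim = c(2, 3, 4))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(1, 1, 1)
  xf <- diag(c(-1, 1, 1, 1)); xf[1, 4] <- 5
  attr(xf, "code") <- 2L
  RNifti::`qform<-`(img, xf) -> img
  RNifti::`sform<-`(img, xf) -> img
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  vol <- load_volume(f)
  expect_equal(vol$data, a[2:1, , ])
})

test_that("loaders reject malformed inputs", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(1:12, 3, 4)), f)
  expect_error(load_volume(f), "3D")
  expect_error(load_volume("does-not-exist.nii"), "not found")
  expect_error(image_volume(array(c(1, NaN), dim = c(2, 1, 1)), c(1, 1, 1)),
               "finite")
  expect_error(image_volume(array(1, dim = c(2, 2, 2)), c(1, -1, 1)),
               "positive")

  ref <- image_volume(array(0, dim = c(4, 4, 4)), c(1, 1, 1))
  fm <- withr::local_tempfile(fileext = ".nii")
  m <- RNifti::asNifti(array(1L, dim = c(3, 4, 4)))
  RNifti::writeNifti(m, fm)
  expect_error(load_mask(fm, ref), "does not match")
})

test_that("masks binarize labels and refuse empty foreground", {
  lab <- array(0, dim = c(3, 3, 3))
  lab[1, 1, 1] <- 2; lab[2, 2, 2] <- 5
  m <- binary_mask(lab, c(1, 1, 1))
  expect_identical(sum(m$data), 2L)
  expect_true(all(m$data[lab > 0]))
  expect_error(binary_mask(array(0, dim = c(2, 2, 2)), c(1, 1, 1)),
               "no foreground")
})

test_that("display windowing maps the standard airway window", {
  expect_equal(apply_display_window(array(-500, c(1, 1, 1)))[1], 0.5)
  expect_equal(apply_display_window(array(-1250, c(1, 1, 1)))[1], 0)
  expect_equal(apply_display_window(array(250, c(1, 1, 1)))[1], 1)
  hu <- sort(runif(100, -1400, 400))
  w <- apply_display_window(array(hu, c(100, 1, 1)))
  expect_true(all(diff(as.numeric(w)) >= 0))
  expect_error(apply_display_window(array(0, c(1, 1, 1)), width = 0), "width")
})
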