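test_that("run_pipeline produces the full output manifest from files", {
  td <- withr::local_tempdir()
  ph <- rasterize_phantom(phantom_spec(
    phantom_airway_tree(taper = 0.25, max_generation = 3),
    spacing = c(0.8, 0.8, 1.0)))
  write_phantom(ph, file.path(td, "case"))
  expect_setequal(list.files(file.path(td, "case")),
                  c("ct.nii.gz", "airway.nii.gz", "truth.csv"))

  cfg <- list(ct = file.path(td, "case", "ct.nii.gz"),
              airway = file.path(td, "case", "airway.nii.gz"),
              out_dir = file.path(td, "out"), patient_id = "p1",
              gen_lo = 2, gen_hi = 3)
  run_pipeline(cfg)
  for (f in c("segments.csv", "patient_summary.csv", "graph.graphml",
              "data_dictionary.csv", "config.json", "resolved_config.json",
              "run_log.txt"))
    expect_true(file.exists(file.path(td, "out", f)), label = f)

  seg <- utils::read.csv(file.path(td, "out", "segments.csv"))
  expect_equal(nrow(seg), nrow(ph$truth))
  summ <- utils::read.csv(file.path(td, "out", "patient_summary.csv"))
  expect_identical(summ$patient_id, "p1")
  expect_true(summ$valid)

  # byte-identical outputs when re-run with the identical config
  run_pipeline(utils::modifyList(cfg, list(out_dir = file.path(td, "out2"))))
  for (f in c("segments.csv", "patient_summary.csv"))
    expect_identical(readBin(file.path(td, "out", f), "raw", 5e6),
                     readBin(file.path(td, "out2", f), "raw", 5e6),
                     label = f)

  expect_error(run_pipeline(utils::modifyList(
    cfg, list(airway = file.path(td, "nope.nii.gz")))), "nope")
})

test_that("stage failures name the failing stage", {
  vol <- image_volume(array(-1000, c(8, 8, 8)), c(1, 1, 1))
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  msk <- binary_mask(m, c(1, 1, 1))
  expect_error(bronchiq(vol, msk), "skeleton_graph")
})

test_that("graph rendering maps diameter to width and lobe to colour", {
  ph <- fixture("y_phantom", y_phantom)
  g <- assign_generations(graph_from_mask(ph$mask))
  g <- classify_lobes(g)
  root <- which(is.na(g$edges$parent))
  g$edges$mean_diameter_mm <- rep(5, nrow(g$edges))
  g$edges$mean_diameter_mm[root] <- 10
  f <- withr::local_tempfile(fileext = ".png")
  out <- render_airway_graph(g, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  w <- out$widths
  expect_equal(w[root] / max(w[-root]), 2)

  g$edges$mean_diameter_mm <- NULL
  f2 <- withr::local_tempfile(fileext = ".png")
  expect_warning(out2 <- render_airway_graph(g, file = f2), "uniform")
  expect_equal(length(unique(out2$widths)), 1L)
})

test_that("six-lobe trees render with six distinct lobe colours", {
  tf <- tree_fit()
  f <- withr::local_tempfile(fileext = ".png")
  out <- render_airway_graph(tf$fit$graph, file = f)
  lobes <- unique(tf$fit$segments$lobe)
  expect_gte(length(unique(out$colours)), 7L)
})
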