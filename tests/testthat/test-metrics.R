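test_that("intersegmental tapering follows the parent-normalised definition", {
  expect_equal(intersegmental_tapering(10, 7), 30)
  expect_equal(intersegmental_tapering(8, 9), -12.5)
  expect_equal(intersegmental_tapering(5, 5), 0)
  expect_error(intersegmental_tapering(0, 3), "positive")
  expect_error(intersegmental_tapering(3, -1), "positive")
  # scale invariance
  expect_equal(intersegmental_tapering(10 * 3.7, 7 * 3.7), 30)
})

test_that("tortuosity is the arc-to-chord ratio, clipped at 1", {
  expect_equal(tortuosity(12, 10), 1.2)
  expect_equal(tortuosity(9.9999999, 10), 1)
  expect_error(tortuosity(5, 0), "positive")
  expect_equal(tortuosity(12 * 2, 10 * 2), 1.2)
  # half sine arc oracle
  L <- 20; A <- L / (2 * pi)
  arc <- stats::integrate(function(t)
    sqrt(L^2 + (A * pi * cos(pi * t))^2), 0, 1, rel.tol = 1e-10)$value
  expect_equal(tortuosity(arc, L), arc / L, tolerance = 1e-12)
  expect_gt(tortuosity(arc, L), 1)
})

metric_graph <- function(tapering, tort, gen, lobe, valid = TRUE) {
  n <- length(tapering)
  structure(list(edges = data.frame(
    id = seq_len(n), parent = c(NA, seq_len(n - 1)),
    generation = gen, lobe = lobe,
    mean_diameter_mm = 5, tapering_pct = tapering,
    tortuosity = tort, measure_valid = rep_len(valid, n))),
    class = "airway_graph")
}

test_that("patient summary takes medians over valid window segments", {
  g <- metric_graph(tapering = c(NA, 10, 20, 60),
                    tort = c(1, 1.1, 1.2, 1.6),
                    gen = c(1, 2, 3, 4), lobe = c("TRACHEA_MAIN", "RUL",
                                                  "RUL", "RLL"))
  s <- summarize_patient(g, 2, 6)
  expect_equal(s$median_intersegmental_tapering_pct, 20)
  expect_equal(s$median_tortuosity, 1.2)
  expect_equal(s$total_segment_count, 4L)
  expect_true(s$valid)

  # even count: midpoint convention
  g2 <- metric_graph(c(NA, 10, 30, 20, 40), c(1, 1, 1, 1, 1),
                     c(1, 2, 2, 3, 3), c("TRACHEA_MAIN", "RUL", "LUL",
                                         "RUL", "LUL"))
  expect_equal(summarize_patient(g2)$median_intersegmental_tapering_pct, 25)

  # zero valid segments in the window -> flagged
  g3 <- metric_graph(c(NA, 10), c(1, 1), c(0, 1),
                     c("TRACHEA_MAIN", "TRACHEA_MAIN"))
  expect_false(summarize_patient(g3, 2, 6)$valid)
})

test_that("per-lobe breakdowns aggregate within each lobe", {
  g <- metric_graph(c(NA, 10, 30, 50), c(1, 1.1, 1.3, 1.5),
                    c(1, 2, 2, 2), c("TRACHEA_MAIN", "RUL", "RUL", "LLL"))
  s <- summarize_patient(g)
  expect_equal(s$by_lobe$RUL[["median_tapering_pct"]], 20)
  expect_equal(s$by_lobe$LLL[["median_tapering_pct"]], 50)
})

test_that("survival table flattens summaries and joins clinical data", {
  gg <- function(id) {
    s <- summarize_patient(metric_graph(c(NA, 10 + id), c(1, 1.2),
                                        c(1, 2), c("TRACHEA_MAIN", "RUL")),
                           patient_id = paste0("p", id))
    s
  }
  summ <- lapply(1:3, gg)
  tab <- export_survival_table(summ)
  expect_equal(dim(tab), c(3L, 4L))
  expect_identical(tab$patient_id, c("p1", "p2", "p3"))

  clin <- data.frame(patient_id = c("p2", "p1", "p3"),
                     fvc = c(70, 80, 90))
  tab2 <- export_survival_table(summ, clinical = clin)
  expect_equal(tab2$fvc[tab2$patient_id == "p1"], 80)

  tab3 <- export_survival_table(summ, standardize_tortuosity = TRUE)
  expect_equal(mean(tab3$median_tortuosity), 0, tolerance = 1e-12)

  expect_error(export_survival_table(summ[c(1, 1)]), "duplicate")
})
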