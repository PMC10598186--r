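# hand-built six-lobe topology: trachea -> mains -> upper seeds +
# intermediate trunks -> middle/lower seeds
six_lobe_toy <- function() {
  xyz <- rbind(c(0, 0, 60), c(0, 0, 30),
               c(20, 0, 22), c(26, 2, 34), c(24, -1, 8),
               c(32, 10, 0), c(28, -6, -6),
               c(-20, 0, 22), c(-26, 2, 34), c(-24, -1, 8),
               c(-32, 10, 0), c(-28, -6, -6))
  edges <- data.frame(
    from   = c(1, 2, 3, 3, 5, 5, 2, 8, 8, 10, 10),
    to     = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    parent = c(NA, 1, 2, 2, 4, 4, 1, 7, 7, 9, 9))
  toy_graph(edges, xyz)
}

test_that("generations count divisions from the trachea", {
  g <- assign_generations(six_lobe_toy())
  expect_identical(g$edges$generation,
                   c(0L, 1L, 2L, 2L, 3L, 3L, 1L, 2L, 2L, 3L, 3L))

  # Y graph
  y <- toy_graph(data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                            parent = c(NA, 1, 1)),
                 rbind(c(0, 0, 30), c(0, 0, 10), c(10, 0, 0), c(-10, 0, 0)))
  expect_identical(assign_generations(y)$edges$generation, c(0L, 1L, 1L))

  # merge-suppressed trifurcation: all three children get parent + 1
  tri <- toy_graph(data.frame(from = c(1, 2, 2, 2), to = c(2, 3, 4, 5),
                              parent = c(NA, 1, 1, 1)),
                   rbind(c(0, 0, 30), c(0, 0, 10), c(10, 0, 0),
                         c(-10, 0, 0), c(0, 10, 0)))
  expect_identical(assign_generations(tri)$edges$generation,
                   c(0L, 1L, 1L, 1L))
})

test_that("direction heuristic assigns all six lobes on the toy tree", {
  g <- classify_lobes(assign_generations(six_lobe_toy()))
  expect_identical(
    g$edges$lobe,
    c("TRACHEA_MAIN", "TRACHEA_MAIN", "RUL", "TRACHEA_MAIN", "RML", "RLL",
      "TRACHEA_MAIN", "LUL", "TRACHEA_MAIN", "LML", "LLL"))
  expect_false(any(g$edges$lobe_flagged))
})

test_that("lobe labels match the phantom's declared lobes exactly", {
  tf <- tree_fit()
  seg <- tf$fit$segments
  tru <- tf$phantom$truth
  expect_identical(sort(table(seg$lobe)), sort(table(tru$lobe)))
  # per generation x lobe contingency matches the truth
  expect_equal(unclass(table(seg$lobe, seg$generation)),
               unclass(table(tru$lobe, tru$depth)))
})

test_that("overrides relabel whole subtrees and win over the heuristic", {
  g <- classify_lobes(assign_generations(six_lobe_toy()),
                      overrides = data.frame(node_id = 3, lobe = "RLL"))
  expect_identical(g$edges$lobe[3:6], rep("RLL", 4))
  expect_identical(g$edges$lobe[8:11], c("LUL", "TRACHEA_MAIN", "LML", "LLL"))
  expect_error(classify_lobes(assign_generations(six_lobe_toy()),
                              overrides = data.frame(node_id = 3,
                                                     lobe = "XXX")),
               "unknown lobe")
})

test_that("a graph without a division is all trachea/main, with a warning", {
  chain <- toy_graph(data.frame(from = c(1, 2), to = c(2, 3),
                                parent = c(NA, 1)),
                     rbind(c(0, 0, 30), c(0, 0, 10), c(0, 0, -10)))
  expect_warning(g <- classify_lobes(assign_generations(chain)),
                 "no division")
  expect_identical(unique(g$edges$lobe), "TRACHEA_MAIN")
})

test_that("lobar generation restarts at each lobe's seeding bronchus", {
  g <- classify_lobes(assign_generations(six_lobe_toy()))
  lg <- lobar_generation(g)
  expect_identical(lg[3], 0L)   # RUL seed
  expect_identical(lg[5], 0L)   # RML seed
  expect_true(all(is.na(lg[g$edges$lobe == "TRACHEA_MAIN"])))
})

test_that("analysis window selects the requested generations by lobe", {
  g <- classify_lobes(assign_generations(six_lobe_toy()))
  w <- select_analysis_window(g, 2, 6)
  expect_setequal(w$id, c(3, 4, 5, 6, 8, 9, 10, 11))
  expect_identical(select_analysis_window(g, 0, 0)$id, 1L)
  expect_error(select_analysis_window(g, 4, 2))

  # counts against a deeper phantom truth table
  tf <- tree_fit()
  w2 <- select_analysis_window(tf$fit$graph, 2, 4)
  expect_equal(nrow(w2), sum(tf$phantom$truth$depth >= 2 &
                               tf$phantom$truth$depth <= 4))
})

test_that("generations are strictly increasing along root-to-tip paths", {
  tf <- tree_fit()
  ed <- tf$fit$segments
  kids <- which(!is.na(ed$parent))
  expect_true(all(ed$generation[kids] ==
                    ed$generation[ed$parent[kids]] + 1L))
  # a segment's lobe equals its parent's unless it is a lobar seed
  same <- ed$lobe[kids] == ed$lobe[ed$parent[kids]]
  seeds <- !same
  expect_true(all(ed$lobe[kids][seeds] != "TRACHEA_MAIN" |
                    ed$lobe[ed$parent[kids]][seeds] == "TRACHEA_MAIN"))
})
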