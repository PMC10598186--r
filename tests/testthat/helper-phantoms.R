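# Shared phantom fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# single-tube phantom: a root branch from `start` along `dir` with length L
tube_phantom <- function(r, spacing, L = 40, dir = c(0, 0, -1),
                         amplitude = 0, cycles = 1, r1 = r) {
  dir <- dir / sqrt(sum(dir^2))
  start <- c(0, 0, L / 2 * abs(dir[3]) + L / 4)
  br <- list(phantom_branch(1, NA, start, start + dir * L, r0 = r, r1 = r1,
                            amplitude_mm = amplitude, cycles = cycles))
  rasterize_phantom(phantom_spec(br, spacing = spacing))
}

# skeleton -> graph chain used by several tests
graph_from_mask <- function(mask, ...) {
  seed <- find_trachea_seed(mask)
  sk <- skeletonize(mask, seed)
  sk <- break_cycles(sk)
  sk <- prune_spurs(sk)
  sk <- trim_tips(sk)
  sk <- prune_spurs(sk)
  skeleton_to_graph(sk, ...)
}

# Y phantom: vertical trachea splitting into two oblique children
y_phantom <- function(spacing = c(0.8, 0.8, 0.8)) {
  br <- list(
    phantom_branch(1, NA, c(0, 0, 40), c(0, 0, 10), r0 = 3),
    phantom_branch(2, 1, c(0, 0, 10), c(16, 0, -12), r0 = 2.2),
    phantom_branch(3, 1, c(0, 0, 10), c(-16, 0, -12), r0 = 2.2))
  rasterize_phantom(phantom_spec(br, spacing = spacing))
}

# small six-lobe tree fit, shared across anatomy / metrics / acceptance
tree_fit <- function() fixture("tree_fit", function() {
  ph <- rasterize_phantom(phantom_spec(
    phantom_airway_tree(taper = 0.25, max_generation = 4),
    spacing = c(0.8, 0.8, 0.8)))
  list(phantom = ph,
       fit = bronchiq(ph$volume, ph$mask,
                      control = bronchiq_control(gen_lo = 2, gen_hi = 4)))
})

# hand-built airway graph for anatomy unit tests: straight vertical paths
# are irrelevant there, only topology and directions matter
toy_graph <- function(edges, node_xyz) {
  nodes <- data.frame(id = seq_len(nrow(node_xyz)),
                      i = 0L, j = 0L, k = 0L,
                      x = node_xyz[, 1], y = node_xyz[, 2], z = node_xyz[, 3])
  paths <- lapply(seq_len(nrow(edges)), function(e) {
    rbind(as.integer(round(node_xyz[edges$from[e], ])),
          as.integer(round(node_xyz[edges$to[e], ])))
  })
  structure(list(nodes = nodes,
                 edges = data.frame(id = seq_len(nrow(edges)),
                                    from = edges$from, to = edges$to,
                                    parent = edges$parent,
                                    length_mm = 1,
                                    generation = NA_integer_,
                                    lobe = NA_character_,
                                    stringsAsFactors = FALSE),
                 paths = paths, root_node = 1L,
                 dims = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                 origin = c(0, 0, 0), log = list()),
            class = "airway_graph")
}

expect_tree_invariants <- function(graph) {
  expect_equal(nrow(graph$edges), nrow(graph$nodes) - 1L)
  roots <- which(is.na(graph$edges$parent))
  non_root_nodes <- setdiff(graph$nodes$id, graph$root_node)
  expect_setequal(graph$edges$to, non_root_nodes)
  expect_false(any(duplicated(graph$edges$to)))
}
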