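## Lobe and generation labelling of airway graph segments.

# unit direction (world mm) of an edge, proximal -> distal
.edge_direction <- function(graph, e) {
  p <- graph$paths[[e]]
  w <- .voxel_to_world(p, graph$spacing, graph$origin)
  d <- w[nrow(w), ] - w[1, ]
  n <- sqrt(sum(d^2))
  if (n < 1e-9) c(0, 0, 0) else d / n
}

.children_of <- function(graph, e) {
  which(!is.na(graph$edges$parent) & graph$edges$parent == e)
}

.edges_from_node <- function(graph, nd) which(graph$edges$from == nd)

# all edges in the subtree rooted at edge e (inclusive)
.subtree_edges <- function(graph, e) {
  out <- e
  frontier <- e
  while (length(frontier)) {
    kids <- which(graph$edges$parent %in% frontier)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Assign airway generations
#'
#' Generations are counted sequentially from the trachea: the trachea
#' edge(s) leaving the root node are generation 0, and a new generation is
#' produced every time an airway divides, so each child edge gets its
#' parent's generation plus one. With this origin the main bronchi are
#' generation 1 and the lobar bronchi are typically generation 2.
#'
#' @param graph an \code{airway_graph}.
#' @return The graph with \code{edges$generation} filled in.
#' @export
assign_generations <- function(graph) {
  stopifnot(inherits(graph, "airway_graph"))
  gen <- rep(NA_integer_, nrow(graph$edges))
  roots <- which(is.na(graph$edges$parent))
  gen[roots] <- 0L
  frontier <- roots
  while (length(frontier)) {
    kids <- which(graph$edges$parent %in% frontier)
    if (!length(kids)) break
    gen[kids] <- gen[graph$edges$parent[kids]] + 1L
    frontier <- kids
  }
  graph$edges$generation <- gen
  graph
}

#' Lobar generation (generation counted from the lobar bronchus)
#'
#' For each segment, its global generation minus the generation of the
#' seeding (first) segment of its lobe. Trachea/main segments get NA.
#'
#' @param graph an \code{airway_graph} with generations and lobes assigned.
#' @return Integer vector, one value per edge.
#' @export
lobar_generation <- function(graph) {
  ed <- graph$edges
  out <- rep(NA_integer_, nrow(ed))
  for (lb in setdiff(unique(ed$lobe), c(NA, "TRACHEA_MAIN"))) {
    in_lobe <- which(ed$lobe == lb)
    seed_gen <- min(ed$generation[in_lobe])
    out[in_lobe] <- ed$generation[in_lobe] - seed_gen
  }
  out
}

#' Classify segments into lung lobes
#'
#' Direction-based heuristic in RAS space. At the first division below the
#' trachea the child with the most rightward mean direction is the right
#' main bronchus and the most leftward child the left main bronchus. On each
#' side, at the first division below the main bronchus the most
#' superior-directed child seeds the upper lobe (RUL/LUL); when a single
#' sibling remains it is treated as the intermediate bronchus (labelled with
#' the trachea/main class) and at its next division the most
#' anterior-directed child seeds the middle lobe (RML, or LML for the
#' lingula) with the remainder seeding the lower lobe; when several siblings
#' remain the middle/lower split is applied to them directly. The same rule
#' is used on both sides (the lingula is treated as the left middle lobe),
#' which makes the labelling exactly mirror-symmetric: reflecting the image
#' left-right swaps R and L labels.
#'
#' Every descendant inherits its seed's lobe. Entries of \code{overrides}
#' (node id -> lobe) relabel the whole subtree hanging from that node and
#' take precedence over the heuristic.
#'
#' @param graph an \code{airway_graph} with generations assigned.
#' @param overrides optional data frame with columns \code{node_id},
#'   \code{lobe}, or a named character vector (names = node ids).
#' @return The graph with \code{edges$lobe} filled in and a logical
#'   \code{edges$lobe_flagged} column marking heuristic fallbacks.
#' @export
classify_lobes <- function(graph, overrides = NULL) {
  stopifnot(inherits(graph, "airway_graph"))
  if (all(is.na(graph$edges$generation)))
    stop("assign generations before classifying lobes")
  ne <- nrow(graph$edges)
  lobe <- rep(NA_character_, ne)
  flagged <- logical(ne)

  dirs <- t(vapply(seq_len(ne), function(e) .edge_direction(graph, e),
                   numeric(3)))

  # trachea: follow single-child chain from the root edge(s) to the first
  # division
  roots <- which(is.na(graph$edges$parent))
  lobe[roots] <- "TRACHEA_MAIN"
  first_div <- NULL
  cur <- roots
  repeat {
    if (length(cur) != 1L) { first_div <- NULL; break }
    kids <- .children_of(graph, cur)
    if (length(kids) >= 2L) { first_div <- cur; div_kids <- kids; break }
    if (!length(kids)) { first_div <- NULL; break }
    lobe[kids] <- "TRACHEA_MAIN"
    cur <- kids
  }
  if (is.null(first_div)) {
    warning("no division below the trachea; labelling everything TRACHEA_MAIN")
    graph$edges$lobe <- ifelse(is.na(lobe), "TRACHEA_MAIN", lobe)
    graph$edges$lobe_flagged <- TRUE
    return(graph)
  }

  label_subtree <- function(seed_edge, lb) {
    sub <- .subtree_edges(graph, seed_edge)
    lobe[sub] <<- lb
  }

  classify_side <- function(main_edge, upper, middle, lower) {
    lobe[main_edge] <<- "TRACHEA_MAIN"
    cur <- main_edge
    repeat {
      kids <- .children_of(graph, cur)
      if (!length(kids)) return(invisible(NULL))
      if (length(kids) >= 2L) break
      lobe[kids] <<- "TRACHEA_MAIN"
      cur <- kids
    }
    sup <- kids[which.max(dirs[kids, 3])]
    label_subtree(sup, upper)
    rest <- setdiff(kids, sup)
    if (length(rest) == 1L) {
      # intermediate bronchus: descend to its next division
      lobe[rest] <<- "TRACHEA_MAIN"
      cur <- rest
      repeat {
        kids2 <- .children_of(graph, cur)
        if (!length(kids2)) { flagged[cur] <<- TRUE; return(invisible(NULL)) }
        if (length(kids2) >= 2L) break
        lobe[kids2] <<- "TRACHEA_MAIN"
        cur <- kids2
      }
      mid <- kids2[which.max(dirs[kids2, 2])]
      label_subtree(mid, middle)
      for (k in setdiff(kids2, mid)) label_subtree(k, lower)
    } else if (length(rest) >= 2L) {
      mid <- rest[which.max(dirs[rest, 2])]
      label_subtree(mid, middle)
      for (k in setdiff(rest, mid)) label_subtree(k, lower)
    }
    invisible(NULL)
  }

  rmain <- div_kids[which.max(dirs[div_kids, 1])]
  lmain <- div_kids[which.min(dirs[div_kids, 1])]
  classify_side(rmain, "RUL", "RML", "RLL")
  classify_side(lmain, "LUL", "LML", "LLL")
  extras <- setdiff(div_kids, c(rmain, lmain))
  for (e in extras) {
    lb <- if (dirs[e, 1] > 0) "RLL" else "LLL"
    label_subtree(e, lb)
    flagged[.subtree_edges(graph, e)] <- TRUE
  }

  # unresolved segments: inherit the nearest labelled ancestor, flagged
  unresolved <- which(is.na(lobe))
  for (e in unresolved) {
    p <- graph$edges$parent[e]
    while (!is.na(p) && is.na(lobe[p])) p <- graph$edges$parent[p]
    lobe[e] <- if (!is.na(p)) lobe[p] else "TRACHEA_MAIN"
    flagged[e] <- TRUE
  }

  # explicit overrides win
  if (!is.null(overrides)) {
    if (is.data.frame(overrides)) {
      ov_nodes <- overrides$node_id
      ov_lobes <- as.character(overrides$lobe)
    } else {
      ov_nodes <- as.integer(names(overrides))
      ov_lobes <- as.character(overrides)
    }
    bad <- !(ov_lobes %in% .lobe_levels)
    if (any(bad)) stop("unknown lobe label(s): ",
                       paste(unique(ov_lobes[bad]), collapse = ", "))
    # apply shallow nodes first so deeper overrides refine them
    depth <- graph$edges$generation[match(ov_nodes, graph$edges$from)]
    ord <- order(ifelse(is.na(depth), Inf, depth))
    for (i in ord) {
      seeds <- .edges_from_node(graph, ov_nodes[i])
      for (s in seeds) {
        sub <- .subtree_edges(graph, s)
        lobe[sub] <- ov_lobes[i]
        flagged[sub] <- FALSE
      }
    }
  }

  graph$edges$lobe <- lobe
  graph$edges$lobe_flagged <- flagged
  graph
}

#' Select segments in a generation window
#'
#' Returns the segments with \code{gen_lo <= generation <= gen_hi}, ordered
#' by lobe then generation, for lobar-basis analysis. Defaults select
#' generations 2-6 (lobar bronchi and the four divisions below them when
#' the trachea is generation 0).
#'
#' @param graph an \code{airway_graph} with generations assigned.
#' @param gen_lo,gen_hi inclusive generation bounds, \code{0 <= gen_lo <=
#'   gen_hi}.
#' @return A data frame of edge rows (columns of \code{graph$edges}).
#' @export
select_analysis_window <- function(graph, gen_lo = 2, gen_hi = 6) {
  stopifnot(inherits(graph, "airway_graph"),
            gen_lo >= 0, gen_lo <= gen_hi)
  ed <- graph$edges
  sel <- ed[!is.na(ed$generation) & ed$generation >= gen_lo &
              ed$generation <= gen_hi, , drop = FALSE]
  sel[order(match(sel$lobe, .lobe_levels), sel$generation, sel$id), ,
      drop = FALSE]
}
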