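## Skeletonization and conversion to a rooted acyclic airway graph.
##
## A skeleton is stored as an ordered set of 0-based voxel triples plus the
## grid geometry; the graph keeps, per edge, the ordered voxel chain from the
## parent node to the child node.

.lin_index <- function(vox, dims) {
  vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3])
}

.offsets26 <- local({
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

# neighbour row indices within the skeleton for each voxel: list of integer
# vectors (rows into `vox`)
.skel_adjacency <- function(vox, dims) {
  n <- nrow(vox)
  lin <- .lin_index(vox, dims)
  ord <- order(lin)
  lin_s <- lin[ord]
  adj <- vector("list", n)
  for (k in seq_len(nrow(.offsets26))) {
    off <- .offsets26[k, ]
    cand <- sweep(vox, 2, off, `+`)
    ok <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
      cand[, 2] >= 0 & cand[, 2] < dims[2] &
      cand[, 3] >= 0 & cand[, 3] < dims[3]
    cl <- cand[, 1] + dims[1] * (cand[, 2] + dims[2] * cand[, 3])
    pos <- findInterval(cl, lin_s)
    hit <- ok & pos > 0 & lin_s[pmax(pos, 1)] == cl
    w <- which(hit)
    tgt <- ord[pos[hit]]
    for (i in seq_along(w)) adj[[w[i]]] <- c(adj[[w[i]]], tgt[i])
  }
  lapply(adj, sort)
}

.new_skeleton <- function(vox, dims, spacing, origin, root,
                          dt_mm = NULL, n_cycles_broken = 0L,
                          n_spurs_pruned = 0L, n_tip_trimmed = 0L) {
  structure(list(voxels = vox, dims = dims, spacing = spacing,
                 origin = origin, root = root, dt_mm = dt_mm,
                 n_cycles_broken = n_cycles_broken,
                 n_spurs_pruned = n_spurs_pruned,
                 n_tip_trimmed = n_tip_trimmed),
            class = "airway_skeleton")
}

#' @export
print.airway_skeleton <- function(x, ...) {
  cat("airway_skeleton:", nrow(x$voxels), "voxels, root at (",
      paste(x$voxels[x$root, ], collapse = ", "), ")\n")
  invisible(x)
}

#' Locate a trachea seed voxel
#'
#' Finds a seed inside the trachea as the centroid-nearest foreground voxel
#' of the largest connected component within the most superior 5% of axial
#' slices that contain foreground. Assumes RAS orientation (third axis
#' points superiorly).
#'
#' @param mask a [binary_mask()].
#' @return 0-based voxel index triple (integer length 3).
#' @export
find_trachea_seed <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  dims <- dim(mask$data)
  zs <- which(apply(mask$data, 3, any))
  if (!length(zs)) stop("mask has no foreground in any axial slice")
  nslab <- max(1L, ceiling(0.05 * length(zs)))
  slab_z <- utils::tail(zs, nslab)
  slab <- array(FALSE, dim = dims)
  slab[, , slab_z] <- mask$data[, , slab_z]
  if (!any(slab)) stop("no foreground in the superior slab")
  lab <- array(cpp_label_components(as.logical(slab), dims), dim = dims)
  keep <- which.max(tabulate(lab[lab > 0]))
  comp <- which(lab == keep, arr.ind = TRUE)  # 1-based
  topz <- max(comp[, 3])
  top <- comp[comp[, 3] == topz, , drop = FALSE]
  cen <- colMeans(top[, 1:2, drop = FALSE])
  d2 <- (top[, 1] - cen[1])^2 + (top[, 2] - cen[2])^2
  as.integer(top[which.min(d2), ] - 1L)
}

#' Skeletonize an airway mask
#'
#' Topology-preserving 3D thinning of the mask to a one-voxel-thick
#' centreline (distance-ordered homotopic thinning with curve-endpoint
#' preservation), retaining only the skeleton component containing (nearest
#' to) the trachea seed.
#'
#' @param mask a [binary_mask()].
#' @param seed 0-based voxel triple from [find_trachea_seed()]; must be
#'   foreground.
#' @return An \code{airway_skeleton}.
#' @export
skeletonize <- function(mask, seed) {
  stopifnot(inherits(mask, "binary_mask"))
  dims <- dim(mask$data)
  if (!mask$data[seed[1] + 1, seed[2] + 1, seed[3] + 1])
    stop("seed voxel (", paste(seed, collapse = ", "), ") is not foreground")
  seed_lin <- as.integer(seed[1] + dims[1] * (seed[2] + dims[2] * seed[3]))
  sk <- array(cpp_thin(as.logical(mask$data), dims, seed_lin), dim = dims)
  vox1 <- which(sk, arr.ind = TRUE)
  vox <- vox1 - 1L
  ord <- order(.lin_index(vox, dims))
  vox <- vox[ord, , drop = FALSE]
  # component containing the skeleton voxel nearest the seed (world mm)
  lab <- array(cpp_label_components(as.logical(sk), dims), dim = dims)
  d2 <- colSums((t(vox) - as.numeric(seed))^2 * mask$spacing^2)
  near <- which.min(d2)
  keep_lab <- lab[vox[near, 1] + 1, vox[near, 2] + 1, vox[near, 3] + 1]
  in_comp <- lab[vox + 1L] == keep_lab
  vox <- vox[in_comp, , drop = FALSE]
  d2 <- d2[in_comp]
  # mask distance-to-boundary at the skeleton voxels (chamfer 3-4-5, one
  # face step = 3 units), in mm via the smallest voxel dimension
  dt <- cpp_chamfer_dt(as.logical(mask$data), dims)
  dt_mm <- dt[.lin_index(vox, dims) + 1L] / 3 * min(mask$spacing)
  .new_skeleton(vox, dims, mask$spacing, mask$origin, root = which.min(d2),
                dt_mm = dt_mm)
}

.skel_igraph <- function(skel, adj = NULL) {
  if (is.null(adj)) adj <- .skel_adjacency(skel$voxels, skel$dims)
  n <- nrow(skel$voxels)
  from <- rep.int(seq_len(n), lengths(adj))
  to <- unlist(adj, use.names = FALSE)
  keep <- from < to
  el <- cbind(from[keep], to[keep])
  w <- sqrt(rowSums(((skel$voxels[el[, 1], , drop = FALSE] -
                        skel$voxels[el[, 2], , drop = FALSE]) *
                       rep(skel$spacing, each = nrow(el)))^2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  g
}

# shortest-path tree parents over the skeleton voxels (NA for the root)
.skel_tree_parents <- function(skel, g = NULL) {
  if (is.null(g)) g <- .skel_igraph(skel)
  sp <- igraph::shortest_paths(g, from = skel$root, to = igraph::V(g),
                               predecessors = TRUE)
  pred <- as.integer(sp$predecessors)
  pred[skel$root] <- NA_integer_
  pred
}

# children list from a parent vector
.skel_children <- function(parent) {
  n <- length(parent)
  ch <- vector("list", n)
  has <- which(!is.na(parent))
  sp <- split(has, parent[has])
  ch[as.integer(names(sp))] <- lapply(sp, sort)
  ch
}

# subset a skeleton to `keep` (kept voxels must not be parents of dropped
# descendants' kept children -- callers only drop whole leaf chains or
# recompute the tree afterwards)
.skel_subset <- function(skel, keep, new_root = skel$root) {
  remap <- match(seq_len(nrow(skel$voxels)), keep)
  skel$voxels <- skel$voxels[keep, , drop = FALSE]
  if (!is.null(skel$dt_mm)) skel$dt_mm <- skel$dt_mm[keep]
  if (!is.null(skel$parent)) {
    p <- skel$parent[keep]
    skel$parent <- ifelse(is.na(p), NA_integer_, remap[p])
  }
  skel$root <- remap[new_root]
  skel
}

#' Derive the rooted spanning structure and break genuine cycles
#'
#' Computes a shortest-path spanning tree from the root over the skeleton's
#' 26-neighbourhood voxel adjacency (edge weight = Euclidean step length).
#' Non-tree adjacencies whose fundamental cycle is short (below
#' \code{min_cycle_mm}) are discretization artifacts of diagonal
#' connectivity at curve corners and are simply ignored; longer ones are
#' genuine loops (e.g. from segmentation leaks between airways): for each,
#' the voxel midway along the cycle is deleted and the tree recomputed,
#' until none remain. The break count is recorded in
#' \code{n_cycles_broken}; the resulting parent structure is stored on the
#' skeleton and used by all downstream stages.
#'
#' @param skeleton an \code{airway_skeleton}.
#' @param min_cycle_mm cycles shorter than this are treated as adjacency
#'   artifacts, not loops.
#' @return An \code{airway_skeleton} with tree structure attached.
#' @export
break_cycles <- function(skeleton, min_cycle_mm = 5) {
  stopifnot(inherits(skeleton, "airway_skeleton"))
  broken <- skeleton$n_cycles_broken
  repeat {
    g <- .skel_igraph(skeleton)
    pred <- .skel_tree_parents(skeleton, g)
    if (anyNA(pred[-skeleton$root]))
      stop("skeleton is not connected")
    el <- igraph::as_edgelist(g)
    ew <- igraph::E(g)$weight
    tree_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    tv <- which(!is.na(pred))
    tset <- tree_key(tv, pred[tv])
    nontree <- which(!(tree_key(el[, 1], el[, 2]) %in% tset))
    if (!length(nontree)) break
    # arc length from every voxel back to the root along the tree
    dist_root <- igraph::distances(g, v = skeleton$root,
                                   weights = igraph::E(g)$weight)[1, ]
    path_to_root <- function(v) {
      p <- v
      while (!is.na(pred[v])) { v <- pred[v]; p <- c(p, v) }
      p
    }
    cyc <- NULL
    nontree <- nontree[order(pmin(el[nontree, 1], el[nontree, 2]),
                             pmax(el[nontree, 1], el[nontree, 2]))]
    for (e in nontree) {
      u <- el[e, 1]; v <- el[e, 2]
      pu <- path_to_root(u); pv <- path_to_root(v)
      common <- intersect(pu, pv)
      lca <- common[1]
      arc <- dist_root[u] + dist_root[v] - 2 * dist_root[lca] + ew[e]
      if (arc >= min_cycle_mm) {
        lca_u <- which(pu == lca); lca_v <- which(pv == lca)
        cyc <- c(pu[seq_len(lca_u)], rev(pv[seq_len(lca_v - 1L)]))
        break
      }
    }
    if (is.null(cyc)) break  # only artifact adjacencies remain
    # delete near the cycle's midpoint, but avoid the root and junction
    # voxels so side branches hanging off the loop are not stranded
    deg <- igraph::degree(g)
    mid_pos <- max(2L, min(length(cyc) - 1L, ceiling(length(cyc) / 2)))
    cand <- order(abs(seq_along(cyc) - mid_pos))
    cand <- cand[cand > 1L & cand < length(cyc)]
    ok_pos <- cand[cyc[cand] != skeleton$root & deg[cyc[cand]] == 2L]
    mid <- cyc[if (length(ok_pos)) ok_pos[1] else mid_pos]
    keep <- setdiff(seq_len(nrow(skeleton$voxels)), mid)
    skeleton$parent <- NULL
    skeleton <- .skel_subset(skeleton, keep)
    broken <- broken + 1L
    # deleting a cycle voxel may strand a side branch; keep the root side
    adj <- .skel_adjacency(skeleton$voxels, skeleton$dims)
    g2 <- .skel_igraph(skeleton, adj)
    comp <- igraph::components(g2)$membership
    skeleton <- .skel_subset(skeleton, which(comp == comp[skeleton$root]))
  }
  skeleton$parent <- pred
  skeleton$n_cycles_broken <- broken
  skeleton
}

# make sure the spanning structure exists
.skel_need_tree <- function(skeleton) {
  if (is.null(skeleton$parent))
    skeleton$parent <- .skel_tree_parents(skeleton)
  skeleton
}

#' Prune short terminal spurs
#'
#' Thinning of bumpy masks creates short spurious side-branches. Terminal
#' chains whose arc length from tip to the nearest branching of the
#' spanning structure is below \code{min_mm} are removed (the root's own
#' chain is protected). The removed voxel count is recorded in
#' \code{n_spurs_pruned}.
#'
#' @param skeleton an \code{airway_skeleton} (after [break_cycles()]).
#' @param min_mm spur length threshold in mm.
#' @return An \code{airway_skeleton}.
#' @export
prune_spurs <- function(skeleton, min_mm = 2) {
  stopifnot(inherits(skeleton, "airway_skeleton"))
  skeleton <- .skel_need_tree(skeleton)
  pruned <- skeleton$n_spurs_pruned
  repeat {
    vox <- skeleton$voxels
    parent <- skeleton$parent
    ch <- .skel_children(parent)
    nch <- lengths(ch)
    leaves <- which(nch == 0L & seq_along(nch) != skeleton$root)
    drop <- integer(0)
    for (leaf in leaves) {
      chain <- leaf
      cur <- leaf
      len <- 0
      repeat {
        p <- parent[cur]
        if (is.na(p)) break
        len <- len + sqrt(sum(((vox[p, ] - vox[cur, ]) *
                                 skeleton$spacing)^2))
        if (nch[p] != 1L || p == skeleton$root) break
        cur <- p; chain <- c(chain, cur)
      }
      # junction bulges spawn anchor spurs up to the local lumen radius, so
      # the threshold adapts to the distance transform at the attachment
      thr <- min_mm
      if (!is.null(skeleton$dt_mm) && !is.na(p))
        thr <- max(thr, 1.2 * skeleton$dt_mm[p] + min(skeleton$spacing))
      if (len < thr && length(chain) < nrow(vox) - 1L)
        drop <- union(drop, chain)
    }
    if (!length(drop)) break
    skeleton <- .skel_subset(skeleton, setdiff(seq_len(nrow(vox)), drop))
    pruned <- pruned + length(drop)
  }
  skeleton$n_spurs_pruned <- pruned
  skeleton
}

#' Retract skeleton tips to the medial endpoint
#'
#' Endpoint-preserving thinning traces terminal branches all the way to the
#' extremity of the mask (e.g. the apex of a rounded airway tip), which
#' overshoots the medial axis by roughly the local lumen radius and would
#' bias terminal segment lengths and diameters. Along such an overshoot the
#' mask distance transform climbs with arc distance from the tip (slope
#' about 1 inside a rounded cap) and plateaus at the local radius once the
#' tube body is reached; each terminal chain (and the root's own chain) is
#' retracted to the farthest voxel of the cap-like climb. The removed voxel
#' count is recorded in \code{n_tip_trimmed}.
#'
#' @param skeleton an \code{airway_skeleton} (with its stored distance
#'   transform; returned unchanged if absent).
#' @param max_trim_mm upper bound on the retraction per tip.
#' @return An \code{airway_skeleton}.
#' @export
trim_tips <- function(skeleton, max_trim_mm = 12) {
  stopifnot(inherits(skeleton, "airway_skeleton"))
  if (is.null(skeleton$dt_mm)) return(skeleton)
  skeleton <- .skel_need_tree(skeleton)
  vox <- skeleton$voxels
  parent <- skeleton$parent
  ch <- .skel_children(parent)
  nch <- lengths(ch)

  trim_plan <- function(chain) {
    # chain runs tip-first; returns kept-voxel position or NULL. The medial
    # endpoint of a rounded tip lies one local radius inside the apex, so
    # the retraction is the local radius (distance-transform plateau) minus
    # the tip's own boundary distance.
    if (length(chain) < 3L) return(NULL)
    d <- skeleton$dt_mm[chain]
    step <- sqrt(rowSums((diff(vox[chain, , drop = FALSE]) *
                            rep(skeleton$spacing,
                                each = length(chain) - 1L))^2))
    s <- c(0, cumsum(step))
    retract <- min(max_trim_mm, max(0, max(d) - d[1]))
    if (retract <= 0) return(NULL)
    j <- which(s >= retract - 1e-9)[1]
    if (is.na(j) || j < 2L) return(NULL)
    min(j, length(chain))
  }

  drop <- integer(0)
  new_root <- skeleton$root
  leaves <- which(nch == 0L & seq_along(nch) != skeleton$root)
  for (leaf in leaves) {
    chain <- leaf
    cur <- leaf
    arc <- 0
    repeat {
      p <- parent[cur]
      if (is.na(p) || nch[p] != 1L || p == skeleton$root) break
      arc <- arc + sqrt(sum(((vox[p, ] - vox[cur, ]) * skeleton$spacing)^2))
      if (arc > max_trim_mm) break
      cur <- p; chain <- c(chain, cur)
    }
    j <- trim_plan(chain)
    if (!is.null(j)) drop <- union(drop, chain[seq_len(j - 1L)])
  }
  # the root end of the trachea is a tip too
  chain <- skeleton$root
  cur <- skeleton$root
  arc <- 0
  while (nch[cur] == 1L && arc <= max_trim_mm) {
    nxt <- ch[[cur]]
    arc <- arc + sqrt(sum(((vox[nxt, ] - vox[cur, ]) * skeleton$spacing)^2))
    cur <- nxt
    chain <- c(chain, cur)
  }
  j <- trim_plan(chain)
  if (!is.null(j)) {
    drop <- union(drop, chain[seq_len(j - 1L)])
    new_root <- chain[j]
  }

  if (length(drop)) {
    keep <- setdiff(seq_len(nrow(vox)), drop)
    skeleton <- .skel_subset(skeleton, keep, new_root = new_root)
    skeleton$parent[skeleton$root] <- NA_integer_
    skeleton$n_tip_trimmed <- skeleton$n_tip_trimmed + length(drop)
  }
  skeleton
}

#' Convert a skeleton into an airway graph
#'
#' Nodes are placed where the rooted spanning structure branches or ends
#' (voxels with a number of children different from one, plus the root);
#' edges are the maximal single-child chains between nodes, oriented
#' proximal to distal. Internal edges shorter than \code{min_edge_mm} are
#' merged into their parent edge (the junction moves distally, producing an
#' effective trifurcation), and the merge count is logged.
#'
#' @param skeleton an acyclic, connected \code{airway_skeleton} (after
#'   [break_cycles()]).
#' @param min_edge_mm minimum internal edge length in mm (default 2).
#' @return An object of class \code{airway_graph} with elements
#'   \code{nodes} (data frame: id, voxel indices, world mm position),
#'   \code{edges} (data frame: id, from, to, parent, length_mm, generation,
#'   lobe), \code{paths} (list of 0-based voxel matrices, parent node
#'   first), \code{root_node}, and grid geometry.
#' @export
skeleton_to_graph <- function(skeleton, min_edge_mm = 2) {
  stopifnot(inherits(skeleton, "airway_skeleton"))
  skeleton <- .skel_need_tree(skeleton)
  vox <- skeleton$voxels
  if (nrow(vox) < 2L) stop("skeleton has fewer than 2 voxels")
  parent <- skeleton$parent
  ch <- .skel_children(parent)
  nch <- lengths(ch)
  root_row <- skeleton$root
  node_rows <- sort(union(which(nch != 1L), root_row))

  # trace chains node -> node in breadth-first order from the root
  paths <- list()
  efrom <- eto <- integer(0)
  parent_edge <- integer(0)
  queue <- list(list(node = root_row, pedge = NA_integer_))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    nd <- item$node
    for (c0 in ch[[nd]]) {
      chain <- c(nd, c0)
      cur <- c0
      while (!(cur %in% node_rows)) {
        cur <- ch[[cur]]
        chain <- c(chain, cur)
      }
      paths[[length(paths) + 1L]] <- chain
      efrom <- c(efrom, nd); eto <- c(eto, cur)
      parent_edge <- c(parent_edge, item$pedge)
      queue[[length(queue) + 1L]] <- list(node = cur,
                                          pedge = length(paths))
    }
  }
  if (!length(paths)) stop("skeleton graph has no edges")

  step_len <- function(chain) {
    d <- diff(vox[chain, , drop = FALSE] *
                rep(skeleton$spacing, each = length(chain)))
    sum(sqrt(rowSums(d^2)))
  }
  elen <- vapply(paths, step_len, 0)

  # merge short internal edges into their parent (junction slides distally)
  n_merged <- 0L
  repeat {
    child_of <- function(e) which(!is.na(parent_edge) & parent_edge == e)
    short <- which(elen < min_edge_mm & !is.na(parent_edge) &
                     vapply(seq_along(paths),
                            function(e) length(child_of(e)) > 0, TRUE))
    if (!length(short)) break
    e <- short[1]
    p <- parent_edge[e]
    paths[[p]] <- c(paths[[p]], paths[[e]][-1])
    eto[p] <- eto[e]
    elen[p] <- elen[p] + elen[e]
    for (k in child_of(e)) parent_edge[k] <- p
    keep <- setdiff(seq_along(paths), e)
    paths <- paths[keep]
    efrom <- efrom[keep]; eto <- eto[keep]; elen <- elen[keep]
    parent_edge <- match(parent_edge[keep], keep)
    n_merged <- n_merged + 1L
  }

  used_nodes <- sort(unique(c(efrom, eto, root_row)))
  nid <- match(seq_len(nrow(vox)), used_nodes)
  world <- .voxel_to_world(vox[used_nodes, , drop = FALSE],
                           skeleton$spacing, skeleton$origin)
  nodes <- data.frame(id = seq_along(used_nodes),
                      i = vox[used_nodes, 1], j = vox[used_nodes, 2],
                      k = vox[used_nodes, 3],
                      x = world[, 1], y = world[, 2], z = world[, 3])
  edges <- data.frame(id = seq_along(paths),
                      from = nid[efrom], to = nid[eto],
                      parent = parent_edge,
                      length_mm = elen,
                      generation = NA_integer_,
                      lobe = NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 paths = lapply(paths, function(cc) vox[cc, , drop = FALSE]),
                 root_node = nid[root_row],
                 dims = skeleton$dims, spacing = skeleton$spacing,
                 origin = skeleton$origin,
                 log = list(n_skeleton_voxels = nrow(vox),
                            n_cycles_broken = skeleton$n_cycles_broken,
                            n_spurs_pruned = skeleton$n_spurs_pruned,
                            n_tip_voxels_trimmed =
                              if (is.null(skeleton$n_tip_trimmed)) 0L else
                                skeleton$n_tip_trimmed,
                            n_short_edges_merged = n_merged)),
            class = "airway_graph")
}

#' @export
print.airway_graph <- function(x, ...) {
  cat("airway_graph:", nrow(x$edges), "segments,", nrow(x$nodes),
      "nodes, root node", x$root_node, "\n")
  if (!all(is.na(x$edges$generation)))
    cat("  generations 0 ..", max(x$edges$generation, na.rm = TRUE), "\n")
  if (!all(is.na(x$edges$lobe)))
    cat("  lobes:", paste(sort(unique(x$edges$lobe)), collapse = " "), "\n")
  invisible(x)
}
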