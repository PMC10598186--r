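## Synthetic CT airway-tree phantoms with analytic ground truth.
##
## A phantom is a declarative list of tube branches (straight chord plus an
## optional in-plane sinusoidal displacement, linear radius taper along the
## branch). The radial intensity model is a dark lumen, a bright Gaussian
## wall and intermediate parenchyma; the Gaussian wall is centred at
## r + sigma*sqrt(2*log(2)) so that the declared lumen radius is exactly the
## inner half-maximum radius of the wall profile -- the quantity the FWHM
## caliper estimates.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length direction")
  v / n
}

.rotate <- function(v, axis, theta) {
  a <- .unit(axis)
  v * cos(theta) + c(a[2] * v[3] - a[3] * v[2],
                     a[3] * v[1] - a[1] * v[3],
                     a[1] * v[2] - a[2] * v[1]) * sin(theta) +
    a * sum(a * v) * (1 - cos(theta))
}

.sin_normal <- function(chord) {
  n <- c(chord[2] * 1 - chord[3] * 0,
         chord[3] * 0 - chord[1] * 1,
         chord[1] * 0 - chord[2] * 0)  # chord x z
  if (sqrt(sum(n^2)) < 1e-6) n <- c(1, 0, 0)
  .unit(n)
}

#' Declare one phantom branch
#'
#' @param id integer branch id (unique).
#' @param parent parent branch id or NA for the root.
#' @param start,end world mm endpoints; a child's start must coincide with
#'   its parent's end.
#' @param r0,r1 proximal and distal lumen radius in mm (linear taper); both
#'   > 0. \code{r1} defaults to \code{r0}.
#' @param amplitude_mm sinusoidal centreline displacement amplitude (0 =
#'   straight).
#' @param cycles number of full sine cycles along the branch.
#' @param lobe declared lobe label (one of TRACHEA_MAIN, RUL, RML, RLL, LUL,
#'   LML, LLL).
#' @return A \code{phantom_branch} list.
#' @export
phantom_branch <- function(id, parent, start, end, r0, r1 = r0,
                           amplitude_mm = 0, cycles = 1,
                           lobe = "TRACHEA_MAIN") {
  stopifnot(r0 > 0, r1 > 0, lobe %in% .lobe_levels)
  structure(list(id = as.integer(id), parent = as.integer(parent),
                 start = as.numeric(start), end = as.numeric(end),
                 r0 = r0, r1 = r1, amplitude_mm = amplitude_mm,
                 cycles = cycles, lobe = lobe),
            class = "phantom_branch")
}

# centreline point(s) of a branch at parameter t in [0,1]
.branch_points <- function(br, t) {
  chord <- br$end - br$start
  n <- .sin_normal(chord)
  disp <- br$amplitude_mm * sin(2 * pi * br$cycles * t)
  cbind(br$start[1] + chord[1] * t + n[1] * disp,
        br$start[2] + chord[2] * t + n[2] * disp,
        br$start[3] + chord[3] * t + n[3] * disp)
}

.branch_radius <- function(br, t) br$r0 + (br$r1 - br$r0) * t

#' Assemble a phantom specification
#'
#' Validates the declared tree (unique ids, single root, children starting
#' at their parent's end, root oriented superior to inferior) and fixes the
#' image grid. When \code{dims}/\code{origin} are omitted the grid is sized
#' automatically to contain the tree plus its walls with a margin.
#'
#' @param branches list of [phantom_branch()] objects.
#' @param spacing voxel spacing in mm.
#' @param dims,origin optional explicit grid.
#' @param lumen_hu,wall_peak_hu,background_hu intensity model (HU).
#' @param wall_sigma_mm Gaussian wall width in mm.
#' @param noise_sd_hu additive Gaussian noise SD (0 = none).
#' @param seed RNG seed used for the noise.
#' @return A \code{phantom_spec} object.
#' @export
phantom_spec <- function(branches, spacing = c(0.8, 0.8, 0.8),
                         dims = NULL, origin = NULL,
                         lumen_hu = -1000, wall_peak_hu = 0,
                         background_hu = -850, wall_sigma_mm = 0.6,
                         noise_sd_hu = 0, seed = 1L) {
  ids <- vapply(branches, function(b) b$id, 0L)
  if (anyDuplicated(ids)) stop("duplicate branch ids")
  parents <- vapply(branches, function(b) b$parent, 0L)
  roots <- which(is.na(parents))
  if (length(roots) != 1L) stop("phantom must have exactly one root branch")
  root <- branches[[roots]]
  if (root$end[3] >= root$start[3])
    stop("root branch must be oriented superior to inferior (start above end)")
  for (b in branches) {
    if (is.na(b$parent)) next
    p <- branches[[match(b$parent, ids)]]
    if (max(abs(b$start - p$end)) > 1e-6)
      stop("branch ", b$id, " does not start at the end of its parent ",
           b$parent)
  }
  # depth = number of divisions from the root
  depth <- rep(NA_integer_, length(branches))
  depth[roots] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      pd <- depth[match(parents[i], ids)]
      if (!is.na(pd)) { depth[i] <- pd + 1L; progressed <- TRUE }
    }
    if (!progressed) stop("branch parents do not form a tree")
  }

  if (is.null(dims) || is.null(origin)) {
    tt <- seq(0, 1, length.out = 33)
    allpts <- do.call(rbind, lapply(branches, .branch_points, t = tt))
    rmax <- max(vapply(branches, function(b) max(b$r0, b$r1), 0))
    margin <- rmax + wall_sigma_mm * (sqrt(2 * log(2)) + 3.5) + 1
    lo <- apply(allpts, 2, min) - margin
    hi <- apply(allpts, 2, max) + margin
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  }
  structure(list(branches = branches, ids = ids, depth = depth,
                 spacing = as.numeric(spacing), dims = as.integer(dims),
                 origin = as.numeric(origin),
                 lumen_hu = lumen_hu, wall_peak_hu = wall_peak_hu,
                 background_hu = background_hu,
                 wall_sigma_mm = wall_sigma_mm,
                 noise_sd_hu = noise_sd_hu, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", length(x$branches), "branches, grid",
      paste(x$dims, collapse = "x"), "at",
      paste(format(x$spacing), collapse = "x"), "mm\n")
  invisible(x)
}

# analytic truth table: per-branch lengths/diameters by fine quadrature
.phantom_truth <- function(spec) {
  nq <- 4000L
  tt <- seq(0, 1, length.out = nq + 1L)
  rows <- lapply(spec$branches, function(b) {
    pts <- .branch_points(b, tt)
    dl <- sqrt(rowSums(diff(pts)^2))
    arc <- sum(dl)
    eucl <- sqrt(sum((b$end - b$start)^2))
    rmid <- .branch_radius(b, (tt[-1] + tt[-(nq + 1)]) / 2)
    mean_d <- sum(2 * rmid * dl) / arc
    data.frame(id = b$id, parent = b$parent, lobe = b$lobe,
               depth = spec$depth[match(b$id, spec$ids)],
               r0 = b$r0, r1 = b$r1,
               amplitude_mm = b$amplitude_mm, cycles = b$cycles,
               mean_diameter_mm = mean_d,
               arc_length_mm = arc, euclidean_length_mm = eucl,
               tortuosity = max(arc / eucl, 1))
  })
  tr <- do.call(rbind, rows)
  dp <- tr$mean_diameter_mm[match(tr$parent, tr$id)]
  tr$tapering_vs_parent_pct <- 100 * (dp - tr$mean_diameter_mm) / dp
  tr
}

#' Rasterize a phantom into a CT volume, mask and truth table
#'
#' Renders the declared tube tree in HU with 2x supersampling for partial
#' volume realism (optionally with Gaussian noise, seeded), produces the
#' binary lumen mask (voxels with majority subvoxel occupancy), and computes
#' the analytic ground-truth table (mean diameter, arc and Euclidean length
#' by quadrature, tortuosity, tapering versus parent, lobe, depth).
#'
#' Unrelated branches (sharing no endpoint) that come closer than the sum of
#' their radii raise an error naming the pair; branches whose lumen leaves
#' the grid raise an error.
#'
#' @param spec a [phantom_spec()].
#' @param supersample supersampling factor (default 2).
#' @return List with \code{volume} ([image_volume()]), \code{mask}
#'   ([binary_mask()]), \code{truth} (data frame), \code{spec}.
#' @export
rasterize_phantom <- function(spec, supersample = 2L) {
  stopifnot(inherits(spec, "phantom_spec"))
  step <- min(spec$spacing) / (2 * supersample)

  # overlap check between unrelated branches (coarse polylines)
  nb <- length(spec$branches)
  ends <- lapply(spec$branches, function(b) rbind(b$start, b$end))
  coarse <- lapply(spec$branches, .branch_points,
                   t = seq(0, 1, length.out = 17))
  rmaxs <- vapply(spec$branches, function(b) max(b$r0, b$r1), 0)
  if (nb > 1) {
    for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
      shared <- any(apply(ends[[i]], 1, function(p)
        any(abs(ends[[j]][, 1] - p[1]) < 1e-6 &
              abs(ends[[j]][, 2] - p[2]) < 1e-6 &
              abs(ends[[j]][, 3] - p[3]) < 1e-6)))
      if (shared) next
      pi_ <- coarse[[i]]; pj <- coarse[[j]]
      d2 <- outer(rowSums(pi_^2), rowSums(pj^2), `+`) - 2 * pi_ %*% t(pj)
      if (sqrt(max(min(d2), 0)) < rmaxs[i] + rmaxs[j])
        stop("unrelated branches ", spec$branches[[i]]$id, " and ",
             spec$branches[[j]]$id, " overlap")
    }
  }

  samples <- do.call(rbind, lapply(spec$branches, function(b) {
    chord <- sqrt(sum((b$end - b$start)^2))
    arc_est <- chord + 8 * abs(b$amplitude_mm) * abs(b$cycles)
    nseg <- max(8L, ceiling(arc_est / step))
    tt <- seq(0, 1, length.out = nseg + 1L)
    cbind(.branch_points(b, tt), .branch_radius(b, tt))
  }))

  lo <- spec$origin - spec$spacing / 2
  hi <- spec$origin + (spec$dims - 0.5) * spec$spacing
  rall <- samples[, 4]
  if (any(samples[, 1] - rall < lo[1]) || any(samples[, 1] + rall > hi[1]) ||
      any(samples[, 2] - rall < lo[2]) || any(samples[, 2] + rall > hi[2]) ||
      any(samples[, 3] - rall < lo[3]) || any(samples[, 3] + rall > hi[3]))
    stop("a branch lumen exits the image grid; enlarge dims or the margin")

  ras <- cpp_rasterize(spec$dims, spec$spacing, spec$origin, samples,
                       spec$lumen_hu, spec$wall_peak_hu, spec$background_hu,
                       spec$wall_sigma_mm, as.integer(supersample))
  hu <- ras$hu
  if (spec$noise_sd_hu > 0) {
    set.seed(spec$seed)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd_hu)
  }
  vol <- image_volume(array(hu, dim = spec$dims), spec$spacing, spec$origin)
  msk <- binary_mask(array(ras$inside_frac >= 0.5, dim = spec$dims),
                     spec$spacing, spec$origin, reference = vol)
  list(volume = vol, mask = msk, truth = .phantom_truth(spec), spec = spec)
}

#' Build a six-lobe airway tree phantom
#'
#' Constructs a stylised human airway tree in RAS coordinates: a vertical
#' trachea, left and right main bronchi, an upper-lobe seed and an
#' intermediate bronchus on each side (the intermediate bronchus divides
#' into the middle- and lower-lobe seeds; the lingula plays the left middle
#' lobe), and a binary subtree within every lobe down to
#' \code{max_generation} (generation 0 = trachea). All child branches narrow
#' by the fraction \code{taper}; every branch receives a sinusoidal
#' centreline displacement of one cycle with amplitude \code{amplitude_ratio
#' * length}, so all branches share one analytic tortuosity.
#'
#' @param taper fractional diameter reduction per division (0.25 = each
#'   child is 25\% narrower than its parent).
#' @param amplitude_ratio sinusoid amplitude as a fraction of branch length
#'   (0 = straight tree).
#' @param max_generation deepest global generation to generate (>= 3).
#' @param r_trachea trachea lumen radius in mm (default 8, adult scale).
#' @param mirror left-right mirror the tree (negates x and swaps R/L lobe
#'   labels).
#' @param scale global geometric scale factor.
#' @return List of [phantom_branch()] objects.
#' @export
phantom_airway_tree <- function(taper = 0.25, amplitude_ratio = 0,
                                max_generation = 4, r_trachea = 4.5,
                                mirror = FALSE, scale = 1) {
  stopifnot(max_generation >= 3)
  k <- 1 - taper
  mx <- if (mirror) -1 else 1
  swap <- function(lb) {
    if (!mirror) return(lb)
    map <- c(TRACHEA_MAIN = "TRACHEA_MAIN", RUL = "LUL", RML = "LML",
             RLL = "LLL", LUL = "RUL", LML = "RML", LLL = "RLL")
    unname(map[lb])
  }
  branches <- list()
  nid <- 0L
  add <- function(parent, start, end, r, lobe) {
    nid <<- nid + 1L
    len <- sqrt(sum((end - start)^2))
    branches[[nid]] <<- phantom_branch(nid, parent, start, end, r0 = r,
                                       amplitude_mm = amplitude_ratio * len,
                                       cycles = 1, lobe = swap(lobe))
    nid
  }
  P <- function(x, y, z) scale * c(mx * x, y, z)

  tr <- add(NA, P(0, 0, 55), P(0, 0, 15), r_trachea, "TRACHEA_MAIN")
  r1 <- r_trachea * k
  rm_ <- add(tr, P(0, 0, 15), P(19, 0, 4), r1, "TRACHEA_MAIN")
  lm_ <- add(tr, P(0, 0, 15), P(-19, 0, 4), r1, "TRACHEA_MAIN")
  r2 <- r1 * k

  # binary subtree below a seed branch: alternate split planes, geometric
  # decay, uniform taper
  grow <- function(parent_id, start, dir, len, r, lobe, gen) {
    end <- start + dir * len
    id <- add(parent_id, start, end, r, lobe)
    if (gen >= max_generation) return(invisible(NULL))
    a1 <- c(dir[2], -dir[1], 0)
    if (sqrt(sum(a1^2)) < 1e-6) a1 <- c(1, 0, 0)
    a1 <- .unit(a1)
    a2 <- .unit(c(dir[2] * a1[3] - dir[3] * a1[2],
                  dir[3] * a1[1] - dir[1] * a1[3],
                  dir[1] * a1[2] - dir[2] * a1[1]))
    axis <- if (gen %% 2 == 0) a1 else a2
    th <- 38 * pi / 180
    for (s in c(-1, 1))
      grow(id, end, .unit(.rotate(dir, axis, s * th)), len * 0.72, r * k,
           lobe, gen + 1L)
    invisible(NULL)
  }

  seed_dir <- function(x, y, z) .unit(c(mx * x, y, z))
  # right side: RUL seed + intermediate bronchus -> RML/RLL seeds
  n_rm <- branches[[rm_]]$end
  grow(rm_, n_rm, seed_dir(0.55, 0.15, 0.82), 17 * scale, r2, "RUL", 2L)
  bi <- add(rm_, n_rm, n_rm + scale * c(mx * 4, -1, -13), r2, "TRACHEA_MAIN")
  n_bi <- branches[[bi]]$end
  r3 <- r2 * k
  grow(bi, n_bi, seed_dir(0.50, 0.72, -0.48), 16 * scale, r3, "RML", 3L)
  grow(bi, n_bi, seed_dir(0.38, -0.52, -0.77), 16 * scale, r3, "RLL", 3L)
  # left side: LUL seed + lower trunk -> LML (lingula) / LLL seeds
  n_lm <- branches[[lm_]]$end
  grow(lm_, n_lm, seed_dir(-0.55, 0.15, 0.82), 17 * scale, r2, "LUL", 2L)
  lt <- add(lm_, n_lm, n_lm + scale * c(-mx * 4, -1, -13), r2, "TRACHEA_MAIN")
  n_lt <- branches[[lt]]$end
  grow(lt, n_lt, seed_dir(-0.50, 0.72, -0.48), 16 * scale, r3, "LML", 3L)
  grow(lt, n_lt, seed_dir(-0.38, -0.52, -0.77), 16 * scale, r3, "LLL", 3L)
  branches
}

#' Generate a cohort of phantom cases
#'
#' Draws, per case, a taper fraction from U(0.20, 0.30) and a sinusoid
#' amplitude ratio from U(0, 0.03), builds the six-lobe tree of
#' [phantom_airway_tree()] down to \code{max_generation}, and returns the
#' specs together with the drawn parameters. Deterministic given
#' \code{seed}: the same seed yields bit-identical rasterized volumes.
#'
#' @param n_patients number of cases (>= 1).
#' @param seed integer RNG seed.
#' @param max_generation deepest generation per tree.
#' @param spacing voxel spacing in mm.
#' @return List of cases, each with \code{case_id}, \code{spec},
#'   \code{taper}, \code{amplitude_ratio}.
#' @export
standard_cohort <- function(n_patients, seed = 1L, max_generation = 6,
                            spacing = c(0.75, 0.75, 0.75)) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  taper <- stats::runif(n_patients, 0.20, 0.30)
  amp <- stats::runif(n_patients, 0, 0.03)
  lapply(seq_len(n_patients), function(i) {
    branches <- phantom_airway_tree(taper = taper[i], amplitude_ratio = amp[i],
                                    max_generation = max_generation)
    list(case_id = sprintf("case%02d", i),
         spec = phantom_spec(branches, spacing = spacing,
                             seed = seed + i),
         taper = taper[i], amplitude_ratio = amp[i])
  })
}

#' Write a rasterized phantom case to disk
#'
#' Writes \code{ct.nii.gz}, \code{airway.nii.gz} and \code{truth.csv} into
#' \code{dir}.
#'
#' @param phantom a [rasterize_phantom()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$volume, file.path(dir, "ct.nii.gz"))
  write_volume(phantom$mask, file.path(dir, "airway.nii.gz"))
  utils::write.csv(phantom$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
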