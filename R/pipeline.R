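## End-to-end orchestration: the bronchiq() entry point, its S3 methods,
## and the file outputs (CSV, GraphML, graph rendering).

#' Pipeline tuning parameters
#'
#' Collects every tunable of the pipeline with its default. \code{NULL}
#' means "derive from the image": the closing radius defaults to one voxel,
#' the measurement interval and patch pitch to half the smallest voxel
#' dimension.
#'
#' @param close_radius_mm closing element radius (mm); \code{NULL} = one
#'   voxel, 0 disables closing.
#' @param min_edge_mm minimum internal graph edge length before merging.
#' @param spur_mm skeleton spur-pruning threshold (mm).
#' @param gen_lo,gen_hi generation analysis window (trachea = 0).
#' @param interval_mm centreline measurement interval; \code{NULL} = half
#'   the smallest voxel dimension.
#' @param pitch_mm patch pixel pitch; \code{NULL} = same as the interval.
#' @param max_extent_mm maximum perpendicular patch extent per side.
#' @param n_rays caliper ray count.
#' @param dead_zone_mm,min_prominence_hu,gauss_window_mm,refine_centre,min_valid_frac,centre_max_hu
#'   caliper parameters, see [measure_fwhm_ellipse()].
#' @return A named list of class \code{bronchiq_control}.
#' @export
bronchiq_control <- function(close_radius_mm = NULL, min_edge_mm = 2,
                             spur_mm = 2, gen_lo = 2, gen_hi = 6,
                             interval_mm = NULL, pitch_mm = NULL,
                             max_extent_mm = 40, n_rays = 60,
                             dead_zone_mm = 0.5, min_prominence_hu = 100,
                             gauss_window_mm = 2, refine_centre = TRUE,
                             min_valid_frac = 0.6, centre_max_hu = -800) {
  structure(list(close_radius_mm = close_radius_mm,
                 min_edge_mm = min_edge_mm, spur_mm = spur_mm,
                 gen_lo = gen_lo, gen_hi = gen_hi,
                 interval_mm = interval_mm, pitch_mm = pitch_mm,
                 max_extent_mm = max_extent_mm, n_rays = n_rays,
                 dead_zone_mm = dead_zone_mm,
                 min_prominence_hu = min_prominence_hu,
                 gauss_window_mm = gauss_window_mm,
                 refine_centre = refine_centre,
                 min_valid_frac = min_valid_frac,
                 centre_max_hu = centre_max_hu),
            class = "bronchiq_control")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Quantify an airway tree from CT
#'
#' Runs the full pipeline: mask cleaning (morphological closing, largest
#' connected component), skeletonization and graph extraction, lobe and
#' generation labelling, spline resampling and FWHM ellipse diameter
#' measurement, and per-segment/per-patient biomarker computation
#' (intersegmental tapering, segmental tortuosity, total segment count).
#'
#' @param ct an [image_volume()] or a path to a CT NIfTI file.
#' @param airway a [binary_mask()] or a path to the airway segmentation
#'   NIfTI (voxel-aligned to the CT).
#' @param overrides optional lobe overrides: data frame with
#'   \code{node_id}, \code{lobe} columns or path to such a CSV.
#' @param control a [bronchiq_control()] list.
#' @param patient_id identifier carried into summaries and exports.
#' @return An object of class \code{bronchiq} with components \code{graph}
#'   (the labelled \code{airway_graph}), \code{segments} (per-segment data
#'   frame with geometry, anatomy and measurements), \code{measurements}
#'   (per-sample detail), \code{summary} (a \code{patient_summary}),
#'   \code{control} and \code{log} (per-stage counts).
#' @export
bronchiq <- function(ct, airway, overrides = NULL,
                     control = bronchiq_control(),
                     patient_id = NA_character_) {
  log <- list()
  vol <- .stage("load_ct", {
    if (inherits(ct, "image_volume")) ct else load_volume(ct)
  })
  mask <- .stage("load_mask", {
    if (inherits(airway, "binary_mask")) airway else load_mask(airway, vol)
  })
  if (is.character(overrides)) overrides <- utils::read.csv(overrides)
  log$n_mask_voxels <- sum(mask$data)

  mask <- .stage("mask_prep", {
    r <- control$close_radius_mm
    if (is.null(r)) r <- min(mask$spacing)
    m <- morphological_close(mask, r)
    largest_component(m)
  })
  log$n_clean_mask_voxels <- sum(mask$data)

  graph <- .stage("skeleton_graph", {
    seed <- find_trachea_seed(mask)
    sk <- skeletonize(mask, seed)
    sk <- break_cycles(sk)
    sk <- prune_spurs(sk, min_mm = control$spur_mm)
    sk <- trim_tips(sk)
    # retraction can expose residual fork stubs at rounded tips
    sk <- prune_spurs(sk, min_mm = control$spur_mm)
    skeleton_to_graph(sk, min_edge_mm = control$min_edge_mm)
  })
  log <- c(log, graph$log)

  graph <- .stage("anatomy", {
    g <- assign_generations(graph)
    classify_lobes(g, overrides = overrides)
  })

  interval <- control$interval_mm
  if (is.null(interval)) interval <- sampling_interval(vol$spacing)
  pitch <- control$pitch_mm
  if (is.null(pitch)) pitch <- interval

  ne <- nrow(graph$edges)
  meas <- .stage("caliper", {
    lapply(seq_len(ne), function(e) {
      sp <- fit_spline(graph$paths[[e]], graph$spacing, graph$origin)
      m <- measure_segment(vol, sp, interval = interval, pitch = pitch,
                           max_extent = control$max_extent_mm,
                           n_rays = control$n_rays,
                           dead_zone_mm = control$dead_zone_mm,
                           min_prominence_hu = control$min_prominence_hu,
                           gauss_window_mm = control$gauss_window_mm,
                           refine_centre = control$refine_centre,
                           min_valid_frac = control$min_valid_frac,
                           centre_max_hu = control$centre_max_hu)
      list(spline = sp, measurement = m)
    })
  })

  graph <- .stage("metrics", {
    ed <- graph$edges
    ed$arc_length_mm <- vapply(meas, function(m) m$spline$arc_length_mm, 0)
    ed$euclidean_length_mm <-
      vapply(meas, function(m) m$spline$euclidean_length_mm, 0)
    ed$tortuosity <- tortuosity(ed$arc_length_mm, ed$euclidean_length_mm)
    ed$mean_diameter_mm <-
      vapply(meas, function(m) m$measurement$mean_diameter_mm, 0)
    ed$measure_valid <- vapply(meas, function(m) m$measurement$valid, TRUE)
    ed$n_samples <- vapply(meas, function(m) nrow(m$measurement$samples), 0L)
    ed$n_valid_samples <-
      vapply(meas, function(m) sum(m$measurement$samples$valid), 0L)
    ed$parent_mean_diameter_mm <- ed$mean_diameter_mm[ed$parent]
    ed$tapering_pct <- ifelse(
      !is.na(ed$parent_mean_diameter_mm) & ed$parent_mean_diameter_mm > 0 &
        !is.na(ed$mean_diameter_mm) & ed$mean_diameter_mm > 0,
      100 * (ed$parent_mean_diameter_mm - ed$mean_diameter_mm) /
        ed$parent_mean_diameter_mm,
      NA_real_)
    # a child's tapering needs a valid parent too
    ed$tapering_pct[!is.na(ed$parent) &
                      !ed$measure_valid[pmax(ed$parent, 1)]] <- NA_real_
    graph$edges <- ed
    graph$edges$lobar_generation <- lobar_generation(graph)
    graph
  })
  log$n_valid_segments <- sum(graph$edges$measure_valid)

  summ <- summarize_patient(graph, gen_lo = control$gen_lo,
                            gen_hi = control$gen_hi,
                            patient_id = patient_id)
  structure(list(graph = graph, segments = graph$edges,
                 measurements = lapply(meas, `[[`, "measurement"),
                 splines = lapply(meas, `[[`, "spline"),
                 summary = summ, control = control,
                 patient_id = patient_id, log = log),
            class = "bronchiq")
}

#' @export
print.bronchiq <- function(x, ...) {
  cat("bronchiq airway quantification",
      if (!is.na(x$patient_id)) paste0("[", x$patient_id, "]"), "\n")
  cat(" ", nrow(x$segments), "segments,",
      sum(x$segments$measure_valid), "with valid diameter series\n")
  cat(sprintf("  median tapering %0.2f %%, median tortuosity %0.4f (generations %d-%d)\n",
              x$summary$median_intersegmental_tapering_pct,
              x$summary$median_tortuosity,
              x$control$gen_lo, x$control$gen_hi))
  invisible(x)
}

#' @export
summary.bronchiq <- function(object, ...) {
  print(object$summary)
  ed <- object$segments
  cat("\nper-lobe segment counts:\n")
  print(table(factor(ed$lobe, levels = .lobe_levels)))
  invisible(object$summary)
}

#' @export
plot.bronchiq <- function(x, ...) {
  render_airway_graph(x$graph, ...)
}

.lobe_palette <- c(TRACHEA_MAIN = "grey40", RUL = "#E41A1C",
                   RML = "#FF7F00", RLL = "#A65628", LUL = "#377EB8",
                   LML = "#984EA3", LLL = "#4DAF4A")

.graph_to_igraph <- function(graph) {
  ed <- graph$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$from, to = ed$to, id = ed$id,
               lobe = if (is.null(ed$lobe)) NA else ed$lobe,
               generation = ed$generation,
               length_mm = ed$length_mm,
               mean_diameter_mm = if ("mean_diameter_mm" %in% names(ed))
                 ed$mean_diameter_mm else NA_real_),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$id, x = graph$nodes$x,
                          y = graph$nodes$y, z = graph$nodes$z))
  g
}

#' Render the airway graph
#'
#' Draws the airway tree as a 2D rooted layout in which nodes are airway
#' divisions, edge width is proportional to the segment's mean luminal
#' diameter and edge colour encodes the lobe (distinct colours for RUL,
#' RML, RLL, LUL, LML, LLL; grey for trachea/main bronchi). When no
#' diameters have been measured a uniform width is used with a warning.
#'
#' @param graph an \code{airway_graph} (with lobes, and ideally diameters,
#'   assigned).
#' @param file optional output file; \code{.png} or \code{.svg} decides the
#'   device. \code{NULL} draws on the current device.
#' @param width_scale edge width per mm of diameter.
#' @return The output file (or NULL), invisibly.
#' @export
render_airway_graph <- function(graph, file = NULL, width_scale = 1.2) {
  stopifnot(inherits(graph, "airway_graph"))
  ed <- graph$edges
  dia <- if ("mean_diameter_mm" %in% names(ed)) ed$mean_diameter_mm
    else rep(NA_real_, nrow(ed))
  if (all(is.na(dia))) {
    warning("no diameters assigned; using uniform edge width")
    w <- rep(2, nrow(ed))
  } else {
    w <- width_scale * ifelse(is.na(dia), stats::median(dia, na.rm = TRUE),
                              dia)
  }
  col <- .lobe_palette[ifelse(is.na(ed$lobe), "TRACHEA_MAIN", ed$lobe)]
  g <- .graph_to_igraph(graph)
  lay <- igraph::layout_as_tree(
    g, root = match(graph$root_node, graph$nodes$id))
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 1200, height = 900, res = 130),
           svg = grDevices::svg(file, width = 9, height = 7),
           stop("unsupported image format: ", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  igraph::plot.igraph(g, layout = lay, edge.width = w, edge.color = col,
                      edge.arrow.size = 0, vertex.size = 2.5,
                      vertex.label = NA, vertex.color = "grey20")
  graphics::legend("topright", legend = names(.lobe_palette),
                   col = .lobe_palette, lwd = 3, bty = "n", cex = 0.8)
  invisible(list(file = file, widths = w, colours = col))
}

.data_dictionary <- function() {
  data.frame(
    column = c("id", "parent", "from", "to", "lobe", "lobe_flagged",
               "generation", "lobar_generation", "length_mm",
               "arc_length_mm", "euclidean_length_mm", "tortuosity",
               "mean_diameter_mm", "parent_mean_diameter_mm",
               "tapering_pct", "n_samples", "n_valid_samples",
               "measure_valid"),
    unit = c("-", "-", "-", "-", "-", "-", "-", "-", "mm", "mm", "mm", "-",
             "mm", "mm", "percent", "-", "-", "-"),
    description = c(
      "segment id (breadth-first from the trachea)",
      "parent segment id (NA for the trachea)",
      "proximal node id", "distal node id",
      "lung lobe label (lingula = LML)",
      "TRUE when the lobe came from a fallback rule",
      "airway generation, trachea = 0, +1 per division",
      "generation counted from the lobar bronchus",
      "voxel-path length", "spline arc length L_a",
      "straight-line spline endpoint distance L_e",
      "segmental tortuosity L_a / L_e (>= 1)",
      "mean FWHM ellipse diameter over valid samples",
      "parent segment mean diameter",
      "intersegmental tapering 100*(d_parent - d)/d_parent",
      "number of centreline measurement samples",
      "samples with a valid ellipse fit",
      "TRUE when >= 50% of samples are valid"),
    stringsAsFactors = FALSE)
}

#' Write pipeline outputs to a directory
#'
#' Writes \code{segments.csv}, \code{patient_summary.csv},
#' \code{graph.graphml}, \code{airway_graph.png},
#' \code{data_dictionary.csv}, the resolved configuration
#' (\code{config.json}) and a run log (\code{run_log.txt}). Re-running with
#' an identical configuration reproduces the CSV outputs byte for byte.
#'
#' @param fit a [bronchiq()] result.
#' @param dir output directory (created if needed).
#' @param render also write the graph rendering (default TRUE).
#' @return \code{dir}, invisibly.
#' @export
write_bronchiq_outputs <- function(fit, dir, render = TRUE) {
  stopifnot(inherits(fit, "bronchiq"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seg <- fit$segments
  num <- vapply(seg, is.numeric, TRUE) & !vapply(seg, is.integer, TRUE)
  seg[num] <- lapply(seg[num], function(v) round(v, 6))
  utils::write.csv(seg, file.path(dir, "segments.csv"), row.names = FALSE)
  s <- fit$summary
  utils::write.csv(data.frame(
    patient_id = s$patient_id,
    median_intersegmental_tapering_pct =
      round(s$median_intersegmental_tapering_pct, 6),
    median_tortuosity = round(s$median_tortuosity, 6),
    total_segment_count = s$total_segment_count,
    n_window_segments = s$n_window_segments,
    n_valid_window_segments = s$n_valid_window_segments,
    gen_lo = s$generation_window[1], gen_hi = s$generation_window[2],
    valid = s$valid,
    tapering_sign_convention = s$tapering_sign_convention),
    file.path(dir, "patient_summary.csv"), row.names = FALSE)
  utils::write.csv(.data_dictionary(),
                   file.path(dir, "data_dictionary.csv"), row.names = FALSE)
  igraph::write_graph(.graph_to_igraph(fit$graph),
                      file.path(dir, "graph.graphml"), format = "graphml")
  ctl <- unclass(fit$control)
  ctl$patient_id <- fit$patient_id
  jsonlite::write_json(ctl, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(c(paste0("bronchiq run: ", fit$patient_id),
               paste0(names(fit$log), ": ", unlist(fit$log))),
             file.path(dir, "run_log.txt"))
  if (render)
    try(render_airway_graph(fit$graph,
                            file.path(dir, "airway_graph.png")),
        silent = TRUE)
  invisible(dir)
}

#' Run the pipeline from a configuration
#'
#' Thin orchestration over [bronchiq()] and [write_bronchiq_outputs()]: a
#' configuration names the inputs, the output directory and any control
#' overrides, and a saved configuration reproduces the run exactly.
#'
#' @param config named list (or path to a JSON file) with elements
#'   \code{ct}, \code{airway}, \code{out_dir}, optional \code{overrides}
#'   (CSV path), \code{patient_id}, and any [bronchiq_control()] fields.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  for (f in c("ct", "airway", "out_dir"))
    if (is.null(config[[f]])) stop("config is missing '", f, "'")
  for (f in c("ct", "airway"))
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  ctl_fields <- names(formals(bronchiq_control))
  ctl <- do.call(bronchiq_control, config[intersect(names(config),
                                                    ctl_fields)])
  fit <- bronchiq(config$ct, config$airway,
                  overrides = config$overrides, control = ctl,
                  patient_id = if (is.null(config$patient_id))
                    NA_character_ else config$patient_id)
  write_bronchiq_outputs(fit, config$out_dir)
  cfg <- config
  cfg$resolved_control <- unclass(fit$control)
  jsonlite::write_json(cfg, file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(config$out_dir)
}
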