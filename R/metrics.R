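## Per-segment biomarkers and per-patient summaries.

#' Intersegmental tapering
#'
#' Relative narrowing from a parent segment to its child, as a percentage of
#' the parent's mean diameter: \code{100 * (d_p - d) / d_p}. Positive values
#' indicate the normal distal narrowing of healthy airways; reduced (lower)
#' tapering is the traction-bronchiectasis signature. The sign convention is
#' recorded in exported metadata.
#'
#' @param d_p parent segment mean diameter in mm (> 0).
#' @param d child segment mean diameter in mm (> 0).
#' @return Tapering in percent.
#' @export
intersegmental_tapering <- function(d_p, d) {
  if (any(!is.na(d_p) & d_p <= 0) || any(!is.na(d) & d <= 0))
    stop("diameters must be positive")
  100 * (d_p - d) / d_p
}

#' Segmental tortuosity
#'
#' Ratio of a segment's centreline arc length to the Euclidean distance
#' between its endpoints; 1 for a straight segment, larger for curved ones.
#' Values marginally below 1 (numerical noise) are clipped to 1.
#'
#' @param L_a arc length in mm.
#' @param L_e Euclidean (straight-line) length in mm (> 0).
#' @return Dimensionless tortuosity >= 1.
#' @export
tortuosity <- function(L_a, L_e) {
  if (any(!is.na(L_e) & L_e <= 0)) stop("Euclidean length must be positive")
  pmax(L_a / L_e, 1)
}

#' Per-patient summary of airway metrics
#'
#' Computes the patient-level biomarkers: median intersegmental tapering and
#' median segmental tortuosity over the valid segments within the
#' generation window (default generations 2-6), and the total number of
#' airway segments identified in the whole tree. Per-lobe and per-generation
#' medians are returned as breakdowns. Medians use the usual
#' midpoint-average convention for even counts.
#'
#' @param graph an \code{airway_graph} whose edges carry
#'   \code{mean_diameter_mm}, \code{tapering_pct}, \code{tortuosity},
#'   \code{measure_valid} columns (as produced by the pipeline).
#' @param gen_lo,gen_hi inclusive generation window.
#' @param patient_id optional identifier stored in the summary.
#' @return An object of class \code{patient_summary}.
#' @export
summarize_patient <- function(graph, gen_lo = 2, gen_hi = 6,
                              patient_id = NA_character_) {
  stopifnot(inherits(graph, "airway_graph"))
  ed <- graph$edges
  need <- c("tapering_pct", "tortuosity", "measure_valid")
  if (!all(need %in% names(ed)))
    stop("graph edges lack metric columns; run the measurement stage first")
  win <- ed[!is.na(ed$generation) & ed$generation >= gen_lo &
              ed$generation <= gen_hi, , drop = FALSE]
  ok <- win$measure_valid
  tap <- win$tapering_pct[ok & !is.na(win$tapering_pct)]
  tor <- win$tortuosity[ok & !is.na(win$tortuosity)]

  by_lobe <- lapply(split(win[ok, , drop = FALSE], win$lobe[ok]), function(d)
    c(median_tapering_pct = stats::median(d$tapering_pct, na.rm = TRUE),
      median_tortuosity = stats::median(d$tortuosity, na.rm = TRUE),
      n_segments = nrow(d)))
  by_gen <- lapply(split(win[ok, , drop = FALSE], win$generation[ok]),
                   function(d)
    c(median_tapering_pct = stats::median(d$tapering_pct, na.rm = TRUE),
      median_tortuosity = stats::median(d$tortuosity, na.rm = TRUE),
      n_segments = nrow(d)))

  structure(list(
    patient_id = patient_id,
    median_intersegmental_tapering_pct = if (length(tap)) stats::median(tap)
      else NA_real_,
    median_tortuosity = if (length(tor)) stats::median(tor) else NA_real_,
    total_segment_count = nrow(ed),
    n_window_segments = nrow(win),
    n_valid_window_segments = sum(ok),
    generation_window = c(gen_lo, gen_hi),
    by_lobe = by_lobe,
    by_generation = by_gen,
    valid = sum(ok) > 0,
    tapering_sign_convention = "100*(d_parent - d_child)/d_parent"),
    class = "patient_summary")
}

#' @export
print.patient_summary <- function(x, ...) {
  cat("patient_summary",
      if (!is.na(x$patient_id)) paste0("[", x$patient_id, "]"), "\n")
  cat(sprintf("  median intersegmental tapering: %.2f %%\n",
              x$median_intersegmental_tapering_pct))
  cat(sprintf("  median segmental tortuosity:    %.4f\n",
              x$median_tortuosity))
  cat(sprintf("  total segment count:            %d\n",
              x$total_segment_count))
  cat(sprintf("  window: generations %d-%d (%d segments, %d valid)%s\n",
              x$generation_window[1], x$generation_window[2],
              x$n_window_segments, x$n_valid_window_segments,
              if (x$valid) "" else "  [INVALID]"))
  invisible(x)
}

#' Export a survival-ready per-patient table
#'
#' Flattens a list of patient summaries into one row per patient (id, median
#' tapering, median tortuosity, total segment count) and optionally joins
#' clinical covariates on \code{patient_id}. The resulting table is the
#' input expected by downstream survival analyses (e.g. Cox
#' proportional-hazards models), which are outside this package's scope.
#'
#' @param summaries list of [summarize_patient()] results.
#' @param clinical optional data frame with a \code{patient_id} column.
#' @param standardize_tortuosity z-standardise tortuosity across the cohort
#'   (mean 0, SD 1), as some cohort reports present it.
#' @return A data frame, one row per patient.
#' @export
export_survival_table <- function(summaries, clinical = NULL,
                                  standardize_tortuosity = FALSE) {
  ids <- vapply(summaries, function(s) as.character(s$patient_id), "")
  if (anyDuplicated(ids))
    stop("duplicate patient ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- data.frame(
    patient_id = ids,
    median_intersegmental_tapering_pct =
      vapply(summaries, function(s) s$median_intersegmental_tapering_pct, 0),
    median_tortuosity = vapply(summaries,
                               function(s) s$median_tortuosity, 0),
    total_segment_count = vapply(summaries,
                                 function(s) s$total_segment_count, 0L),
    stringsAsFactors = FALSE)
  if (standardize_tortuosity) {
    v <- out$median_tortuosity
    out$median_tortuosity <- if (length(v) > 1 && stats::sd(v) > 0)
      (v - mean(v)) / stats::sd(v) else v - mean(v)
  }
  if (!is.null(clinical)) {
    if (!"patient_id" %in% names(clinical))
      stop("clinical table must have a 'patient_id' column")
    clinical$patient_id <- as.character(clinical$patient_id)
    out <- merge(out, clinical, by = "patient_id", all.x = TRUE, sort = FALSE)
  }
  out
}
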