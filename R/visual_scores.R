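## Cap-and-sum aggregation of visually scored traction bronchiectasis.
##
## Raw per-lobe scores come from a radiologist's reading; this module only
## aggregates them. Six lobes are used, with the lingula treated as the
## left middle lobe (LML).

.six_lobes <- c("RUL", "RML", "RLL", "LUL", "LML", "LLL")

.check_lobe_scores <- function(scores) {
  if (!is.null(names(scores))) {
    missing <- setdiff(.six_lobes, names(scores))
    if (length(missing))
      stop("missing lobe scores: ", paste(missing, collapse = ", "))
    scores <- scores[.six_lobes]
  } else if (length(scores) == 6L) {
    names(scores) <- .six_lobes
  } else {
    stop("expected 6 per-lobe scores (RUL, RML, RLL, LUL, LML, LLL)")
  }
  if (any(scores < 0)) stop("lobe scores must be non-negative")
  scores
}

#' Aggregate traction bronchiectasis extent
#'
#' Extent is the number of airway segments with traction bronchiectasis in
#' each lobe. Each lobe's raw value is capped (3 in the upper and lower
#' lobes, 2 in the middle lobes RML and LML) to avoid excess weighting of a
#' single lobe, then the six capped values are summed, giving a whole-lung
#' score with maximum 16.
#'
#' @param scores numeric length 6, raw per-lobe extent; either named with
#'   RUL, RML, RLL, LUL, LML, LLL or in that order.
#' @return Integer extent score in \code{[0, 16]}.
#' @export
aggregate_tb_extent <- function(scores) {
  s <- .check_lobe_scores(scores)
  caps <- c(RUL = 3, RML = 2, RLL = 3, LUL = 3, LML = 2, LLL = 3)
  sum(pmin(s, caps[names(s)]))
}

#' Aggregate traction bronchiectasis severity
#'
#' Severity is a subjective mild/moderate/severe grading per lobe, capped at
#' 3 in every lobe and summed over the six lobes, giving a whole-lung score
#' with maximum 18.
#'
#' @inheritParams aggregate_tb_extent
#' @return Integer severity score in \code{[0, 18]}.
#' @export
aggregate_tb_severity <- function(scores) {
  s <- .check_lobe_scores(scores)
  sum(pmin(s, 3))
}

#' Aggregate a long-format visual score table
#'
#' @param df data frame with columns \code{patient_id}, \code{lobe},
#'   \code{kind} ("extent" or "severity") and \code{value}.
#' @return Data frame with one row per patient and columns
#'   \code{tb_extent}, \code{tb_severity} (NA when a kind is absent).
#' @export
aggregate_tb_table <- function(df) {
  stopifnot(all(c("patient_id", "lobe", "kind", "value") %in% names(df)))
  res <- lapply(split(df, df$patient_id), function(d) {
    one <- function(kind, fun) {
      dd <- d[d$kind == kind, ]
      if (!nrow(dd)) return(NA_real_)
      fun(stats::setNames(dd$value, dd$lobe))
    }
    data.frame(patient_id = d$patient_id[1],
               tb_extent = one("extent", aggregate_tb_extent),
               tb_severity = one("severity", aggregate_tb_severity))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
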