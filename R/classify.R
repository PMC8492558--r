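# eDISH quadrant classification, grouped counts, and the triage table.

QUADRANT_LEVELS <- c("possible_hys_law", "temples_corollary",
                     "hyperbilirubinemia", "within_range")

#' Classify subjects into eDISH quadrants
#'
#' Partitions the peak-value plane by the configured thresholds, inclusive on
#' the flagged side: with x the peak ALT fold-ULN (or the peak nR ratio when
#' `cfg$x_axis_mode = "nr"`) and y the peak TB fold-ULN,
#' `x >= x-threshold & y >= tb threshold` is possible Hy's Law,
#' `x >= x-threshold` alone is Temple's Corollary, `y >= tb threshold` alone
#' is hyperbilirubinemia, and everything else is within range. Quadrant
#' membership always uses fold-ULN peaks (possibly from different days — the
#' classic eDISH convention); temporal concordance is carried separately by
#' `within_window`.
#'
#' @param summary A [subject_summary()] tibble (evaluable rows).
#' @param cfg An [edish_config()].
#' @return Character vector of quadrant labels, one per row of `summary`.
#' @examples
#' # peaks at 3.5x ULN ALT and 2.5x ULN TB fall in the Hy's Law quadrant
#' @export
classify_quadrant <- function(summary, cfg = edish_config()) {
  if (any(!summary$evaluable)) {
    abort(paste0("not classifiable: subject(s) without post-baseline ALT ",
                 "and TB: ",
                 paste(summary$subject_id[!summary$evaluable], collapse = ", ")),
          class = "edishr_domain_error")
  }
  if (cfg$x_axis_mode == "nr") {
    x <- summary$nr_peak
    x_threshold <- cfg$nr_threshold
  } else {
    x <- summary$alt_peak_fold
    x_threshold <- cfg$alt_fold_threshold
  }
  y <- summary$tb_peak_fold
  dplyr::case_when(
    x >= x_threshold & y >= cfg$tb_fold_threshold ~ "possible_hys_law",
    x >= x_threshold ~ "temples_corollary",
    y >= cfg$tb_fold_threshold ~ "hyperbilirubinemia",
    .default = "within_range"
  )
}

#' Fill the quadrant column of a subject summary
#'
#' Applies [classify_quadrant()] to the evaluable rows and leaves
#' non-evaluable rows `NA`.
#'
#' @inheritParams classify_quadrant
#' @param summaries A [subject_summary()] tibble.
#' @return `summaries` with `quadrant` filled.
#' @export
classify_subjects <- function(summaries, cfg = edish_config()) {
  ev <- summaries$evaluable
  summaries$quadrant <- NA_character_
  if (any(ev)) {
    summaries$quadrant[ev] <- classify_quadrant(summaries[ev, ], cfg)
  }
  summaries
}

#' Quadrant counts, optionally grouped
#'
#' Counts evaluable subjects per quadrant; with `group_by`, a quadrant-by-
#' group table. Every quadrant (and every group level) is reported, zeros
#' included, and counts always sum to the number of evaluable subjects.
#'
#' @param summaries A classified [subject_summary()] tibble.
#' @param cfg An [edish_config()].
#' @param group_by Optional name of a subject-attribute column.
#' @param subject_attributes Optional tibble of per-subject attributes
#'   (`subject_id` plus categorical columns); required when `group_by` is
#'   given.
#' @return Tibble `quadrant`, (`group`,) `n`.
#' @export
quadrant_counts <- function(summaries, cfg = edish_config(), group_by = NULL,
                            subject_attributes = NULL) {
  ev <- summaries[summaries$evaluable, ]
  if (!all(ev$quadrant %in% QUADRANT_LEVELS)) {
    ev <- classify_subjects(ev, cfg)
  }
  quadrant <- factor(ev$quadrant, levels = QUADRANT_LEVELS)
  if (is.null(group_by)) {
    n_by_level <- as.integer(table(quadrant))
    return(tibble::tibble(quadrant = QUADRANT_LEVELS, n = n_by_level))
  }
  if (is.null(subject_attributes) ||
      !group_by %in% names(subject_attributes)) {
    abort(paste0("configuration error: unknown grouping column '",
                 group_by, "'"),
          class = "edishr_config_error")
  }
  grp <- subject_attributes[[group_by]][
    match(ev$subject_id, subject_attributes$subject_id)]
  grp <- factor(as.character(grp))
  tab <- table(quadrant = quadrant, group = grp)
  out <- tibble::as_tibble(tab, n = "n")
  out$n <- as.integer(out$n)
  names(out)[names(out) == "group"] <- group_by
  dplyr::arrange(out, match(.data$quadrant, QUADRANT_LEVELS))
}

#' Triage table for safety review
#'
#' One row per evaluable subject, ordered for rapid review: possible Hy's Law
#' cases first, then Temple's Corollary, hyperbilirubinemia and within-range;
#' within a quadrant by peak ALT fold descending, ties by subject id.
#'
#' @param summaries A classified [subject_summary()] tibble.
#' @param cfg An [edish_config()].
#' @return Tibble with quadrant, peak folds and days, peak-time separation,
#'   window flag, injury pattern and P_ALT.
#' @export
triage_table <- function(summaries, cfg = edish_config()) {
  ev <- summaries[summaries$evaluable, ]
  if (nrow(ev) > 0L && !all(ev$quadrant %in% QUADRANT_LEVELS)) {
    ev <- classify_subjects(ev, cfg)
  }
  ev |>
    dplyr::mutate(.severity = match(.data$quadrant, QUADRANT_LEVELS)) |>
    dplyr::arrange(.data$.severity, dplyr::desc(.data$alt_peak_fold),
                   .data$subject_id) |>
    dplyr::select("subject_id", "quadrant",
                  "alt_peak_fold", "alt_peak_day",
                  "tb_peak_fold", "tb_peak_day",
                  "alp_peak_fold", "peak_time_separation_days",
                  "within_window", "injury_pattern", "p_alt_percent")
}
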