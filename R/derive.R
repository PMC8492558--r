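# Derivation of per-visit and per-subject hepatotoxicity statistics:
# fold-ULN, fold-baseline, R / nR ratios, treatment-emergent peaks,
# peak-time separation, P_ALT, injury pattern, hysteresis paths.

# Dimensionless derived quantities are quantized at 7 significant digits —
# well beyond the ~3 significant digits a clinical assay carries — so that
# derived tables are exactly invariant under unit rescaling (value and ULN
# multiplied by the same constant) and stable across numerics libraries.
FOLD_DIGITS <- 7L

quantize_fold <- function(x) signif(x, FOLD_DIGITS)

#' Fold of the upper limit of normal
#'
#' The core eDISH normalization: a lab result expressed as a multiple of its
#' upper limit of normal, `value / uln`. Dimensionless, so unaffected by the
#' units the study reports, provided value and ULN share them.
#'
#' @param value Numeric result(s), `>= 0`.
#' @param uln Upper limit(s) of normal, `> 0`, same units as `value`.
#' @return `value / uln`, quantized at 7 significant digits.
#' @examples
#' fold_uln(120, 40) # 3
#' @export
fold_uln <- function(value, uln) {
  if (any(!is.na(uln) & uln <= 0)) {
    abort("fold_uln: uln must be > 0", class = "edishr_domain_error")
  }
  if (any(!is.na(value) & value < 0)) {
    abort("fold_uln: value must be >= 0", class = "edishr_domain_error")
  }
  quantize_fold(value / uln)
}

#' Fold of the subject's baseline value
#'
#' `value / baseline` when a positive baseline exists; `NA` (absent) when the
#' baseline is missing or zero — a missing reference is not an error, the
#' statistic is simply undefined.
#'
#' @param value Numeric result(s).
#' @param baseline Baseline value(s), same units.
#' @return `value / baseline`, quantized at 7 significant digits, or `NA`.
#' @export
fold_baseline <- function(value, baseline) {
  out <- ifelse(!is.na(baseline) & baseline > 0, value / baseline, NA_real_)
  quantize_fold(out)
}

# Baseline per (subject, analyte): an explicitly flagged baseline record wins
# (latest if several are flagged); otherwise the latest record at day <= 1
# (CDISC convention: day 1 is first dose, there is no day 0).
baseline_table <- function(records) {
  flagged <- records[records$baseline_flag, ]
  flagged <- flagged |>
    dplyr::slice_max(.data$study_day, n = 1L, with_ties = FALSE,
                     by = c("subject_id", "analyte"))
  by_day <- records[records$study_day <= 1L, ] |>
    dplyr::slice_max(.data$study_day, n = 1L, with_ties = FALSE,
                     by = c("subject_id", "analyte"))
  by_day <- dplyr::anti_join(by_day, flagged,
                             by = c("subject_id", "analyte"))
  dplyr::bind_rows(flagged, by_day) |>
    dplyr::select("subject_id", "analyte", baseline = "value") |>
    dplyr::arrange(.data$subject_id, .data$analyte)
}

#' Per-visit derived values
#'
#' For every (subject, study day) present in the study, the fold-ULN and
#' fold-baseline of each hepatic analyte plus the same-day liver-injury-
#' pattern ratios: `r_ratio = ALT fold / ALP fold` and
#' `nr_ratio = max(ALT, AST) fold / ALP fold`. Ratios are absent (`NA`) at
#' visits lacking a positive same-day ALP fold or the required numerator
#' analyte.
#'
#' @param study An `edish_study`.
#' @param cfg An [edish_config()] (reserved for future per-visit options).
#' @return Tibble with one row per (subject, day): columns
#'   `alt_fold_uln` .. `tb_fold_uln`, `alt_fold_bl` .. `tb_fold_bl`,
#'   `r_ratio`, `nr_ratio`.
#' @export
compute_visit_derived <- function(study, cfg = edish_config()) {
  stopifnot(inherits(study, "edish_study"))
  rec <- study$records
  bl <- baseline_table(rec)
  rec <- dplyr::left_join(rec, bl, by = c("subject_id", "analyte"))
  rec$fold_uln <- fold_uln(rec$value, rec$uln)
  rec$fold_bl <- fold_baseline(rec$value, rec$baseline)

  wide <- rec |>
    dplyr::mutate(analyte = tolower(.data$analyte)) |>
    dplyr::select("subject_id", "study_day", "analyte", "fold_uln",
                  "fold_bl") |>
    tidyr::pivot_wider(names_from = "analyte",
                       values_from = c("fold_uln", "fold_bl"),
                       names_glue = "{analyte}_{.value}")
  for (col in paste0(rep(tolower(CANONICAL_ANALYTES), each = 2),
                     c("_fold_uln", "_fold_bl"))) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- wide |>
    dplyr::select("subject_id", "study_day",
                  "alt_fold_uln", "ast_fold_uln", "alp_fold_uln",
                  "tb_fold_uln", "alt_fold_bl", "ast_fold_bl",
                  "alp_fold_bl", "tb_fold_bl") |>
    dplyr::arrange(.data$subject_id, .data$study_day)

  alp_ok <- !is.na(wide$alp_fold_uln) & wide$alp_fold_uln > 0
  num_nr <- pmax(wide$alt_fold_uln, wide$ast_fold_uln, na.rm = TRUE)
  num_nr[is.na(wide$alt_fold_uln) & is.na(wide$ast_fold_uln)] <- NA_real_
  wide$r_ratio <- quantize_fold(
    ifelse(alp_ok & !is.na(wide$alt_fold_uln),
           wide$alt_fold_uln / wide$alp_fold_uln, NA_real_))
  wide$nr_ratio <- quantize_fold(
    ifelse(alp_ok & !is.na(num_nr), num_nr / wide$alp_fold_uln, NA_real_))
  wide
}

#' Hepatocyte-loss estimate from an ALT elevation (P_ALT)
#'
#' Released-enzyme mass balance: the treatment-emergent ALT excess
#' (peak minus baseline, U/L) times the distribution volume of circulating
#' ALT is the quantity of enzyme released, expressed as a percentage of the
#' total hepatocyte ALT pool and clipped to 100. Zero when the peak does not
#' exceed baseline. The constants are calibration-dependent configuration,
#' see [p_alt_constants()].
#'
#' @param peak_alt,baseline_alt ALT in U/L, `>= 0`.
#' @param constants A [p_alt_constants()].
#' @return Percentage in `[0, 100]`; nondecreasing in `peak_alt`.
#' @examples
#' p_alt(500, 20) # with the default constants: 4.8
#' @export
p_alt <- function(peak_alt, baseline_alt, constants = p_alt_constants()) {
  if (any(!is.na(peak_alt) & peak_alt < 0) ||
      any(!is.na(baseline_alt) & baseline_alt < 0)) {
    abort("p_alt: ALT values must be >= 0", class = "edishr_domain_error")
  }
  released <- pmax(peak_alt - baseline_alt, 0) * constants$distribution_volume_l
  pmin(100 * released / constants$total_hepatocyte_alt_u, 100)
}

#' Liver-injury pattern from an R or nR ratio
#'
#' CIOMS-convention step function of the ratio of transaminase to alkaline-
#' phosphatase elevation: ratio `>= hepatocellular_cut` (default 5) is
#' hepatocellular, ratio `<= cholestatic_cut` (default 2) is cholestatic,
#' strictly in between is mixed, and an absent ratio is indeterminate.
#'
#' @param ratio Numeric R or nR ratio(s); `NA` allowed.
#' @param hepatocellular_cut,cholestatic_cut Breakpoints (defaults 5 and 2).
#' @return Character vector over
#'   `c("hepatocellular", "cholestatic", "mixed", "indeterminate")`.
#' @export
injury_pattern <- function(ratio, hepatocellular_cut = 5,
                           cholestatic_cut = 2) {
  dplyr::case_when(
    is.na(ratio) ~ "indeterminate",
    ratio >= hepatocellular_cut ~ "hepatocellular",
    ratio <= cholestatic_cut ~ "cholestatic",
    .default = "mixed"
  )
}

# Post-baseline peak per (subject, analyte): maximum fold-ULN over days > 1,
# ties broken to the earliest day so peak-time separation is deterministic.
peak_table <- function(records) {
  post <- records[records$study_day > 1L, ]
  post$fold <- fold_uln(post$value, post$uln)
  post |>
    dplyr::arrange(.data$subject_id, .data$analyte,
                   dplyr::desc(.data$fold), .data$study_day) |>
    dplyr::slice_head(n = 1L, by = c("subject_id", "analyte")) |>
    dplyr::select("subject_id", "analyte", peak_value = "value",
                  peak_fold = "fold", peak_day = "study_day")
}

#' Per-subject hepatotoxicity summary
#'
#' Collapses a study to one row per subject: per-analyte baselines and
#' treatment-emergent peaks (maximum post-baseline fold-ULN, ties to the
#' earliest day), peak fold-baseline for ALT and TB, the time separation
#' between the ALT and TB peaks and whether it falls inside the configured
#' concordance window, the P_ALT hepatocyte-loss estimate, subject-level R
#' and nR ratios, and the injury-pattern call. Subjects without post-baseline
#' ALT and TB are retained with `evaluable = FALSE`, never silently dropped.
#'
#' The subject-level ratio depends on `cfg$ratio_basis`: `"visit"` takes the
#' same-day ratio at the visit of the peak transaminase fold (standard
#' clinical practice); `"peak"` forms the ratio from peak folds that may come
#' from different days.
#'
#' @param study An `edish_study`.
#' @param cfg An [edish_config()].
#' @return Tibble, one row per subject, with a `quadrant` column of `NA`
#'   ready to be filled by [classify_subjects()].
#' @export
subject_summary <- function(study, cfg = edish_config()) {
  stopifnot(inherits(study, "edish_study"))
  rec <- study$records
  subjects <- sort(unique(rec$subject_id))

  bl <- baseline_table(rec) |>
    dplyr::mutate(analyte = tolower(.data$analyte)) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "baseline",
                       names_glue = "{analyte}_baseline")
  pk <- peak_table(rec) |>
    dplyr::mutate(analyte = tolower(.data$analyte)) |>
    tidyr::pivot_wider(names_from = "analyte",
                       values_from = c("peak_value", "peak_fold", "peak_day"),
                       names_glue = "{analyte}_{.value}")

  out <- tibble::tibble(subject_id = subjects) |>
    dplyr::left_join(bl, by = "subject_id") |>
    dplyr::left_join(pk, by = "subject_id")
  for (an in tolower(CANONICAL_ANALYTES)) {
    for (suffix in c("_baseline", "_peak_value", "_peak_fold", "_peak_day")) {
      col <- paste0(an, suffix)
      if (!col %in% names(out)) out[[col]] <- NA_real_
    }
  }

  # Peak fold-baseline over post-baseline visits (absent without a positive
  # baseline); used for the fold_baseline axis mode.
  post <- rec[rec$study_day > 1L, ]
  post <- dplyr::left_join(post, baseline_table(rec),
                           by = c("subject_id", "analyte"))
  post$fold_bl <- fold_baseline(post$value, post$baseline)
  max_or_na <- function(x) if (length(x) == 0L) NA_real_ else max(x)
  fb <- post |>
    dplyr::filter(!is.na(.data$fold_bl),
                  .data$analyte %in% c("ALT", "TB")) |>
    dplyr::summarise(peak_fold_bl = max_or_na(.data$fold_bl),
                     .by = c("subject_id", "analyte")) |>
    dplyr::mutate(analyte = tolower(.data$analyte)) |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "peak_fold_bl",
                       names_glue = "{analyte}_peak_fold_bl")
  out <- dplyr::left_join(out, fb, by = "subject_id")
  for (col in c("alt_peak_fold_bl", "tb_peak_fold_bl")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }

  out$evaluable <- !is.na(out$alt_peak_fold) & !is.na(out$tb_peak_fold)
  out$peak_time_separation_days <-
    abs(out$alt_peak_day - out$tb_peak_day)
  out$within_window <-
    out$peak_time_separation_days <= cfg$peak_window_days
  out$p_alt_percent <- ifelse(
    !is.na(out$alt_peak_value) & !is.na(out$alt_baseline),
    p_alt(pmax(out$alt_peak_value, out$alt_baseline), out$alt_baseline,
          cfg$p_alt),
    NA_real_)

  out <- add_subject_ratios(out, study, cfg)
  ratio <- if (cfg$pattern_basis == "r") out$r_value else out$nr_value
  out$injury_pattern <- injury_pattern(ratio, cfg$hepatocellular_cut,
                                       cfg$cholestatic_cut)
  out$quadrant <- NA_character_
  out
}

# Subject-level R/nR ratios. Visit basis: same-day ratio at the visit of the
# peak numerator fold (ALT for R; max(ALT, AST) for nR), plus the maximum
# same-day ratio over post-baseline visits (r_peak / nr_peak, used as the
# "peak nR" x value). Peak basis: ratio of peak folds from possibly
# different days.
add_subject_ratios <- function(out, study, cfg) {
  vis <- compute_visit_derived(study, cfg)
  post <- vis[vis$study_day > 1L, ]

  if (cfg$ratio_basis == "peak") {
    alp_pk <- out$alp_peak_fold
    r_value <- quantize_fold(ifelse(!is.na(alp_pk) & alp_pk > 0,
                                    out$alt_peak_fold / alp_pk, NA_real_))
    num <- pmax(out$alt_peak_fold, out$ast_peak_fold, na.rm = TRUE)
    num[is.na(out$alt_peak_fold) & is.na(out$ast_peak_fold)] <- NA_real_
    nr_value <- quantize_fold(ifelse(!is.na(alp_pk) & alp_pk > 0,
                                     num / alp_pk, NA_real_))
  } else {
    at_alt_peak <- dplyr::inner_join(
      out[, c("subject_id", "alt_peak_day")], post,
      by = c(subject_id = "subject_id", alt_peak_day = "study_day"))
    r_value <- at_alt_peak$r_ratio[match(out$subject_id,
                                         at_alt_peak$subject_id)]
    tx <- post |>
      dplyr::mutate(tx_fold = pmax(.data$alt_fold_uln, .data$ast_fold_uln,
                                   na.rm = TRUE)) |>
      dplyr::filter(!is.na(.data$tx_fold)) |>
      dplyr::arrange(.data$subject_id, dplyr::desc(.data$tx_fold),
                     .data$study_day) |>
      dplyr::slice_head(n = 1L, by = "subject_id")
    nr_value <- tx$nr_ratio[match(out$subject_id, tx$subject_id)]
  }

  ratio_max <- post |>
    dplyr::summarise(
      r_peak = if (all(is.na(.data$r_ratio))) NA_real_
               else max(.data$r_ratio, na.rm = TRUE),
      nr_peak = if (all(is.na(.data$nr_ratio))) NA_real_
                else max(.data$nr_ratio, na.rm = TRUE),
      .by = "subject_id")
  out$r_value <- r_value
  out$nr_value <- nr_value
  out$r_peak <- ratio_max$r_peak[match(out$subject_id, ratio_max$subject_id)]
  out$nr_peak <- ratio_max$nr_peak[match(out$subject_id,
                                         ratio_max$subject_id)]
  if (cfg$ratio_basis == "peak") {
    out$r_peak <- out$r_value
    out$nr_peak <- out$nr_value
  }
  out
}

#' ALT-vs-bilirubin hysteresis path for one subject
#'
#' The ordered trajectory of (study day, ALT fold-ULN, TB fold-ULN) a
#' hysteresis animation steps through. Days where only one of the two
#' analytes was measured carry the other forward from its last observation
#' (LOCF); the path starts at the first day on which both analytes have been
#' observed at least once.
#'
#' @param study An `edish_study`.
#' @param subject_id Subject to extract.
#' @return Tibble `study_day`, `alt_fold_uln`, `tb_fold_uln`, strictly
#'   increasing in `study_day`.
#' @export
hysteresis_path <- function(study, subject_id) {
  rec <- study$records[study$records$subject_id == subject_id, ]
  if (nrow(rec) == 0L) {
    abort(paste0("unknown subject: ", subject_id),
          class = "edishr_lookup_error")
  }
  series <- function(an) {
    s <- rec[rec$analyte == an, ]
    s <- s[order(s$study_day), ]
    tibble::tibble(study_day = s$study_day,
                   fold = fold_uln(s$value, s$uln))
  }
  alt <- series("ALT")
  tb <- series("TB")
  days <- sort(unique(c(alt$study_day, tb$study_day)))
  locf <- function(s) {
    idx <- findInterval(days, s$study_day)
    ifelse(idx == 0L, NA_real_, s$fold[pmax(idx, 1L)])
  }
  path <- tibble::tibble(study_day = days,
                         alt_fold_uln = locf(alt),
                         tb_fold_uln = locf(tb))
  path[!is.na(path$alt_fold_uln) & !is.na(path$tb_fold_uln), ]
}

#' Write derived tables as delimited text
#'
#' Exports the per-visit derived table and the per-subject summary with
#' stable, documented column names.
#'
#' @param visits Result of [compute_visit_derived()].
#' @param summaries Result of [subject_summary()] / [classify_subjects()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_derived_tables <- function(visits, summaries, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(visits = file.path(dir, "visit_derived.csv"),
             subjects = file.path(dir, "subject_summary.csv"))
  data.table::fwrite(visits, paths[["visits"]])
  data.table::fwrite(summaries, paths[["subjects"]])
  invisible(paths)
}
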