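# Interactive report: eDISH figure spec, per-subject profiles, hysteresis
# frames, and export of one fully self-contained HTML document. The document
# embeds its own small SVG/JavaScript runtime, so it renders with networking
# disabled and contains no external references at all.

# Single source of truth for every number the report displays: tooltip and
# panel strings are produced by this formatter applied to the derived-table
# columns, nothing is recomputed downstream.
fmt_val <- function(x) {
  ifelse(is.na(x), "n/a", vapply(x, function(v) {
    if (is.numeric(v)) format(signif(v, 4), trim = TRUE, scientific = FALSE)
    else as.character(v)
  }, character(1)))
}

#' Build the eDISH figure specification
#'
#' One point per evaluable subject at the configured axis coordinates, with
#' reference lines at exactly the configured thresholds, point sizes mapped
#' affinely in rank from the chosen measure (rank-based so extreme values do
#' not dominate; equal when `point_size_measure = "none"`), colors encoding
#' temporal concordance of the ALT and TB peaks, and tooltip strings drawn
#' from the summary table.
#'
#' @param summaries Classified [subject_summary()] tibble.
#' @param cfg An [edish_config()].
#' @param subject_attributes Optional subject-attribute tibble; its
#'   categorical columns become filter controls in the report.
#' @return An `edish_figure` list: `points`, `thresholds`, `axes`, `filters`.
#' @export
build_edish <- function(summaries, cfg = edish_config(),
                        subject_attributes = NULL) {
  ev <- summaries[summaries$evaluable, ]
  if (nrow(ev) == 0L) {
    abort(paste0("zero evaluable subjects: no subject has post-baseline ALT ",
                 "and TB (", sum(!summaries$evaluable), " non-evaluable)"),
          class = "edishr_input_error")
  }
  if (!all(ev$quadrant %in% QUADRANT_LEVELS)) ev <- classify_subjects(ev, cfg)

  coords <- switch(cfg$x_axis_mode,
    fold_uln = list(x = ev$alt_peak_fold, xlab = "Peak ALT (fold ULN)",
                    xthr = cfg$alt_fold_threshold),
    fold_baseline = list(x = ev$alt_peak_fold_bl,
                         xlab = "Peak ALT (fold baseline)",
                         xthr = cfg$alt_fold_threshold),
    nr = list(x = ev$nr_peak, xlab = "Peak nR ratio",
              xthr = cfg$nr_threshold))
  y <- if (cfg$x_axis_mode == "fold_baseline") ev$tb_peak_fold_bl
       else ev$tb_peak_fold
  ylab <- if (cfg$x_axis_mode == "fold_baseline")
    "Peak total bilirubin (fold baseline)" else
    "Peak total bilirubin (fold ULN)"

  measure <- switch(cfg$point_size_measure,
    none = NULL, alp_fold = ev$alp_peak_fold, r_ratio = ev$r_value)
  size <- if (is.null(measure)) rep(1, nrow(ev)) else {
    rk <- rank(measure, ties.method = "average", na.last = "keep")
    rk[is.na(rk)] <- min(rk, na.rm = TRUE)
    0.5 + rk / nrow(ev)
  }

  tips <- tibble::tibble(
    subject = ev$subject_id,
    quadrant = ev$quadrant,
    peak_alt_fold = fmt_val(ev$alt_peak_fold),
    peak_tb_fold = fmt_val(ev$tb_peak_fold),
    peak_alp_fold = fmt_val(ev$alp_peak_fold),
    peak_separation_days = fmt_val(ev$peak_time_separation_days),
    r_ratio = fmt_val(ev$r_value),
    injury_pattern = ev$injury_pattern,
    p_alt_percent = fmt_val(ev$p_alt_percent))

  attrs <- NULL
  filters <- list()
  if (!is.null(subject_attributes)) {
    sa <- subject_attributes[match(ev$subject_id,
                                   subject_attributes$subject_id), ]
    keep <- setdiff(names(sa), "subject_id")
    keep <- keep[vapply(sa[keep], function(col)
      is.character(col) || is.factor(col), logical(1))]
    if (length(keep) > 0L) {
      attrs <- lapply(sa[keep], as.character)
      filters <- lapply(attrs, function(v) sort(unique(v)))
    }
  }

  points <- tibble::tibble(
    subject_id = ev$subject_id, x = coords$x, y = y, size = size,
    within_window = ev$within_window, quadrant = ev$quadrant)
  if (!is.null(attrs)) for (nm in names(attrs)) points[[nm]] <- attrs[[nm]]

  structure(
    list(points = points, tooltips = tips,
         thresholds = list(x = coords$xthr, y = cfg$tb_fold_threshold),
         axes = list(xlab = coords$xlab, ylab = ylab,
                     log = isTRUE(cfg$log_axes),
                     mode = cfg$x_axis_mode),
         filters = filters,
         size_measure = cfg$point_size_measure),
    class = "edish_figure")
}

#' Build a participant drill-down profile
#'
#' Time series of the four hepatic analytes as fold-ULN versus study day,
#' plus the companion same-day R-ratio series. Analytes with no data yield
#' empty, labeled series.
#'
#' @param study An `edish_study`.
#' @param subject_id Subject to profile.
#' @return An `edish_profile` list: `subject_id`, `series` (named list of
#'   tibbles `study_day`, `fold_uln`, `value`), `r_series`.
#' @export
build_profile <- function(study, subject_id) {
  rec <- study$records[study$records$subject_id == subject_id, ]
  if (nrow(rec) == 0L) {
    abort(paste0("unknown subject: ", subject_id),
          class = "edishr_lookup_error")
  }
  series <- lapply(setNames(nm = CANONICAL_ANALYTES), function(an) {
    s <- rec[rec$analyte == an, ]
    s <- s[order(s$study_day), ]
    tibble::tibble(study_day = s$study_day,
                   fold_uln = fold_uln(s$value, s$uln),
                   value = s$value)
  })
  vis <- compute_visit_derived(
    new_edish_study(rec, validation = list()), edish_config())
  r_series <- vis[!is.na(vis$r_ratio), c("study_day", "r_ratio")]
  structure(list(subject_id = subject_id, series = series,
                 r_series = r_series),
            class = "edish_profile")
}

#' Build hysteresis animation frames
#'
#' Frame `k` is the length-`k` prefix of the subject's [hysteresis_path()];
#' the final frame is the whole path.
#'
#' @param study An `edish_study`.
#' @param subject_id Subject to animate.
#' @return An `edish_hysteresis` list: `subject_id`, `path`, `frames`.
#' @export
build_hysteresis <- function(study, subject_id) {
  path <- hysteresis_path(study, subject_id)
  frames <- lapply(seq_len(nrow(path)), function(k) path[seq_len(k), ])
  structure(list(subject_id = subject_id, path = path, frames = frames),
            class = "edish_hysteresis")
}

#' Export the self-contained interactive HTML report
#'
#' Writes one HTML file with everything inlined: the eDISH scatter, the
#' per-subject drill-down profiles, the hysteresis animation, filter
#' controls, the analysis configuration and the validation summary. The
#' document contains no external script, style, font or image references and
#' renders with networking disabled. Output is deterministic: rebuilding
#' from identical inputs is byte-identical unless `timestamp = TRUE`.
#'
#' @param figure An [build_edish()] figure.
#' @param profiles Named list of [build_profile()] results keyed by subject.
#' @param cfg The [edish_config()] used (echoed in the report header).
#' @param path Output file path.
#' @param paths Named list of [hysteresis_path()] tibbles keyed by subject.
#' @param validation Optional [validate_study()] result for the header.
#' @param timestamp Include a build timestamp line (default `FALSE`).
#' @return `path`, invisibly.
#' @export
export_html <- function(figure, profiles = list(), cfg = edish_config(),
                        path, paths = list(), validation = NULL,
                        timestamp = FALSE) {
  stopifnot(inherits(figure, "edish_figure"))
  payload <- list(
    points = figure$points,
    tips = figure$tooltips,
    thresholds = figure$thresholds,
    axes = figure$axes,
    filters = figure$filters,
    size_measure = figure$size_measure,
    profiles = lapply(profiles, function(p) list(
      series = lapply(p$series, function(s)
        list(days = s$study_day, folds = s$fold_uln)),
      r = list(days = p$r_series$study_day, ratios = p$r_series$r_ratio))),
    paths = lapply(paths, function(pp) list(
      days = pp$study_day, alt = pp$alt_fold_uln, tb = pp$tb_fold_uln)),
    config = list(alt_fold_threshold = cfg$alt_fold_threshold,
                  tb_fold_threshold = cfg$tb_fold_threshold,
                  nr_threshold = cfg$nr_threshold,
                  x_axis_mode = cfg$x_axis_mode,
                  peak_window_days = cfg$peak_window_days,
                  point_size_measure = cfg$point_size_measure,
                  pattern_basis = cfg$pattern_basis,
                  ratio_basis = cfg$ratio_basis))
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null")
  header <- report_header_html(cfg, validation, nrow(figure$points),
                               timestamp)
  html <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>eDISH hepatic safety report</title>\n",
    "<style>\n", REPORT_CSS, "\n</style>\n</head>\n<body>\n",
    header,
    REPORT_BODY_HTML,
    "<script>\nconst EDISH = ", json, ";\n", REPORT_JS, "\n</script>\n",
    "</body>\n</html>\n")
  tmp <- paste0(path, ".tmp")
  ok <- tryCatch({
    writeLines(html, tmp, sep = "", useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(tmp)) {
    if (file.exists(tmp)) unlink(tmp)
    abort(paste0("cannot write report to ", path), class = "edishr_io_error")
  }
  file.rename(tmp, path)
  invisible(path)
}

report_header_html <- function(cfg, validation, n_points, timestamp) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  val <- ""
  if (!is.null(validation)) {
    excl <- validation$exclusions
    excl_txt <- if (!is.null(excl) && sum(excl$n) > 0) {
      paste0("; excluded rows: ",
             paste0(excl$reason[excl$n > 0], " (", excl$n[excl$n > 0], ")",
                    collapse = ", "))
    } else ""
    val <- paste0(
      "<p class=\"meta\">Subjects: ", validation$n_subjects,
      " (evaluable: ", validation$n_evaluable, ")", excl_txt, "</p>\n")
  }
  ts <- if (isTRUE(timestamp)) {
    paste0("<p class=\"meta\">Built: ",
           format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"), "</p>\n")
  } else ""
  paste0(
    "<h1>eDISH hepatic safety report</h1>\n",
    "<p class=\"meta\">Thresholds: ALT &#8805; ", esc(cfg$alt_fold_threshold),
    "&#215;ULN, bilirubin &#8805; ", esc(cfg$tb_fold_threshold),
    "&#215;ULN (x axis: ", esc(cfg$x_axis_mode),
    if (cfg$x_axis_mode == "nr")
      paste0(", nR threshold ", esc(cfg$nr_threshold)) else "",
    "; peak concordance window: ", esc(cfg$peak_window_days),
    " days; point size: ", esc(cfg$point_size_measure),
    "; n = ", n_points, " evaluable subjects).",
    " Point size is mapped affinely in rank of the chosen measure.</p>\n",
    val, ts)
}
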