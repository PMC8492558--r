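# Ingest: read raw delimited lab tables (SDTM-like, ADaM-like, or custom),
# auto-detect the dialect, normalize to the internal study model, validate.

SDTM_SIGNATURE <- c("USUBJID", "LBTESTCD", "LBSTRESN", "LBSTNRHI", "LBDY")
ADAM_SIGNATURE <- c("USUBJID", "PARAMCD", "AVAL", "ADY") # plus ANRHI or A1HI

#' Read a delimited laboratory table
#'
#' Thin wrapper around [data.table::fread()]: the field separator (comma or
#' tab) is sniffed automatically and all columns are returned unmodified.
#'
#' @param path Path to a delimited text file.
#' @return A tibble with the columns as found in the file.
#' @export
read_lab_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "edishr_io_error")
  }
  raw <- data.table::fread(path, sep = "auto", data.table = FALSE,
                           colClasses = NULL, showProgress = FALSE)
  tibble::as_tibble(raw)
}

#' Detect the CDISC dialect of a raw laboratory table
#'
#' A table is SDTM-like if it carries the LB-domain signature columns
#' (`USUBJID`, `LBTESTCD`, `LBSTRESN`, `LBSTNRHI`, `LBDY`) and ADaM-like if it
#' carries the ADLB signature (`USUBJID`, `PARAMCD`, `AVAL`, `ADY` plus one of
#' `ANRHI`/`A1HI`). Column-name matching is case-insensitive. If both
#' signatures are present the analysis-ready ADaM dialect wins and a message
#' records the tie.
#'
#' @param raw A data frame of laboratory results.
#' @return `"sdtm"`, `"adam"` or `"unknown"`.
#' @examples
#' detect_dialect(data.frame(USUBJID = "S1", LBTESTCD = "ALT",
#'                           LBSTRESN = 50, LBSTNRHI = 40, LBDY = 8))
#' @export
detect_dialect <- function(raw) {
  if (is.null(raw) || nrow(raw) == 0L) {
    abort("empty input", class = "edishr_input_error")
  }
  cn <- toupper(names(raw))
  is_sdtm <- all(SDTM_SIGNATURE %in% cn)
  is_adam <- all(ADAM_SIGNATURE %in% cn) && any(c("ANRHI", "A1HI") %in% cn)
  if (is_sdtm && is_adam) {
    inform("both SDTM and ADaM signatures present; preferring ADaM")
    return("adam")
  }
  if (is_adam) return("adam")
  if (is_sdtm) return("sdtm")
  "unknown"
}

#' Column mapping for non-standard laboratory tables
#'
#' Binds the columns of an arbitrary lab table to the fields the package
#' needs, and supplies the analyte-code dictionary used to translate source
#' codes to the canonical panel (ALT, AST, ALP, TB).
#'
#' @param subject_id,analyte_code,result_value,uln_value,study_day Column
#'   names in the source table (all required).
#' @param baseline_flag Optional column name; rows with a truthy value
#'   (`"Y"`, `TRUE`, `1`) are treated as the subject's baseline record for
#'   that analyte, overriding the day-based rule.
#' @param group_cols Optional character vector of subject-level grouping
#'   columns (e.g. treatment arm) to carry into the study.
#' @param analyte_dictionary Named character vector mapping source codes to
#'   canonical codes; defaults to [default_analyte_dictionary()]. If the
#'   dictionary does not cover all four canonical analytes the missing ones
#'   are reported in a warning (never silently dropped).
#' @param study_uln Optional named numeric vector (`c(ALT = 40, ...)`) used as
#'   a per-analyte fallback when a record has no usable ULN of its own.
#' @return A `mapping_config` list.
#' @export
mapping_config <- function(subject_id, analyte_code, result_value, uln_value,
                           study_day, baseline_flag = NULL,
                           group_cols = character(),
                           analyte_dictionary = default_analyte_dictionary(),
                           study_uln = NULL) {
  required <- list(subject_id = subject_id, analyte_code = analyte_code,
                   result_value = result_value, uln_value = uln_value,
                   study_day = study_day)
  for (nm in names(required)) {
    v <- required[[nm]]
    if (!is.character(v) || length(v) != 1L || is.na(v) || !nzchar(v)) {
      abort(paste0("mapping_config: required binding '", nm, "' is missing"),
            class = "edishr_config_error")
    }
  }
  dict <- setNames(as.character(analyte_dictionary),
                   toupper(names(analyte_dictionary)))
  uncovered <- setdiff(CANONICAL_ANALYTES, unique(dict))
  if (length(uncovered) > 0L) {
    warn(paste0("analyte dictionary does not cover canonical analyte(s): ",
                paste(uncovered, collapse = ", ")))
  }
  structure(
    list(subject_id = subject_id, analyte_code = analyte_code,
         result_value = result_value, uln_value = uln_value,
         study_day = study_day, baseline_flag = baseline_flag,
         group_cols = group_cols, analyte_dictionary = dict,
         study_uln = study_uln),
    class = "mapping_config"
  )
}

# Built-in mappings synthesized for the two recognised dialects. The raw
# table's column names are matched case-insensitively, so the binding uses the
# uppercase CDISC spelling.
builtin_mapping <- function(dialect, adam_range_var = "ANRHI",
                            study_uln = NULL) {
  switch(dialect,
    sdtm = mapping_config("USUBJID", "LBTESTCD", "LBSTRESN", "LBSTNRHI",
                          "LBDY", study_uln = study_uln),
    adam = mapping_config("USUBJID", "PARAMCD", "AVAL", adam_range_var,
                          "ADY", study_uln = study_uln),
    abort(paste0("no built-in mapping for dialect '", dialect, "'"),
          class = "edishr_config_error")
  )
}

new_edish_study <- function(records, subjects = NULL, provenance = list(),
                            validation = list()) {
  structure(
    list(records = records, subjects = subjects, provenance = provenance,
         validation = validation),
    class = "edish_study"
  )
}

#' @export
print.edish_study <- function(x, ...) {
  cat("<edish_study> ", nrow(x$records), " records, ",
      length(unique(x$records$subject_id)), " subjects (dialect: ",
      x$provenance$dialect %||% "custom", ")\n", sep = "")
  invisible(x)
}

truthy_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- toupper(trimws(as.character(x)))
  !is.na(x) & x %in% c("Y", "YES", "TRUE", "1")
}

# Case-insensitive column lookup; errors with the binding name on a miss.
bind_column <- function(raw, col, binding) {
  hit <- which(toupper(names(raw)) == toupper(col))
  if (length(hit) == 0L) {
    abort(paste0("configuration error: binding '", binding,
                 "' refers to column '", col, "' not present in the input"),
          class = "edishr_config_error")
  }
  raw[[hit[1L]]]
}

#' Normalize a raw laboratory table to an eDISH study
#'
#' Translates a raw table (any dialect) into the validated internal study
#' model: one record per (subject, canonical analyte, study day), each with a
#' non-negative result and a positive upper limit of normal. Rows that cannot
#' be used — unmappable analyte code, non-numeric result, missing/non-positive
#' ULN with no study-level fallback, missing or zero study day — are excluded
#' and counted by reason in the validation report; duplicates of the same
#' (subject, analyte, day) are collapsed by `dedup`.
#'
#' @param raw Data frame of laboratory results (see [read_lab_table()]).
#' @param mapping A [mapping_config()]; if `NULL` the dialect is auto-detected
#'   and the built-in SDTM/ADaM mapping is synthesized. An `unknown` dialect
#'   without a mapping is an error.
#' @param subject_data Optional data frame of per-subject attributes; must
#'   contain a subject-id column (`subject_id`, or `USUBJID`).
#' @param dedup Duplicate policy for repeated (subject, analyte, day):
#'   `"max"` keeps the highest result (conservative for safety screening),
#'   `"first"` the first row in input order, `"mean"` the mean.
#' @param adam_range_var Which ADaM reference-range variable to use when
#'   synthesizing the built-in ADaM mapping (`"ANRHI"` default, or `"A1HI"`).
#' @param study_uln Optional per-analyte fallback ULN (named numeric) applied
#'   when a record's own ULN is missing; forwarded to the built-in mapping.
#' @return An `edish_study`: list with `records` (tibble: `subject_id`,
#'   `analyte`, `value`, `uln`, `study_day`, `baseline_flag`), optional
#'   `subjects` attributes, `provenance`, and a `validation` summary.
#' @examples
#' raw <- data.frame(USUBJID = "S01", LBTESTCD = "ALT", LBSTRESN = 120,
#'                   LBSTNRHI = 40, LBDY = 8)
#' study <- normalize_labs(raw)
#' study$records
#' @export
normalize_labs <- function(raw, mapping = NULL, subject_data = NULL,
                           dedup = c("max", "first", "mean"),
                           adam_range_var = "ANRHI", study_uln = NULL) {
  dedup <- match.arg(dedup)
  if (is.null(raw) || nrow(raw) == 0L) {
    abort("empty input", class = "edishr_input_error")
  }
  dialect <- "custom"
  if (is.null(mapping)) {
    dialect <- detect_dialect(raw)
    if (dialect == "unknown") {
      abort(paste0("could not recognise an SDTM or ADaM table; ",
                   "supply a mapping_config for non-standard data"),
            class = "edishr_config_error")
    }
    mapping <- builtin_mapping(dialect, adam_range_var = adam_range_var,
                               study_uln = study_uln)
  }
  if (!inherits(mapping, "mapping_config")) {
    abort("mapping must be a mapping_config()", class = "edishr_config_error")
  }
  if (!is.null(study_uln)) mapping$study_uln <- study_uln

  n_in <- nrow(raw)
  subject_id <- as.character(bind_column(raw, mapping$subject_id, "subject_id"))
  code <- toupper(trimws(as.character(
    bind_column(raw, mapping$analyte_code, "analyte_code"))))
  value <- suppressWarnings(as.numeric(
    bind_column(raw, mapping$result_value, "result_value")))
  uln <- suppressWarnings(as.numeric(
    bind_column(raw, mapping$uln_value, "uln_value")))
  day <- suppressWarnings(as.integer(round(as.numeric(
    bind_column(raw, mapping$study_day, "study_day")))))
  baseline_flag <- if (!is.null(mapping$baseline_flag)) {
    truthy_flag(bind_column(raw, mapping$baseline_flag, "baseline_flag"))
  } else {
    rep(FALSE, n_in)
  }

  analyte <- unname(mapping$analyte_dictionary[code])

  # ULN fallback to the study-level per-analyte value where the record's own
  # reference range is unusable; without a reference, fold-ULN is undefined.
  bad_uln <- is.na(uln) | uln <= 0
  n_uln_fallback <- 0L
  if (any(bad_uln) && !is.null(mapping$study_uln)) {
    fb <- mapping$study_uln[analyte]
    fixable <- bad_uln & !is.na(fb) & fb > 0
    uln[fixable] <- fb[fixable]
    n_uln_fallback <- sum(fixable)
    bad_uln <- is.na(uln) | uln <= 0
  }

  excl_analyte <- is.na(analyte)
  excl_result <- !excl_analyte & (is.na(value) | value < 0)
  excl_uln <- !excl_analyte & !excl_result & bad_uln
  excl_day <- !excl_analyte & !excl_result & !excl_uln &
    (is.na(day) | day == 0L)
  keep <- !(excl_analyte | excl_result | excl_uln | excl_day)

  exclusions <- tibble::tibble(
    reason = c("unmappable analyte code", "non-numeric or negative result",
               "missing or non-positive ULN", "missing or day-0 study day"),
    n = c(sum(excl_analyte), sum(excl_result), sum(excl_uln), sum(excl_day))
  )

  records <- tibble::tibble(
    subject_id = subject_id[keep], analyte = analyte[keep],
    value = value[keep], uln = uln[keep], study_day = day[keep],
    baseline_flag = baseline_flag[keep]
  )
  if (nrow(records) == 0L) {
    abort("no usable laboratory records after normalization",
          class = "edishr_input_error")
  }

  n_before <- nrow(records)
  records <- dedup_records(records, dedup)
  n_collapsed <- n_before - nrow(records)

  # Mixed-unit heuristic: a ULN that varies more than 2x within one analyte
  # suggests inconsistent units (fold computations would silently mix scales).
  uln_span <- records |>
    dplyr::summarise(span = max(.data$uln) / min(.data$uln),
                     .by = "analyte")
  if (any(uln_span$span > 2)) {
    warn(paste0("ULN varies more than 2-fold within analyte(s): ",
                paste(uln_span$analyte[uln_span$span > 2], collapse = ", "),
                "; check that units are consistent"))
  }

  subjects <- normalize_subject_data(subject_data, mapping$group_cols)

  study <- new_edish_study(
    records = records, subjects = subjects,
    provenance = list(dialect = dialect,
                      mapping = mapping[c("subject_id", "analyte_code",
                                          "result_value", "uln_value",
                                          "study_day")],
                      dedup = dedup),
    validation = list(n_rows_in = n_in, n_records = nrow(records),
                      n_excluded = sum(exclusions$n),
                      exclusions = exclusions,
                      n_dedup_collapsed = n_collapsed,
                      n_uln_fallback = n_uln_fallback)
  )
  vr <- validate_study(study)
  if (vr$n_evaluable == 0L) {
    abort("zero evaluable subjects (no subject has post-baseline ALT and TB)",
          class = "edishr_input_error")
  }
  study$validation <- utils::modifyList(study$validation,
                                        vr[c("n_subjects", "n_evaluable",
                                             "non_evaluable")])
  study
}

dedup_records <- function(records, policy) {
  pick <- switch(policy,
    max = function(d) d[order(-d$value, d$.row_order), ][1L, ],
    first = function(d) d[order(d$.row_order), ][1L, ],
    mean = function(d) {
      out <- d[order(d$.row_order), ][1L, ]
      out$value <- mean(d$value)
      out
    }
  )
  records$.row_order <- seq_len(nrow(records))
  out <- records |>
    dplyr::group_by(.data$subject_id, .data$analyte, .data$study_day) |>
    dplyr::group_modify(~ pick(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$analyte, .data$study_day)
  out$.row_order <- NULL
  dplyr::relocate(out, "subject_id", "analyte", "value", "uln", "study_day")
}

normalize_subject_data <- function(subject_data, group_cols = character()) {
  if (is.null(subject_data)) return(NULL)
  sd <- tibble::as_tibble(subject_data)
  idx <- which(toupper(names(sd)) %in% c("SUBJECT_ID", "USUBJID"))
  if (length(idx) == 0L) {
    abort("subject_data must contain a 'subject_id' or 'USUBJID' column",
          class = "edishr_config_error")
  }
  names(sd)[idx[1L]] <- "subject_id"
  sd$subject_id <- as.character(sd$subject_id)
  if (length(group_cols) > 0L) {
    missing <- setdiff(group_cols, names(sd))
    if (length(missing) > 0L) {
      abort(paste0("configuration error: grouping column(s) not found: ",
                   paste(missing, collapse = ", ")),
            class = "edishr_config_error")
    }
  }
  dplyr::distinct(sd, .data$subject_id, .keep_all = TRUE)
}

#' Validate an eDISH study
#'
#' Pure reporting operation: counts subjects, evaluable subjects (at least one
#' post-baseline ALT record and one post-baseline TB record, study day > 1),
#' and carries forward the exclusion accounting from normalization. The study
#' is not modified.
#'
#' @param study An `edish_study`.
#' @return An `edish_validation` list: `n_subjects`, `n_evaluable`,
#'   `non_evaluable` (tibble of subject id + reason), exclusion counts, and an
#'   `error_level` flag when the record set is empty.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "edish_study"))
  rec <- study$records
  if (nrow(rec) == 0L) {
    return(structure(list(n_subjects = 0L, n_evaluable = 0L,
                          non_evaluable = tibble::tibble(subject_id = character(),
                                                         reason = character()),
                          n_rows_in = study$validation$n_rows_in %||% 0L,
                          n_records = 0L,
                          exclusions = study$validation$exclusions,
                          n_dedup_collapsed = study$validation$n_dedup_collapsed %||% 0L,
                          error_level = TRUE),
                     class = "edish_validation"))
  }
  post <- rec[rec$study_day > 1L, ]
  subjects <- sort(unique(rec$subject_id))
  has_alt <- subjects %in% post$subject_id[post$analyte == "ALT"]
  has_tb <- subjects %in% post$subject_id[post$analyte == "TB"]
  evaluable <- has_alt & has_tb
  reason <- dplyr::case_when(
    !has_alt & !has_tb ~ "no post-baseline ALT or TB",
    !has_alt ~ "no post-baseline ALT",
    !has_tb ~ "no post-baseline TB",
    .default = NA_character_
  )
  structure(
    list(n_subjects = length(subjects),
         n_evaluable = sum(evaluable),
         non_evaluable = tibble::tibble(subject_id = subjects[!evaluable],
                                        reason = reason[!evaluable]),
         n_rows_in = study$validation$n_rows_in %||% nrow(rec),
         n_records = nrow(rec),
         exclusions = study$validation$exclusions,
         n_dedup_collapsed = study$validation$n_dedup_collapsed %||% 0L,
         error_level = FALSE),
    class = "edish_validation"
  )
}

#' @export
print.edish_validation <- function(x, ...) {
  cat("<edish_validation>\n")
  cat("  subjects:          ", x$n_subjects, "\n", sep = "")
  cat("  evaluable:         ", x$n_evaluable, "\n", sep = "")
  cat("  non-evaluable:     ", x$n_subjects - x$n_evaluable, "\n", sep = "")
  if (!is.null(x$exclusions)) {
    excl <- x$exclusions[x$exclusions$n > 0L, ]
    if (nrow(excl) > 0L) {
      cat("  excluded rows:\n")
      for (i in seq_len(nrow(excl))) {
        cat("    ", excl$reason[i], ": ", excl$n[i], "\n", sep = "")
      }
    }
  }
  if (isTRUE(x$error_level)) cat("  ERROR: empty record set\n")
  invisible(x)
}

#' List evaluable subject ids
#'
#' A subject is evaluable when it has at least one post-baseline (study day
#' > 1) ALT record and one post-baseline TB record.
#'
#' @param study An `edish_study`.
#' @return Character vector of subject ids, sorted.
#' @export
evaluable_subjects <- function(study) {
  rec <- study$records[study$records$study_day > 1L, ]
  subjects <- sort(unique(study$records$subject_id))
  subjects[subjects %in% rec$subject_id[rec$analyte == "ALT"] &
           subjects %in% rec$subject_id[rec$analyte == "TB"]]
}
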