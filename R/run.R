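# Run configuration (YAML, JSON-compatible subset) and the one-command
# pipeline: data in, self-contained report plus derived tables out.

default_run_config <- function() {
  list(
    input = NULL, mapping = NULL, subject_data = NULL,
    output_dir = "edish_report",
    dedup = "max", adam_range_var = "ANRHI", study_uln = NULL,
    edish = list(alt_fold_threshold = 3, tb_fold_threshold = 2,
                 nr_threshold = 5, x_axis_mode = "fold_uln",
                 peak_window_days = 30, point_size_measure = "none",
                 pattern_basis = "r", ratio_basis = "visit",
                 hepatocellular_cut = 5, cholestatic_cut = 2,
                 log_axes = TRUE, group_by = NULL),
    p_alt = list(distribution_volume_l = 3, total_hepatocyte_alt_u = 30000),
    timestamp = FALSE, log_level = "info", seed = NULL
  )
}

check_known_keys <- function(given, known, context) {
  unknown <- setdiff(names(given), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown configuration key", if (length(unknown) > 1) "s",
                 " in ", context, ": ", paste(unknown, collapse = ", ")),
          class = "edishr_config_error")
  }
}

#' Load a run configuration
#'
#' Reads a YAML file (a JSON-compatible subset is accepted — `yaml` parses
#' JSON), rejects unknown keys by name, fills defaults for everything
#' omitted, validates the analysis block, and echoes the fully resolved
#' configuration to the log.
#'
#' @param path Path to a YAML/JSON config file; an empty file yields the
#'   all-defaults configuration.
#' @param quiet Suppress the resolved-config echo.
#' @return A `run_config` list (see [default_run_config] keys).
#' @export
load_run_config <- function(path = NULL, quiet = FALSE) {
  defaults <- default_run_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path),
            class = "edishr_io_error")
    }
    user <- tryCatch(yaml::read_yaml(path),
      error = function(e) {
        abort(paste0("malformed config file ", path, ": ",
                     conditionMessage(e)),
              class = "edishr_config_error")
      })
    if (is.null(user)) user <- list()
  }
  if (!is.list(user)) {
    abort("config file must contain a mapping of keys to values",
          class = "edishr_config_error")
  }
  check_known_keys(user, names(defaults), "run config")
  for (block in c("edish", "p_alt")) {
    if (!is.null(user[[block]])) {
      check_known_keys(user[[block]], names(defaults[[block]]),
                       paste0("'", block, "' block"))
      defaults[[block]] <- utils::modifyList(defaults[[block]],
                                             user[[block]],
                                             keep.null = TRUE)
    }
  }
  cfg <- utils::modifyList(defaults,
                           user[setdiff(names(user), c("edish", "p_alt"))],
                           keep.null = TRUE)
  # Validate analysis invariants through the constructors; they name the
  # offending key.
  as_edish_config(cfg)
  rc <- structure(cfg, class = "run_config")
  if (!quiet && !identical(cfg$log_level, "quiet")) {
    inform(paste0("resolved run config:\n",
                  yaml::as.yaml(unclass(rc))))
  }
  rc
}

#' Write a run configuration back to YAML
#'
#' Inverse of [load_run_config()]: a written config reloads to an equal
#' `run_config`.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  # unset (NULL) keys are defaults; omit them rather than writing '~'
  yaml::write_yaml(Filter(Negate(is.null), unclass(cfg)), path)
  invisible(path)
}

#' @rdname load_run_config
#' @param cfg A `run_config` list.
#' @export
as_edish_config <- function(cfg) {
  args <- cfg$edish
  args$p_alt <- do.call(p_alt_constants, cfg$p_alt)
  do.call(edish_config, args)
}

#' Run the full eDISH pipeline
#'
#' One command from a laboratory data file to the interactive report:
#' ingest and validate, derive per-visit and per-subject statistics, classify
#' quadrants, and write the report plus derived tables. Artifacts are staged
#' in a temporary directory and only moved into `output_dir` once everything
#' has been produced, so a failure never leaves a partial report behind.
#'
#' @param cfg A `run_config` from [load_run_config()], or `NULL` for
#'   defaults plus the explicit arguments below.
#' @param input Optional input path overriding `cfg$input`.
#' @param output_dir Optional output directory overriding `cfg$output_dir`.
#' @param report Write the HTML report (`TRUE`) or derived tables only.
#' @return Invisibly, a list: `artifacts` (named paths), `validation`,
#'   `counts`, `summaries`.
#' @export
run_pipeline <- function(cfg = NULL, input = NULL, output_dir = NULL,
                         report = TRUE) {
  if (is.null(cfg)) cfg <- load_run_config(NULL, quiet = TRUE)
  if (!is.null(input)) cfg$input <- input
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$input)) {
    abort("run: no input file configured", class = "edishr_config_error")
  }
  if (!file.exists(cfg$input)) {
    abort(paste0("run: input file not found: ", cfg$input),
          class = "edishr_io_error")
  }
  ecfg <- as_edish_config(cfg)

  warnings_seen <- character()
  collect <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    raw <- read_lab_table(cfg$input)
    mapping <- if (!is.null(cfg$mapping)) load_mapping_config(cfg$mapping)
    subject_data <- if (!is.null(cfg$subject_data))
      read_lab_table(cfg$subject_data)
    study_uln <- if (!is.null(cfg$study_uln)) unlist(cfg$study_uln)
    study <- normalize_labs(raw, mapping = mapping,
                            subject_data = subject_data,
                            dedup = cfg$dedup,
                            adam_range_var = cfg$adam_range_var,
                            study_uln = study_uln)
    validation <- validate_study(study)
    visits <- compute_visit_derived(study, ecfg)
    summaries <- classify_subjects(subject_summary(study, ecfg), ecfg)
    counts <- quadrant_counts(summaries, ecfg,
                              group_by = ecfg$group_by,
                              subject_attributes = study$subjects)
    triage <- triage_table(summaries, ecfg)
  }, warning = collect)
  validation$warnings <- warnings_seen

  stage <- tempfile("edish_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  write_derived_tables(visits, summaries, stage)
  data.table::fwrite(triage, file.path(stage, "triage.csv"))
  data.table::fwrite(counts, file.path(stage, "quadrant_counts.csv"))
  jsonlite::write_json(
    list(n_subjects = validation$n_subjects,
         n_evaluable = validation$n_evaluable,
         non_evaluable = validation$non_evaluable,
         n_rows_in = validation$n_rows_in,
         n_records = validation$n_records,
         exclusions = validation$exclusions,
         n_dedup_collapsed = validation$n_dedup_collapsed,
         warnings = warnings_seen),
    file.path(stage, "validation.json"), auto_unbox = TRUE, digits = NA)
  if (report) {
    figure <- build_edish(summaries, ecfg,
                          subject_attributes = study$subjects)
    ids <- evaluable_subjects(study)
    profiles <- lapply(setNames(nm = ids), build_profile, study = study)
    paths <- lapply(setNames(nm = ids), hysteresis_path, study = study)
    export_html(figure, profiles, ecfg,
                path = file.path(stage, "report.html"), paths = paths,
                validation = validation, timestamp = isTRUE(cfg$timestamp))
  }

  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
  }
  staged <- list.files(stage, full.names = TRUE)
  ok <- file.copy(staged, cfg$output_dir, overwrite = TRUE)
  if (!all(ok)) {
    abort(paste0("could not write artifacts to ", cfg$output_dir),
          class = "edishr_io_error")
  }
  artifacts <- setNames(file.path(cfg$output_dir, basename(staged)),
                        sub("[.][^.]+$", "", basename(staged)))
  if (!identical(cfg$log_level, "quiet")) {
    inform(paste0("wrote ", length(artifacts), " artifact(s) to ",
                  cfg$output_dir))
  }
  invisible(list(artifacts = artifacts, validation = validation,
                 counts = counts, summaries = summaries))
}

#' Load a column-mapping configuration file
#'
#' YAML/JSON file whose keys are the [mapping_config()] arguments
#' (`subject_id`, `analyte_code`, `result_value`, `uln_value`, `study_day`,
#' optional `baseline_flag`, `group_cols`, `analyte_dictionary`,
#' `study_uln`). Unknown keys are rejected by name.
#'
#' @param path Path to the mapping file.
#' @return A [mapping_config()].
#' @export
load_mapping_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("mapping file not found: ", path),
          class = "edishr_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("subject_id", "analyte_code", "result_value", "uln_value",
             "study_day", "baseline_flag", "group_cols",
             "analyte_dictionary", "study_uln")
  check_known_keys(raw, known, "mapping config")
  if (!is.null(raw$analyte_dictionary)) {
    raw$analyte_dictionary <- unlist(raw$analyte_dictionary)
  } else {
    raw$analyte_dictionary <- default_analyte_dictionary()
  }
  if (!is.null(raw$study_uln)) raw$study_uln <- unlist(raw$study_uln)
  if (!is.null(raw$group_cols)) raw$group_cols <- as.character(raw$group_cols)
  do.call(mapping_config, raw)
}
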