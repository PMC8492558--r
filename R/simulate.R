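# Synthetic clinical-trial hepatic panels with known injury phenotypes.
# The generator gives every other module a ground truth: each simulated
# subject carries a designed phenotype whose peak folds satisfy its defining
# inequalities with at least a 1.2x margin at zero noise, so the full
# pipeline must recover the design exactly when noise is off.

SIM_PHENOTYPES <- c("normal", "hys_law", "temples", "hyperbili",
                    "cholestatic", "mixed")

# Designed excursions per phenotype: target peak fold-ULN, onset day and peak
# day per affected analyte. Analytes without an excursion sit at the baseline
# fold (0.6). Margins at zero noise (thresholds ALT 3, TB 2, ratio cuts 2/5):
#   hys_law    : ALT 6 >= 3.6, TB 3 >= 2.4, R at ALT peak = 6/0.6 = 10 >= 6
#   temples    : ALT 5 >= 3.6, TB 0.6 <= 2/1.2
#   hyperbili  : TB 3 >= 2.4, ALT 0.6 <= 3/1.2
#   cholestatic: ALP 3, R at ALT peak = 1.2/3 = 0.4 <= 2/1.2
#   mixed      : ALT 3.8 >= 3.6, R = 3.8/1.2 ~ 3.17 in (2*1.2, 5/1.2)
#   normal     : all folds 0.6 < 1.5/1.2
phenotype_registry <- function() {
  exc <- function(peak_fold, onset, peak_day) {
    list(peak_fold = peak_fold, onset = onset, peak_day = peak_day)
  }
  list(
    normal = list(),
    hys_law = list(ALT = exc(6.0, 8, 15), AST = exc(5.0, 8, 15),
                   TB = exc(3.0, 15, 22)),
    temples = list(ALT = exc(5.0, 8, 15), AST = exc(4.0, 8, 15)),
    hyperbili = list(TB = exc(3.0, 8, 15)),
    cholestatic = list(ALP = exc(3.0, 8, 15), ALT = exc(1.2, 8, 15),
                       TB = exc(1.4, 8, 15)),
    mixed = list(ALT = exc(3.8, 8, 15), AST = exc(3.0, 8, 15),
                 ALP = exc(1.2, 8, 15))
  )
}

BASELINE_FOLD <- 0.6

#' Specification of a synthetic hepatic-safety trial
#'
#' @param n_subjects Number of subjects; must equal the sum of a count-valued
#'   `phenotype_mix`.
#' @param phenotype_mix Named vector over
#'   `c("normal", "hys_law", "temples", "hyperbili", "cholestatic", "mixed")`;
#'   either counts summing to `n_subjects` or proportions summing to 1
#'   (rounded to counts by largest remainder). The default mix emulates a
#'   trial with a modest hepatotoxic signal: 1.5% Hy's Law, 2.5% Temple's
#'   Corollary, 2.5% hyperbilirubinemia, 5% cholestatic, 5% mixed, the rest
#'   normal.
#' @param visit_schedule Study days sampled (CDISC convention, no day 0);
#'   must include at least one day `<= 1` (baseline candidate) and two days
#'   `> 1`. Default: screening at day -7, first dose day 1, then days 8, 15,
#'   22, 29, 43, 57.
#' @param uln Named per-analyte upper limits of normal; defaults ALT 40 U/L,
#'   AST 40 U/L, ALP 120 U/L, TB 1.2 mg/dL.
#' @param noise_sd Lognormal noise on the log scale applied to baselines and
#'   to every visit value; default 0.1 (~10% CV, typical short-term analytic
#'   plus biological variation of serum liver tests). 0 gives a fully
#'   deterministic study.
#' @param decay_half_life Half-life (days) of the post-peak return toward
#'   baseline on the log-fold scale; default 10.
#' @param n_arms Number of treatment arms subjects are assigned to (round
#'   robin), providing a grouping attribute; default 2.
#' @param seed Master seed; every subject draws from an independent substream
#'   derived from it, so changing `n_subjects` never reshuffles earlier
#'   subjects.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_subjects = 200,
                     phenotype_mix = c(hys_law = 0.015, temples = 0.025,
                                       hyperbili = 0.025, cholestatic = 0.05,
                                       mixed = 0.05, normal = 0.835),
                     visit_schedule = c(-7, 1, 8, 15, 22, 29, 43, 57),
                     uln = c(ALT = 40, AST = 40, ALP = 120, TB = 1.2),
                     noise_sd = 0.1, decay_half_life = 10, n_arms = 2,
                     seed = 1) {
  if (is.null(names(phenotype_mix)) ||
      !all(names(phenotype_mix) %in% SIM_PHENOTYPES)) {
    abort(paste0("phenotype_mix names must be among: ",
                 paste(SIM_PHENOTYPES, collapse = ", ")),
          class = "edishr_config_error")
  }
  counts <- resolve_mix(phenotype_mix, n_subjects)
  if (sum(counts) != n_subjects) {
    abort("phenotype_mix must sum to n_subjects (counts) or 1 (proportions)",
          class = "edishr_config_error")
  }
  days <- sort(unique(as.integer(visit_schedule)))
  if (any(days == 0L) || sum(days <= 1L) < 1L || sum(days > 1L) < 2L) {
    abort(paste0("visit_schedule must avoid day 0 and include >= 1 day <= 1 ",
                 "and >= 2 days > 1"), class = "edishr_config_error")
  }
  if (!all(CANONICAL_ANALYTES %in% names(uln)) || any(uln <= 0)) {
    abort("uln must name positive limits for ALT, AST, ALP, TB",
          class = "edishr_config_error")
  }
  if (noise_sd < 0 || decay_half_life <= 0) {
    abort("noise_sd must be >= 0 and decay_half_life > 0",
          class = "edishr_config_error")
  }
  structure(list(n_subjects = n_subjects, counts = counts,
                 visit_schedule = days, uln = uln, noise_sd = noise_sd,
                 decay_half_life = decay_half_life,
                 n_arms = as.integer(n_arms), seed = as.integer(seed)),
            class = "sim_spec")
}

resolve_mix <- function(mix, n) {
  counts <- setNames(integer(length(SIM_PHENOTYPES)), SIM_PHENOTYPES)
  mix <- mix[mix > 0]
  if (all(mix == round(mix)) && sum(mix) == n) {
    counts[names(mix)] <- as.integer(mix)
  } else if (isTRUE(all.equal(sum(mix), 1))) {
    # proportions: largest-remainder rounding to counts
    raw <- mix * n
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
      top_up <- order(raw - base, decreasing = TRUE)[seq_len(left)]
      base[top_up] <- base[top_up] + 1
    }
    counts[names(mix)] <- as.integer(base)
  } else {
    return(setNames(rep(-1L, length(SIM_PHENOTYPES)), SIM_PHENOTYPES))
  }
  counts
}

# Designed fold-ULN trajectory: flat at the baseline fold until onset,
# log-linear rise to the designed peak, then exponential decay of the
# log-fold excess with the configured half-life (floors at baseline).
designed_fold <- function(day, baseline_fold, excursion, half_life) {
  lb <- log(baseline_fold)
  if (is.null(excursion)) return(rep(baseline_fold, length(day)))
  lp <- log(excursion$peak_fold)
  frac <- ifelse(
    day <= excursion$onset, 0,
    ifelse(day <= excursion$peak_day,
           (day - excursion$onset) / (excursion$peak_day - excursion$onset),
           2^(-(day - excursion$peak_day) / half_life)))
  exp(lb + (lp - lb) * frac)
}

#' Simulate one subject's hepatic panel
#'
#' Draws a per-analyte baseline fold (lognormal around 0.6 x ULN), overlays
#' the phenotype's designed excursions, and applies per-visit multiplicative
#' lognormal noise. Uses the current RNG state; [simulate_study()] seeds an
#' independent substream per subject.
#'
#' @param phenotype One of `r paste(SIM_PHENOTYPES, collapse = ", ")`.
#' @param spec A [sim_spec()].
#' @param subject_id Identifier for the emitted records.
#' @return Tibble of records (`subject_id`, `analyte`, `value`, `uln`,
#'   `study_day`).
#' @export
simulate_subject <- function(phenotype, spec = sim_spec(),
                             subject_id = "S0001") {
  registry <- phenotype_registry()
  if (!phenotype %in% names(registry)) {
    abort(paste0("unknown phenotype: ", phenotype),
          class = "edishr_config_error")
  }
  excursions <- registry[[phenotype]]
  days <- spec$visit_schedule
  out <- vector("list", length(CANONICAL_ANALYTES))
  for (i in seq_along(CANONICAL_ANALYTES)) {
    an <- CANONICAL_ANALYTES[i]
    baseline_fold <- BASELINE_FOLD * exp(rnorm(1, 0, spec$noise_sd))
    fold <- designed_fold(days, baseline_fold, excursions[[an]],
                          spec$decay_half_life)
    value <- spec$uln[[an]] * fold * exp(rnorm(length(days), 0, spec$noise_sd))
    out[[i]] <- tibble::tibble(subject_id = subject_id, analyte = an,
                               value = value, uln = spec$uln[[an]],
                               study_day = days)
  }
  dplyr::bind_rows(out)
}

# Truth labels for a phenotype, derived from the designed (zero-noise) folds
# through the same public classification rules the pipeline applies.
designed_truth <- function(phenotype, spec, cfg = edish_config()) {
  excursions <- phenotype_registry()[[phenotype]]
  peak_fold <- setNames(rep(BASELINE_FOLD, 4), CANONICAL_ANALYTES)
  peak_day <- setNames(rep(NA_integer_, 4), CANONICAL_ANALYTES)
  post <- spec$visit_schedule[spec$visit_schedule > 1L]
  for (an in names(excursions)) {
    folds <- designed_fold(post, BASELINE_FOLD, excursions[[an]],
                           spec$decay_half_life)
    peak_fold[[an]] <- max(folds)
    peak_day[[an]] <- post[which.max(folds)]
  }
  # At zero noise un-excursed analytes are flat; the earliest post-baseline
  # day is the tie-broken peak day.
  peak_day[is.na(peak_day)] <- min(post)
  alt_peak_day <- peak_day[["ALT"]]
  alp_at_alt_peak <- designed_fold(alt_peak_day, BASELINE_FOLD,
                                   excursions[["ALP"]],
                                   spec$decay_half_life)
  r_design <- peak_fold[["ALT"]] / alp_at_alt_peak
  fake <- tibble::tibble(
    subject_id = "truth", evaluable = TRUE,
    alt_peak_fold = peak_fold[["ALT"]], tb_peak_fold = peak_fold[["TB"]],
    nr_peak = max(peak_fold[["ALT"]], peak_fold[["AST"]]) / alp_at_alt_peak)
  tibble::tibble(
    phenotype = phenotype,
    alt_peak_fold = peak_fold[["ALT"]], ast_peak_fold = peak_fold[["AST"]],
    alp_peak_fold = peak_fold[["ALP"]], tb_peak_fold = peak_fold[["TB"]],
    alt_peak_day = peak_day[["ALT"]], tb_peak_day = peak_day[["TB"]],
    quadrant = classify_quadrant(fake, cfg),
    injury_pattern = injury_pattern(r_design, cfg$hepatocellular_cut,
                                    cfg$cholestatic_cut)
  )
}

#' Simulate a hepatic-safety study with truth labels
#'
#' Generates `spec$n_subjects` subjects in phenotype order, each from an
#' independent RNG substream derived from the master seed (so a run with more
#' subjects reproduces the earlier ones exactly), assigns treatment arms
#' round-robin, and returns both the normalized study and the designed truth.
#'
#' @param spec A [sim_spec()].
#' @param cfg An [edish_config()] used to express the designed truth labels.
#' @return List with `study` (an `edish_study`) and `truth` (tibble:
#'   `subject_id`, `phenotype`, designed peak folds and days, designed
#'   `quadrant` and `injury_pattern`).
#' @examples
#' sim <- simulate_study(sim_spec(n_subjects = 10,
#'                                phenotype_mix = c(normal = 8, hys_law = 2),
#'                                noise_sd = 0, seed = 7))
#' sim$truth$quadrant
#' @export
simulate_study <- function(spec = sim_spec(), cfg = edish_config()) {
  stopifnot(inherits(spec, "sim_spec"))
  phenotypes <- rep(names(spec$counts), spec$counts)
  n <- length(phenotypes)
  ids <- sprintf("S%04d", seq_len(n))
  # Independent per-subject substreams: subject seeds are a pure function of
  # (master seed, subject index), so prefixes are stable under n changes.
  subject_seeds <- (spec$seed + 1000003L * seq_len(n)) %% .Machine$integer.max

  truth_by_pheno <- lapply(setNames(nm = names(spec$counts)[spec$counts > 0]),
                           designed_truth, spec = spec, cfg = cfg)
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    records[[i]] <- simulate_subject(phenotypes[i], spec, ids[i])
    truth[[i]] <- dplyr::bind_cols(tibble::tibble(subject_id = ids[i]),
                                   truth_by_pheno[[phenotypes[i]]])
  }
  records <- dplyr::bind_rows(records)
  records$baseline_flag <- FALSE
  subjects <- tibble::tibble(
    subject_id = ids,
    arm = paste0("Arm ", LETTERS[(seq_len(n) - 1L) %% spec$n_arms + 1L]))
  study <- new_edish_study(
    records = dplyr::arrange(records, .data$subject_id, .data$analyte,
                             .data$study_day),
    subjects = subjects,
    provenance = list(dialect = "simulated", seed = spec$seed),
    validation = list(n_rows_in = nrow(records), n_records = nrow(records),
                      n_excluded = 0L,
                      exclusions = tibble::tibble(reason = character(),
                                                  n = integer()),
                      n_dedup_collapsed = 0L)
  )
  vr <- validate_study(study)
  study$validation <- utils::modifyList(study$validation,
                                        vr[c("n_subjects", "n_evaluable",
                                             "non_evaluable")])
  list(study = study, truth = dplyr::bind_rows(truth))
}

#' Write a study out in a CDISC-like dialect
#'
#' Emits exactly the signature columns [detect_dialect()] recognises — SDTM:
#' `USUBJID, LBTESTCD, LBSTRESN, LBSTNRHI, LBDY`; ADaM: `USUBJID, PARAMCD,
#' AVAL, ANRHI, ADY` — using dictionary synonyms for the analyte codes
#' (`BILI`/`TBILI` for total bilirubin) so the round trip exercises the code
#' dictionary. Values are printed with 17 significant digits, which makes the
#' write/normalize round trip exact in double precision, and rows are sorted,
#' so a fixed study yields a byte-identical file.
#'
#' @param study An `edish_study`.
#' @param dialect `"sdtm"` or `"adam"`.
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_dialect <- function(study, dialect = c("sdtm", "adam"), path) {
  dialect <- match.arg(dialect)
  rec <- dplyr::arrange(study$records, .data$subject_id, .data$analyte,
                        .data$study_day)
  code <- switch(dialect,
    sdtm = c(ALT = "ALT", AST = "AST", ALP = "ALP", TB = "BILI"),
    adam = c(ALT = "ALT", AST = "AST", ALP = "ALP", TB = "TBILI"))
  num <- function(x) sprintf("%.17g", x)
  out <- data.frame(
    USUBJID = rec$subject_id,
    CODE = unname(code[rec$analyte]),
    VALUE = vapply(rec$value, num, character(1)),
    ULN = vapply(rec$uln, num, character(1)),
    DAY = rec$study_day,
    stringsAsFactors = FALSE)
  names(out) <- switch(dialect,
    sdtm = c("USUBJID", "LBTESTCD", "LBSTRESN", "LBSTNRHI", "LBDY"),
    adam = c("USUBJID", "PARAMCD", "AVAL", "ANRHI", "ADY"))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Write simulator truth labels
#'
#' @param truth Truth tibble from [simulate_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path)
  invisible(path)
}
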