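# Shared fixtures and independent reference implementations used by the
# property tests. The oracles deliberately avoid the package's derivation
# code paths: they are plain loops over raw records.

# Build a study from a plain records data frame through the public ingest
# surface (identity SDTM-style table).
make_study <- function(df, ...) {
  raw <- data.frame(USUBJID = df$subject_id, LBTESTCD = df$analyte,
                    LBSTRESN = df$value, LBSTNRHI = df$uln,
                    LBDY = df$study_day, stringsAsFactors = FALSE)
  normalize_labs(raw, ...)
}

# A random messy study: per subject a random subset of analytes and visit
# days, lognormal values. Subject 1 is always fully evaluable so the study
# normalizes. Duplicate-free by construction (days sampled without
# replacement).
random_study <- function(n_subjects, seed) {
  set.seed(seed)
  uln <- c(ALT = 40, AST = 40, ALP = 120, TB = 1.2)
  all_days <- setdiff(-7:60, 0)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    id <- sprintf("R%03d", i)
    analytes <- if (i == 1) names(uln) else {
      names(uln)[runif(4) < 0.85]
    }
    for (an in analytes) {
      n_days <- if (i == 1 && an %in% c("ALT", "TB")) {
        sample(4:9, 1)
      } else {
        sample(1:9, 1)
      }
      days <- sample(all_days, n_days)
      if (i == 1 && an %in% c("ALT", "TB")) days <- unique(c(days, -2, 10))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, analyte = an,
        value = rlnorm(length(days), log(0.8 * uln[[an]]), 0.6),
        uln = uln[[an]], study_day = days, stringsAsFactors = FALSE)
    }
  }
  make_study(do.call(rbind, rows))
}

# Brute-force per-subject summary: full scan over raw records with explicit
# loops. Baselines are the latest record at day <= 1; peaks the maximum
# post-baseline fold-ULN, ties to the earliest day.
oracle_summary <- function(records, window = 30) {
  out <- list()
  for (id in sort(unique(records$subject_id))) {
    row <- list(subject_id = id)
    for (an in c("ALT", "AST", "ALP", "TB")) {
      sub <- records[records$subject_id == id & records$analyte == an, ]
      bl <- sub[sub$study_day <= 1, ]
      row[[paste0(tolower(an), "_baseline")]] <-
        if (nrow(bl) == 0) NA_real_ else bl$value[which.max(bl$study_day)]
      post <- sub[sub$study_day > 1, ]
      if (nrow(post) == 0) {
        row[[paste0(tolower(an), "_peak_fold")]] <- NA_real_
        row[[paste0(tolower(an), "_peak_day")]] <- NA_real_
        row[[paste0(tolower(an), "_peak_value")]] <- NA_real_
      } else {
        folds <- fold_uln(post$value, post$uln)
        best <- which(folds == max(folds))
        best <- best[which.min(post$study_day[best])]
        row[[paste0(tolower(an), "_peak_fold")]] <- folds[best]
        row[[paste0(tolower(an), "_peak_day")]] <- post$study_day[best]
        row[[paste0(tolower(an), "_peak_value")]] <- post$value[best]
      }
    }
    row$peak_time_separation_days <-
      abs(row$alt_peak_day - row$tb_peak_day)
    row$within_window <- row$peak_time_separation_days <= window
    out[[length(out) + 1L]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}

# Brute-force LOCF merge of a subject's ALT and TB fold series.
oracle_hysteresis <- function(records, id) {
  sub <- records[records$subject_id == id, ]
  get <- function(an) {
    s <- sub[sub$analyte == an, ]
    s <- s[order(s$study_day), ]
    data.frame(day = s$study_day, fold = fold_uln(s$value, s$uln))
  }
  alt <- get("ALT"); tb <- get("TB")
  days <- sort(unique(c(alt$day, tb$day)))
  res <- NULL
  last_alt <- NA_real_; last_tb <- NA_real_
  for (d in days) {
    if (d %in% alt$day) last_alt <- alt$fold[alt$day == d]
    if (d %in% tb$day) last_tb <- tb$fold[tb$day == d]
    if (!is.na(last_alt) && !is.na(last_tb)) {
      res <- rbind(res, data.frame(study_day = d, alt_fold_uln = last_alt,
                                   tb_fold_uln = last_tb))
    }
  }
  res
}

# Compare package summaries against the oracle on the shared columns.
expect_summary_matches_oracle <- function(study, cfg = edish_config()) {
  got <- subject_summary(study, cfg)
  want <- oracle_summary(study$records, window = cfg$peak_window_days)
  got <- got[order(got$subject_id), ]
  want <- want[order(want$subject_id), ]
  expect_equal(got$subject_id, want$subject_id)
  for (col in setdiff(names(want), "subject_id")) {
    expect_equal(got[[col]], unname(want[[col]]), tolerance = 0,
                 label = paste0("summary column ", col))
  }
}

acceptance_mix <- c(hys_law = 3, temples = 5, hyperbili = 5,
                    cholestatic = 10, mixed = 10, normal = 167)

# Pipeline-vs-truth phenotype recovery: fraction of subjects whose quadrant
# and injury pattern both match the simulator's designed labels.
recovery_rate <- function(sim, cfg = edish_config()) {
  summ <- classify_subjects(subject_summary(sim$study, cfg), cfg)
  m <- merge(summ[, c("subject_id", "quadrant", "injury_pattern")],
             sim$truth, by = "subject_id")
  mean(m$quadrant.x == m$quadrant.y &
         m$injury_pattern.x == m$injury_pattern.y)
}

extract_report_payload <- function(path) {
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(html, regexpr("const EDISH = \\{.*?\\};\n", html))
  json <- sub("^const EDISH = ", "", sub(";\n$", "", m))
  jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
}
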