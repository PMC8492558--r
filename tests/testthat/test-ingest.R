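test_that("dialect detection recognises the SDTM and ADaM signatures", {
  sdtm <- data.frame(USUBJID = "S1", LBTESTCD = "ALT", LBSTRESN = 50,
                     LBSTNRHI = 40, LBDY = 8)
  adam <- data.frame(USUBJID = "S1", PARAMCD = "ALT", AVAL = 50,
                     ANRHI = 40, ADY = 8)
  expect_identical(detect_dialect(sdtm), "sdtm")
  expect_identical(detect_dialect(adam), "adam")
  expect_identical(detect_dialect(data.frame(id = "S1", test = "ALT",
                                             result = 50)), "unknown")
  # A1HI is an accepted reference-range variable
  adam2 <- adam; names(adam2)[4] <- "A1HI"
  expect_identical(detect_dialect(adam2), "adam")
  # both signatures present: analysis-ready data wins, tie is logged
  both <- cbind(sdtm, adam[, -1])
  expect_message(expect_identical(detect_dialect(both), "adam"), "ADaM")
  expect_error(detect_dialect(sdtm[0, ]), "empty input")
})

test_that("normalization maps rows one-to-one and counts exclusions", {
  raw <- data.frame(
    USUBJID = c("S01", "S01", "S01", "S01"),
    LBTESTCD = c("ALT", "BILI", "XXX", "ALT"),
    LBSTRESN = c("120", "2.4", "50", "NQ"),
    LBSTNRHI = c(40, 1.2, 40, 40),
    LBDY = c(8, 8, 8, 15))
  study <- normalize_labs(raw)
  expect_s3_class(study, "edish_study")
  expect_equal(nrow(study$records), 2L)
  alt <- study$records[study$records$analyte == "ALT", ]
  expect_equal(alt$value, 120)
  expect_equal(alt$uln, 40)
  expect_equal(alt$study_day, 8L)
  # BILI maps to canonical TB via the dictionary
  expect_true("TB" %in% study$records$analyte)
  excl <- study$validation$exclusions
  expect_equal(excl$n[excl$reason == "unmappable analyte code"], 1L)
  expect_equal(excl$n[excl$reason == "non-numeric or negative result"], 1L)
  # exclusion accounting: rows in = records + excluded (no dups here)
  expect_equal(study$validation$n_rows_in,
               study$validation$n_records + study$validation$n_excluded)
})

test_that("duplicate (subject, analyte, day) rows collapse per policy", {
  raw <- data.frame(USUBJID = "S01",
                    LBTESTCD = c("ALT", "ALT", "ALT", "TBILI"),
                    LBSTRESN = c(100, 110, 30, 2.5),
                    LBSTNRHI = 40, LBDY = c(8, 8, 1, 8))
  raw$LBSTNRHI <- c(40, 40, 40, 1.2)
  for (policy in c("max", "first", "mean")) {
    study <- normalize_labs(raw, dedup = policy)
    alt8 <- study$records[study$records$analyte == "ALT" &
                            study$records$study_day == 8L, ]
    expect_equal(nrow(alt8), 1L)
    expect_equal(alt8$value,
                 switch(policy, max = 110, first = 100, mean = 105))
    expect_equal(study$validation$n_dedup_collapsed, 1L)
  }
})

test_that("normalization errors are specific", {
  raw <- data.frame(USUBJID = "S01", LBTESTCD = "ALT", LBSTRESN = 120,
                    LBSTNRHI = 40, LBDY = 8)
  bad_map <- mapping_config("USUBJID", "LBTESTCD", "RESULT_MISSING",
                            "LBSTNRHI", "LBDY")
  expect_error(normalize_labs(raw, mapping = bad_map), "result_value")
  expect_error(mapping_config("USUBJID", "LBTESTCD", NULL, "LBSTNRHI",
                              "LBDY"), "result_value")
  # no TB anywhere -> zero evaluable subjects
  expect_error(normalize_labs(raw), "zero evaluable")
  expect_error(normalize_labs(data.frame(id = 1, test = "a", result = 2)),
               "mapping")
})

test_that("missing ULN falls back to the study-level value or is excluded", {
  raw <- data.frame(USUBJID = "S01", LBTESTCD = c("ALT", "ALT", "TBILI"),
                    LBSTRESN = c(120, 80, 2.5), LBSTNRHI = c(NA, NA, 1.2),
                    LBDY = c(8, 15, 8))
  study <- normalize_labs(raw, study_uln = c(ALT = 40))
  expect_equal(sort(study$records$uln), c(1.2, 40, 40))
  expect_equal(study$validation$n_uln_fallback, 2L)
  raw2 <- raw
  raw2$LBSTNRHI <- c(NA, 40, 1.2)
  study2 <- normalize_labs(raw2)
  excl <- study2$validation$exclusions
  expect_equal(excl$n[excl$reason == "missing or non-positive ULN"], 1L)
})

test_that("day-0 records are excluded and a >2x ULN spread warns", {
  raw <- data.frame(USUBJID = "S01",
                    LBTESTCD = c("ALT", "ALT", "ALT", "TBILI"),
                    LBSTRESN = c(120, 50, 60, 2.5),
                    LBSTNRHI = c(40, 100, 40, 1.2),
                    LBDY = c(8, 15, 0, 8))
  expect_warning(study <- normalize_labs(raw), "ULN varies")
  excl <- study$validation$exclusions
  expect_equal(excl$n[excl$reason == "missing or day-0 study day"], 1L)
})

test_that("validation report is pure and accounts for every subject", {
  raw <- data.frame(
    USUBJID = c("S01", "S01", "S02"),
    LBTESTCD = c("ALT", "TBILI", "ALT"),
    LBSTRESN = c(120, 2.5, 80), LBSTNRHI = c(40, 1.2, 40),
    LBDY = c(8, 15, 8))
  study <- normalize_labs(raw)
  before <- study$records
  rep <- validate_study(study)
  expect_identical(study$records, before)
  expect_equal(rep$n_subjects, 2L)
  expect_equal(rep$n_evaluable, 1L)
  expect_equal(nrow(rep$non_evaluable) + rep$n_evaluable, rep$n_subjects)
  expect_match(rep$non_evaluable$reason, "no post-baseline TB")
})

test_that("every default-generator subject is evaluable (direct scan)", {
  sim <- simulate_study(sim_spec(n_subjects = 100, seed = 11))
  rep <- validate_study(sim$study)
  # independent scan over raw records
  rec <- sim$study$records
  post <- rec[rec$study_day > 1, ]
  n_scan <- length(intersect(post$subject_id[post$analyte == "ALT"],
                             post$subject_id[post$analyte == "TB"]))
  expect_equal(rep$n_evaluable, 100L)
  expect_equal(rep$n_evaluable, n_scan)
})

test_that("dialect writers round-trip and normalization is idempotent", {
  sim <- simulate_study(sim_spec(n_subjects = 12, seed = 21))
  f_sdtm <- withr::local_tempfile(fileext = ".csv")
  f_adam <- withr::local_tempfile(fileext = ".csv")
  write_dialect(sim$study, "sdtm", f_sdtm)
  write_dialect(sim$study, "adam", f_adam)
  s1 <- normalize_labs(read_lab_table(f_sdtm))
  s2 <- normalize_labs(read_lab_table(f_adam))
  expect_identical(s1$records, s2$records)
  expect_identical(
    as.data.frame(s1$records),
    as.data.frame(dplyr::arrange(sim$study$records, subject_id, analyte,
                                 study_day)))
  # normalize(write(normalize(x))) = normalize(x)
  f_again <- withr::local_tempfile(fileext = ".csv")
  write_dialect(s1, "sdtm", f_again)
  s3 <- normalize_labs(read_lab_table(f_again))
  expect_identical(s3$records, s1$records)
})
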