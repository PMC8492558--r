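one_subject_study <- function() {
  make_study(data.frame(
    subject_id = "S01",
    analyte = c("ALT", "TB", "ALP", "ALT", "TB", "ALP"),
    value = c(30, 0.6, 100, 140, 2.6, 130),
    uln = c(40, 1.2, 120, 40, 1.2, 120),
    study_day = c(1, 1, 1, 8, 8, 8)))
}

test_that("eDISH figure places points and thresholds per configuration", {
  study <- one_subject_study()
  cfg <- edish_config()
  summ <- classify_subjects(subject_summary(study, cfg), cfg)
  fig <- build_edish(summ, cfg)
  expect_equal(nrow(fig$points), 1L)
  expect_equal(fig$points$x, fold_uln(140, 40))
  expect_equal(fig$points$y, fold_uln(2.6, 1.2))
  expect_equal(fig$thresholds, list(x = 3, y = 2))
  # fold-baseline mode swaps the coordinates, not the classification
  cfg_bl <- edish_config(x_axis_mode = "fold_baseline")
  fig_bl <- build_edish(classify_subjects(summ, cfg_bl), cfg_bl)
  expect_equal(fig_bl$points$x, fold_baseline(140, 30))
  expect_equal(fig_bl$points$quadrant, fig$points$quadrant)
  # zero evaluable subjects is an error carrying the validation context
  none <- summ
  none$evaluable <- FALSE
  expect_error(build_edish(none, cfg), "zero evaluable")
})

test_that("point sizes increase with the chosen measure", {
  sim <- simulate_study(sim_spec(
    n_subjects = 3, phenotype_mix = c(normal = 1, cholestatic = 1, mixed = 1),
    noise_sd = 0, seed = 2))
  cfg <- edish_config(point_size_measure = "alp_fold")
  summ <- classify_subjects(subject_summary(sim$study, cfg), cfg)
  fig <- build_edish(summ, cfg)
  ord <- order(summ$alp_peak_fold)
  expect_true(all(diff(fig$points$size[ord]) > 0))
  fig_none <- build_edish(summ, edish_config())
  expect_equal(length(unique(fig_none$points$size)), 1L)
})

test_that("participant profiles carry all analyte series and the R series", {
  sim <- simulate_study(sim_spec(n_subjects = 4, seed = 6))
  study <- sim$study
  id <- evaluable_subjects(study)[1]
  prof <- build_profile(study, id)
  expect_named(prof$series, c("ALT", "AST", "ALP", "TB"))
  rec <- study$records[study$records$subject_id == id, ]
  for (an in names(prof$series)) {
    s <- prof$series[[an]]
    sub <- rec[rec$analyte == an, ]
    sub <- sub[order(sub$study_day), ]
    expect_equal(s$study_day, sub$study_day)
    expect_equal(s$fold_uln, fold_uln(sub$value, sub$uln))
    expect_true(all(diff(s$study_day) > 0))
  }
  expect_gt(nrow(prof$r_series), 0)
  # a subject with no AST yields an empty, labeled AST series
  df <- data.frame(subject_id = "X", analyte = c("ALT", "TB"),
                   value = c(120, 2.5), uln = c(40, 1.2), study_day = 8)
  prof2 <- build_profile(make_study(df), "X")
  expect_equal(nrow(prof2$series$AST), 0L)
  expect_equal(nrow(prof2$series$ALT), 1L)
  expect_error(build_profile(study, "NOPE"), "unknown subject")
})

test_that("hysteresis frames are prefixes ending in the full path", {
  sim <- simulate_study(sim_spec(n_subjects = 2, seed = 9))
  id <- evaluable_subjects(sim$study)[1]
  h <- build_hysteresis(sim$study, id)
  expect_equal(length(h$frames), nrow(h$path))
  for (k in seq_along(h$frames)) {
    expect_identical(h$frames[[k]], h$path[seq_len(k), ])
    if (k > 1) {
      expect_identical(h$frames[[k]][seq_len(k - 1), ], h$frames[[k - 1]])
    }
  }
  expect_identical(h$frames[[length(h$frames)]], h$path)
  # degenerate single-observation path
  df <- data.frame(subject_id = "X", analyte = c("ALT", "TB"),
                   value = c(120, 2.5), uln = c(40, 1.2),
                   study_day = c(8, 8))
  h1 <- build_hysteresis(make_study(df), "X")
  expect_equal(length(h1$frames), 1L)
})

test_that("exported report is self-contained, complete and deterministic", {
  sim <- simulate_study(sim_spec(n_subjects = 15, seed = 12))
  cfg <- edish_config()
  summ <- classify_subjects(subject_summary(sim$study, cfg), cfg)
  fig <- build_edish(summ, cfg, sim$study$subjects)
  ids <- evaluable_subjects(sim$study)
  profiles <- lapply(setNames(nm = ids), build_profile, study = sim$study)
  paths <- lapply(setNames(nm = ids), hysteresis_path, study = sim$study)
  f1 <- withr::local_tempfile(fileext = ".html")
  f2 <- withr::local_tempfile(fileext = ".html")
  export_html(fig, profiles, cfg, f1, paths = paths,
              validation = validate_study(sim$study))
  export_html(fig, profiles, cfg, f2, paths = paths,
              validation = validate_study(sim$study))
  html <- readLines(f1, warn = FALSE)
  expect_false(any(grepl("http://|https://", html)))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  payload <- extract_report_payload(f1)
  expect_equal(nrow(payload$points), length(ids))
  expect_equal(length(payload$profiles), length(ids))
  # filter controls derived from subject attributes
  expect_true("arm" %in% names(payload$filters))
})

test_that("tooltip strings are formatted from the summary table values", {
  sim <- simulate_study(sim_spec(n_subjects = 10, seed = 14))
  cfg <- edish_config()
  summ <- classify_subjects(subject_summary(sim$study, cfg), cfg)
  fig <- build_edish(summ, cfg)
  f <- withr::local_tempfile(fileext = ".html")
  export_html(fig, cfg = cfg, path = f)
  tips <- extract_report_payload(f)$tips
  fmt <- function(x) vapply(x, function(v) {
    if (is.na(v)) "n/a"
    else format(signif(v, 4), trim = TRUE, scientific = FALSE)
  }, character(1))
  m <- match(tips$subject, summ$subject_id)
  expect_equal(tips$peak_alt_fold, unname(fmt(summ$alt_peak_fold[m])))
  expect_equal(tips$peak_tb_fold, unname(fmt(summ$tb_peak_fold[m])))
  expect_equal(tips$p_alt_percent, unname(fmt(summ$p_alt_percent[m])))
  expect_equal(tips$quadrant, summ$quadrant[m])
})
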