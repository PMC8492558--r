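test_that("fold computations follow their definitions", {
  expect_equal(fold_uln(120, 40), 3)
  expect_equal(fold_uln(40, 40), 1)
  expect_equal(fold_uln(0, 40), 0)
  expect_error(fold_uln(10, 0), "uln")
  expect_error(fold_uln(-1, 40), "value")
  expect_equal(fold_baseline(90, 30), 3)
  expect_equal(fold_baseline(30, 30), 1)
  expect_true(is.na(fold_baseline(90, 0)))
  expect_true(is.na(fold_baseline(90, NA)))
})

test_that("per-visit R and nR ratios pair same-day folds", {
  df <- data.frame(
    subject_id = "S01",
    analyte = c("ALT", "TB", "ALT", "AST", "ALP", "TB", "ALT", "TB"),
    value = c(30, 0.6, 120, 80, 150, 0.6, 100, 0.7),
    uln = c(40, 1.2, 40, 40, 120, 1.2, 40, 1.2),
    study_day = c(1, 1, 8, 8, 8, 8, 15, 15))
  vis <- compute_visit_derived(make_study(df))
  d8 <- vis[vis$study_day == 8, ]
  expect_equal(d8$alt_fold_uln, 3)
  expect_equal(d8$r_ratio, 3 / 1.25)      # 2.4
  expect_equal(d8$nr_ratio, 3 / 1.25)     # AST fold 2 < ALT fold 3
  d15 <- vis[vis$study_day == 15, ]       # no same-day ALP
  expect_true(is.na(d15$r_ratio) && is.na(d15$nr_ratio))
  # nR numerator is max(ALT, AST)
  df2 <- df
  df2$value[df2$analyte == "AST"] <- 160  # AST fold 4 > ALT fold 3
  vis2 <- compute_visit_derived(make_study(df2))
  expect_equal(vis2$nr_ratio[vis2$study_day == 8], 4 / 1.25) # 3.2
  # fold-baseline columns come from the day <= 1 baseline
  expect_equal(d8$alt_fold_bl, 120 / 30)
})

test_that("nR equals R whenever the AST fold does not exceed the ALT fold", {
  sim <- simulate_study(sim_spec(n_subjects = 40, seed = 5))
  vis <- compute_visit_derived(sim$study)
  sel <- !is.na(vis$r_ratio) & !is.na(vis$ast_fold_uln) &
    vis$ast_fold_uln <= vis$alt_fold_uln
  expect_true(sum(sel) > 0)
  expect_identical(vis$nr_ratio[sel], vis$r_ratio[sel])
})

test_that("subject summary derives baselines, peaks and separation", {
  df <- data.frame(
    subject_id = "S01",
    analyte = c("ALT", "ALT", "ALT", "TB", "TB", "TB"),
    value = c(30, 120, 120, 0.6, 1.0, 3.0),
    uln = c(40, 40, 40, 1.2, 1.2, 1.2),
    study_day = c(-3, 8, 15, -3, 8, 22))
  summ <- subject_summary(make_study(df))
  expect_equal(summ$alt_baseline, 30)
  expect_equal(summ$alt_peak_value, 120)
  expect_equal(summ$alt_peak_day, 8)  # tie at days 8 and 15 -> earliest
  expect_equal(summ$tb_peak_day, 22)
  expect_equal(summ$peak_time_separation_days, 14)
  expect_true(summ$within_window)     # 14 <= default 30
  expect_true(summ$evaluable)
  cfg7 <- edish_config(peak_window_days = 7)
  expect_false(subject_summary(make_study(df), cfg7)$within_window)
})

test_that("subjects without post-baseline ALT or TB are kept, not dropped", {
  df <- data.frame(
    subject_id = c("S01", "S01", "S02", "S02"),
    analyte = c("ALT", "TB", "ALT", "TB"),
    value = c(120, 2.5, 80, 1.0),
    uln = c(40, 1.2, 40, 1.2),
    study_day = c(8, 8, 8, 1))  # S02 has no post-baseline TB
  summ <- subject_summary(make_study(df))
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$evaluable, c(TRUE, FALSE))
})

test_that("subject summary equals the brute-force full-scan oracle", {
  for (seed in 1:4) {
    expect_summary_matches_oracle(random_study(sample(5:30, 1), seed))
  }
  sim <- simulate_study(sim_spec(n_subjects = 50, seed = 99))
  expect_summary_matches_oracle(sim$study)
})

test_that("P_ALT is a clipped, monotone mass-balance estimate", {
  expect_equal(p_alt(100, 100), 0)
  expect_equal(p_alt(50, 100), 0)
  expect_equal(p_alt(1e9, 20), 100)
  # hand-computed: 100 * (500 - 20) * 3 / 30000 = 4.8
  expect_equal(p_alt(500, 20), 4.8)
  # configurable constants: 100 * 480 * 2 / 60000 = 1.6
  expect_equal(p_alt(500, 20, p_alt_constants(2, 60000)), 1.6)
  peaks <- seq(0, 20000, by = 50)
  vals <- p_alt(peaks, 30)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 100))
  expect_error(p_alt(-1, 0), "ALT")
})

test_that("injury pattern is a step function with breakpoints at 2 and 5", {
  expect_equal(injury_pattern(5), "hepatocellular")
  expect_equal(injury_pattern(2), "cholestatic")
  expect_equal(injury_pattern(3.7), "mixed")
  expect_equal(injury_pattern(NA), "indeterminate")
  grid <- seq(0.1, 8, by = 0.01)
  lab <- injury_pattern(grid)
  changes <- which(lab[-1] != lab[-length(lab)])
  expect_equal(length(changes), 2L)
  expect_equal(grid[changes + 1], c(2.01, 5.00), tolerance = 1e-9)
  # configurable breakpoints
  expect_equal(injury_pattern(3, hepatocellular_cut = 3), "hepatocellular")
})

test_that("hysteresis path carries missing analytes forward (LOCF)", {
  df <- data.frame(
    subject_id = "S01",
    analyte = c("ALT", "TB", "ALT", "TB", "ALT"),
    value = c(30, 0.6, 120, 2.4, 60),
    uln = c(40, 1.2, 40, 1.2, 40),
    study_day = c(1, 1, 8, 8, 15))
  study <- make_study(df)
  path <- hysteresis_path(study, "S01")
  expect_equal(path$study_day, c(1, 8, 15))
  expect_equal(path$tb_fold_uln, c(0.5, 2, 2))  # day 15 TB carried from day 8
  # path starts only once both analytes have been observed
  df2 <- df[df$analyte != "TB" | df$study_day > 1, ]
  path2 <- hysteresis_path(make_study(df2), "S01")
  expect_equal(path2$study_day, c(8, 15))
  expect_error(hysteresis_path(study, "NOPE"), "unknown subject")
})

test_that("hysteresis path equals the brute-force merge oracle", {
  sim <- simulate_study(sim_spec(n_subjects = 6, seed = 31))
  st <- random_study(10, seed = 17)
  for (study in list(sim$study, st)) {
    for (id in evaluable_subjects(study)) {
      got <- as.data.frame(hysteresis_path(study, id))
      want <- oracle_hysteresis(study$records, id)
      expect_equal(got, want, ignore_attr = TRUE)
      expect_true(all(diff(got$study_day) > 0))
    }
  }
})

test_that("derived outputs are invariant under unit rescaling", {
  sim <- simulate_study(sim_spec(n_subjects = 25, seed = 13))
  study <- sim$study
  scaled <- study
  scaled$records$value <- scaled$records$value * 7.3
  scaled$records$uln <- scaled$records$uln * 7.3
  cfg <- edish_config()
  expect_identical(compute_visit_derived(study, cfg),
                   compute_visit_derived(scaled, cfg))
  a <- classify_subjects(subject_summary(study, cfg), cfg)
  b <- classify_subjects(subject_summary(scaled, cfg), cfg)
  fold_cols <- c("alt_peak_fold", "ast_peak_fold", "alp_peak_fold",
                 "tb_peak_fold", "alt_peak_fold_bl", "tb_peak_fold_bl",
                 "alt_peak_day", "tb_peak_day", "peak_time_separation_days",
                 "within_window", "r_value", "nr_value", "r_peak", "nr_peak",
                 "injury_pattern", "quadrant")
  expect_identical(a[fold_cols], b[fold_cols])
})

test_that("peak-basis ratios use peak folds from possibly different days", {
  df <- data.frame(
    subject_id = "S01",
    analyte = c("ALT", "ALP", "TB", "ALT", "ALP", "TB"),
    value = c(200, 120, 0.6, 80, 360, 0.6),
    uln = c(40, 120, 1.2, 40, 120, 1.2),
    study_day = c(8, 8, 8, 15, 15, 15))
  study <- make_study(df)
  cfg_visit <- edish_config(ratio_basis = "visit")
  cfg_peak <- edish_config(ratio_basis = "peak")
  s_visit <- subject_summary(study, cfg_visit)
  s_peak <- subject_summary(study, cfg_peak)
  expect_equal(s_visit$r_value, 5)          # same-day at ALT peak: 5 / 1
  # peak ALT fold 5, peak ALP fold 3, quantized at 7 significant digits
  expect_equal(s_peak$r_value, signif(5 / 3, 7))
})
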