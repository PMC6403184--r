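# per-trial source band power (pre-mixing) during MI vs. baseline windows
source_power_by_trial <- function(rec, cfg) {
  fs <- cfg$fs
  wins <- attr(rec, "mi_windows")
  classes <- attr(rec, "trial_classes")
  src <- attr(rec, "sources")
  t(vapply(seq_len(nrow(wins)), function(i) {
    s <- if (classes[i] == "right") 1 else 2  # contralateral source
    mi <- (wins[i, 1] + 1):wins[i, 2]
    base <- (wins[i, 1] - 7 * fs + 1):(wins[i, 1] - 3 * fs)
    c(mi = mean(src[s, mi]^2), base = mean(src[s, base]^2))
  }, c(mi = 0, base = 0)))
}

test_that("EEG generator is deterministic and validates its config", {
  cfg <- eeg_sim_config(n_channels = 6, n_trials_per_class = 4, seed = 42)
  a <- generate_eeg_session(cfg)
  b <- generate_eeg_session(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$events, b$events)
  expect_error(eeg_sim_config(erd_depth = 1), "erd_depth")
  expect_error(eeg_sim_config(erd_depth = -0.1), "erd_depth")
  expect_error(eeg_sim_config(fs = 50), "fs")
})

test_that("zero ERD leaves MI-window source power indistinguishable from baseline", {
  cfg <- eeg_sim_config(n_channels = 6, erd_depth = 0, seed = 11)
  rec <- generate_eeg_session(cfg)
  pw <- source_power_by_trial(rec, cfg)
  tt <- t.test(log(pw[, "mi"]), log(pw[, "base"]))
  expect_gt(tt$p.value, 0.01)
})

test_that("ERD of 0.5 suppresses the contralateral source in nearly every trial", {
  cfg <- eeg_sim_config(n_channels = 6, erd_depth = 0.5, snr = 2, seed = 7)
  rec <- generate_eeg_session(cfg)
  pw <- source_power_by_trial(rec, cfg)
  expect_gt(mean(pw[, "mi"] < pw[, "base"]), 0.95)
})

test_that("cohort generator is deterministic and rejects bad configs", {
  cfg <- cohort_sim_config(n_subjects = 10, seed = 9)
  expect_identical(generate_fa_cohort(cfg), generate_fa_cohort(cfg))
  expect_error(cohort_sim_config(informative_regions = c(nowhere = 1)),
               "not in region_names")
  expect_error(cohort_sim_config(age_fa_corr = list(region = "Column and body of fornix",
                                                    r = 1.2)), "< 1")
  expect_error(generate_fa_cohort(cohort_sim_config(
    informative_regions = c("Tapetum L" = 5))), "too large")
})

test_that("null cohorts keep every region-label correlation small", {
  ok <- vapply(1:200, function(s) {
    ch <- generate_fa_cohort(cohort_sim_config(n_subjects = 200, seed = s))
    y <- as.integer(ch$label == "high")
    regions <- attr(ch, "region_names")
    cors <- vapply(regions, function(r) abs(cor(ch[[r]], y)), 0)
    all(cors < 0.3)
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("an informative region dominates the t-score ranking", {
  info <- c("Genu of corpus callosum" = 2)
  hit <- vapply(1:100, function(s) {
    ch <- generate_fa_cohort(cohort_sim_config(
      n_subjects = 200, informative_regions = info, seed = 5000 + s))
    regions <- attr(ch, "region_names")
    tt <- vapply(regions, function(r) {
      abs(t.test(ch[[r]] ~ ch$label)$statistic)
    }, 0)
    names(which.max(tt)) == "Genu of corpus callosum"
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("a 21-subject cohort splits 11 low / 10 high", {
  ch <- generate_fa_cohort(cohort_sim_config(n_subjects = 21, seed = 2))
  expect_equal(as.vector(table(ch$label)), c(11, 10))
  expect_equal(ncol(ch[, attr(ch, "region_names")]), 48)
  expect_true(all(ch[, attr(ch, "region_names")] > 0 &
                    ch[, attr(ch, "region_names")] < 1))
})

test_that("realized effect sizes converge to the configured d at large n", {
  info <- c("Genu of corpus callosum" = 1.2, "Tapetum L" = -0.8)
  ch <- generate_fa_cohort(cohort_sim_config(
    n_subjects = 2000, informative_regions = info, seed = 31))
  d_of <- function(col) {
    g <- split(ch[[col]], ch$label)
    (mean(g$high) - mean(g$low)) / sqrt((var(g$high) + var(g$low)) / 2)
  }
  expect_equal(d_of("Genu of corpus callosum"), 1.2, tolerance = 0.1)
  expect_equal(d_of("Tapetum L"), -0.8, tolerance = 0.1)
})

test_that("the age-fornix correlation lands near its target", {
  cors <- vapply(1:10, function(s) {
    ch <- generate_fa_cohort(cohort_sim_config(n_subjects = 150, seed = 600 + s))
    cor(ch$age, ch[["Column and body of fornix"]])
  }, 0)
  expect_true(all(abs(cors - (-0.49)) < 0.25))
  expect_lt(abs(mean(cors) - (-0.49)), 0.1)
})

test_that("volume fixtures honor labels, determinism and overlap rejection", {
  regions <- list(list(label = 1L, from = c(1, 1, 1), to = c(3, 3, 3), fa = 0.4))
  v <- generate_fa_volume_fixture(c(3, 3, 3), regions, seed = 1)
  expect_equal(unname(region_mean_fa(v$fa, v$labels)["1"]), 0.4)

  r2 <- list(list(label = 2L, from = c(1, 1, 1), to = c(3, 1, 1),
                  fa = c(0.2, 0.3, 0.5)))
  v2 <- generate_fa_volume_fixture(c(4, 4, 4), r2, seed = 1)
  expect_equal(unname(region_mean_fa(v2$fa, v2$labels)["2"]), 0.4)

  big <- list(list(label = 1L, from = c(1, 1, 1), to = c(8, 8, 4)))
  a <- generate_fa_volume_fixture(c(16, 16, 8), big, seed = 5)
  b <- generate_fa_volume_fixture(c(16, 16, 8), big, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$fa >= 0 & a$fa <= 1))
  expect_true(any(a$fa <= 0.25))

  overlap <- list(list(label = 1L, from = c(1, 1, 1), to = c(4, 4, 4)),
                  list(label = 2L, from = c(3, 3, 3), to = c(6, 6, 6)))
  expect_error(generate_fa_volume_fixture(c(8, 8, 8), overlap), "overlapping")
  expect_error(generate_fa_volume_fixture(c(40, 8, 8), big), "capped")
  bad <- list(list(label = -1L, from = c(1, 1, 1), to = c(2, 2, 2)))
  expect_error(generate_fa_volume_fixture(c(8, 8, 8), bad), "positive")
})

test_that("EDF round-trip preserves signal within quantization and events exactly", {
  cfg <- eeg_sim_config(n_channels = 4, n_trials_per_class = 2, seed = 3)
  rec <- generate_eeg_session(cfg)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, rec$fs)
  n <- ncol(back$signal)
  rng <- max(rec$signal) - min(rec$signal)
  expect_lt(max(abs(back$signal - rec$signal[, seq_len(n)])), rng / 65000 * 2)
  expect_equal(back$events, rec$events)
  unlink(path)
})
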