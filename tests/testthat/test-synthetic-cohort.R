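test_that("identical configuration reproduces a bit-identical cohort, different seeds differ", {
  cfg <- small_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  d <- simulate_cohort(small_config(seed = 102L))
  expect_false(identical(a$startle_trials$cmd_mm, d$startle_trials$cmd_mm))
  expect_false(identical(a$abr_thresholds$threshold_db,
                         d$abr_thresholds$threshold_db))
})

test_that("every subject has every epoch and thresholds are 5 dB multiples in [0, 80]", {
  co <- simulate_cohort(small_config())
  cfg <- co$config
  grid <- table(co$abr_thresholds$subject_id, co$abr_thresholds$epoch)
  expect_true(all(grid == 2 * length(cfg$abr_freqs_khz)))  # both ears
  thr <- co$abr_thresholds$threshold_db
  expect_true(all(thr %% 5 == 0))
  expect_true(all(thr >= 0 & thr <= 80))
  io_epochs <- unique(co$startle_trials[co$startle_trials$trial_type == "IO",
                                        c("subject_id", "epoch")])
  expect_equal(nrow(io_epochs), nrow(co$subjects) * length(cfg$epochs))
})

test_that("session scheduling honors the protocol counts across random configurations", {
  set.seed(11)
  for (r in 1:25) {
    nlev <- sample(3:9, 1)
    ncar <- sample(2:5, 1)
    carriers <- sort(sample(c(4, 8, 12.5, 16, 20, 24), ncar))
    cfg <- cohort_config(
      io_levels_db = seq(60, by = 5, length.out = nlev),
      io_reps_per_level = sample(3:15, 1),
      gpias_carriers_khz = carriers,
      tinnitus_freqs = carriers[ncar],
      gpias_blocks = ncar * sample(2:4, 1),
      gpias_trials_per_block = 2 * sample(2:5, 1),
      seed = r)
    s <- one_subject()
    io <- simulate_io_session(s, "w2", cfg)
    expect_equal(nrow(io), nlev * cfg$io_reps_per_level)
    expect_true(all(table(io$level_db) == cfg$io_reps_per_level))
    gp <- simulate_gpias_day(s, "w2", cfg)
    for (sess in seq_len(cfg$gpias_sessions_per_day)) {
      g <- gp[gp$day_session == sess, ]
      expect_equal(nrow(g), cfg$gpias_blocks * cfg$gpias_trials_per_block)
      blocks_per_carrier <- table(unique(g[, c("block", "carrier_khz")])$carrier_khz)
      expect_true(all(blocks_per_carrier == cfg$gpias_blocks / ncar))
      expect_true(all(table(g$carrier_khz, g$trial_type) ==
                        cfg$gpias_blocks / ncar * cfg$gpias_trials_per_block / 2))
    }
    expect_equal(sum(gp$trial_type == "SILENCE"), cfg$habituation_startles)
  }
})

test_that("null cohorts are exchangeable between dosing groups", {
  co <- simulate_cohort(null_config(seed = 7))
  io <- co$startle_trials[co$startle_trials$trial_type == "IO" &
                            co$startle_trials$epoch == "w2", ]
  ks <- suppressWarnings(
    stats::ks.test(io$cmd_mm[io$group == "control"],
                   io$cmd_mm[io$group == "vehicle"]))
  expect_gt(ks$p.value, 0.001)
  thr <- co$abr_thresholds[co$abr_thresholds$epoch == "w6", ]
  ks2 <- suppressWarnings(
    stats::ks.test(thr$threshold_db[thr$group == "control"],
                   thr$threshold_db[thr$group == "vehicle"]))
  expect_gt(ks2$p.value, 0.001)
})

test_that("noise-free thresholds follow the 5 dB rounding rule (ties away from zero)", {
  cfg <- cohort_config(baseline_threshold_mean = 30, baseline_threshold_sd = 0,
                       shift_sd = 0, seed = 1)
  thr <- simulate_abr_thresholds(one_subject(), cfg)
  expect_true(all(thr$threshold_db[thr$epoch == "baseline"] == 30))
  # planted 12.5 dB at 16 kHz at w2: 42.5 rounds up to 45
  expect_equal(unique(thr$threshold_db[thr$epoch == "w2" & thr$freq_khz == 16]), 45)
  expect_equal(unique(thr$threshold_db[thr$epoch == "w18" & thr$freq_khz == 16]), 30)
})

test_that("mean planted 16 kHz shift at week 2 lies in the 10-15 dB band", {
  cfg <- cohort_config(seed = 5)
  shifts <- replicate(400, NA_real_)
  for (i in 1:400) {
    thr <- simulate_abr_thresholds(one_subject(), cfg, seed = 1000 + i)
    base <- thr$threshold_db[thr$epoch == "baseline" & thr$freq_khz == 16]
    w2 <- thr$threshold_db[thr$epoch == "w2" & thr$freq_khz == 16]
    shifts[i] <- mean(w2 - base)
  }
  expect_gt(mean(shifts), 10)
  expect_lt(mean(shifts), 15)
})

test_that("habituation decays startle magnitude by the closed-form factor", {
  cfg <- cohort_config(habituation_rate = 0.9, trial_noise_cv = 0,
                       hyperacusis_prevalence = 0, seed = 3)
  s <- one_subject()
  base <- simulate_io_session(s, "baseline", cfg)
  w18 <- simulate_io_session(s, "w18", cfg)
  m0 <- tapply(base$cmd_mm, base$level_db, mean)
  m5 <- tapply(w18$cmd_mm, w18$level_db, mean)
  expect_equal(as.numeric(m5 / m0), rep(0.9^5, length(m0)), tolerance = 1e-12)
})

test_that("planted gap ratios are recovered by session-level estimates", {
  for (r_true in c(0.6, 0.9)) {
    cfg <- cohort_config(baseline_gap_ratio = r_true, habituation_rate = 1,
                         seed = 17)
    est <- numeric(400)
    for (i in 1:400) {
      gp <- simulate_gpias_day(one_subject(), "baseline", cfg, seed = 5000 + i)
      g1 <- gp[gp$day_session == 1, ]
      est[i] <- mean(compute_gap_ratios(g1)$ratio)
    }
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - r_true), 4 * se + 0.005)
  }
})

test_that("treated subjects draw phenotypes at the configured prevalence", {
  cfg <- cohort_config(n_control = 0, n_treated_vehicle = 400,
                       n_treated_ebselen = 0, seed = 21)
  co <- simulate_cohort(cfg)
  ph <- mean(co$subjects$true_hyperacusis)
  pt_ <- mean(co$subjects$true_tinnitus)
  expect_lt(abs(ph - 0.5), 1.96 * sqrt(0.25 / 400) + 1e-9)
  expect_lt(abs(pt_ - 0.36), 1.96 * sqrt(0.36 * 0.64 / 400) + 1e-9)
  expect_true(all(co$subjects$tinnitus_freq_khz[co$subjects$true_tinnitus]
                  %in% cfg$tinnitus_freqs))
  # controls never carry planted effects
  co2 <- simulate_cohort(small_config())
  ctrl <- co2$subjects[co2$subjects$group == "control", ]
  expect_false(any(ctrl$true_hyperacusis | ctrl$true_tinnitus))
})

test_that("simulated force waveforms round-trip through force_to_cmd", {
  tr <- simulate_force_waveform(2.5, is_startle = TRUE)
  expect_equal(force_to_cmd(tr, 25, 1000), 2.5, tolerance = 0.01)
  tr2 <- simulate_force_waveform(5.0, is_startle = TRUE)
  expect_equal(force_to_cmd(tr2, 25, 1000) / force_to_cmd(tr, 25, 1000), 2,
               tolerance = 1e-9)
  tpl <- startle_template()
  expect_true(classify_trial(tr, tpl)$startle)
  ns <- simulate_force_waveform(2.5, is_startle = FALSE)
  expect_false(classify_trial(ns, tpl)$startle)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(n_control = -1), "n_control")
  expect_error(cohort_config(hyperacusis_prevalence = 1.2),
               "hyperacusis_prevalence")
  expect_error(cohort_config(habituation_rate = 0), "habituation_rate")
  expect_error(cohort_config(gpias_blocks = 7), "gpias_blocks")
  expect_error(cohort_config(baseline_gap_ratio = 1.2), "baseline_gap_ratio")
  expect_error(cohort_config(tinnitus_freqs = c(3)), "tinnitus_freqs")
})
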