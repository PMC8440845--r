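mk_io <- function(cmd_by_level, reps = 15, jitter = 0, seed = 1) {
  set.seed(seed)
  lv <- as.numeric(names(cmd_by_level))
  data.frame(level_db = rep(lv, each = reps),
             cmd_mm = rep(unlist(cmd_by_level), each = reps) +
               rnorm(length(lv) * reps, 0, jitter),
             valid = TRUE)
}

mk_ratios <- function(means, sessions = 3, sd = 0.005, seed = 1) {
  set.seed(seed)
  carriers <- as.numeric(names(means))
  data.frame(carrier_khz = rep(carriers, each = sessions),
             session = rep(seq_len(sessions), length(carriers)),
             ratio = rep(unlist(means), each = sessions) +
               rnorm(length(carriers) * sessions, 0, sd))
}

test_that("identical I/O sessions are never called hyperacusis", {
  io <- mk_io(list(`60` = 0.5, `80` = 2, `100` = 4))
  r <- hyperacusis_test(io, io)
  expect_equal(r$decision, "negative")
  expect_equal(r$statistic, 0)
})

test_that("the direction gate blocks habituation from being called hyperacusis", {
  base <- mk_io(list(`60` = 0.5, `80` = 2, `100` = 4), jitter = 0.2, seed = 2)
  faded <- base
  faded$cmd_mm <- faded$cmd_mm * 0.5   # strong, highly significant decrease
  r <- hyperacusis_test(base, faded)
  expect_equal(r$decision, "negative")
  expect_lt(r$p.value, 0.001)          # significant, but in the wrong direction
  # and a simulated habituating subject is never positive across epochs
  cfg <- cohort_config(habituation_rate = 0.8, hyperacusis_prevalence = 0,
                       tinnitus_prevalence = 0, seed = 51)
  s <- one_subject()
  trials <- do.call(rbind, lapply(cfg$epochs, function(e)
    simulate_io_session(s, e, cfg)))
  h <- classify_hyperacusis(trials, cfg$epochs)
  expect_false(any(h$calls$decision == "positive"))
})

test_that("epochs with fewer than two usable intensities are excluded", {
  io <- mk_io(list(`60` = 0.5, `80` = 2))
  one <- io[io$level_db == 60, ]
  expect_equal(hyperacusis_test(io, one)$decision, "excluded")
  expect_match(hyperacusis_test(one, io)$exclusion_reason, "intensities")
})

test_that("a planted 3x startle gain is detected in at least 95% of subjects", {
  cfg <- cohort_config(seed = 52)
  hits <- 0
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    s <- one_subject(hyper = TRUE)
    base <- simulate_io_session(s, "baseline", cfg, seed = 2 * i)
    w2 <- simulate_io_session(s, "w2", cfg, seed = 2 * i + 1)
    hits <- hits + (hyperacusis_test(base, w2)$decision == "positive")
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("tinnitus calls require a deficit at one or two adjacent carriers", {
  base <- mk_ratios(list(`4` = 0.6, `8` = 0.6, `12.5` = 0.6, `16` = 0.6,
                         `20` = 0.6))
  expect_equal(tinnitus_test(base, mk_ratios(list(`4` = 0.6, `8` = 0.6,
                                                  `12.5` = 0.6, `16` = 0.6,
                                                  `20` = 0.6), seed = 2))$decision,
               "negative")
  up <- function(at, delta = 0.35, seed = 3) {
    m <- list(`4` = 0.6, `8` = 0.6, `12.5` = 0.6, `16` = 0.6, `20` = 0.6)
    for (f in at) m[[f]] <- m[[f]] + delta
    mk_ratios(m, seed = seed)
  }
  r20 <- tinnitus_test(base, up("20"))
  expect_equal(r20$decision, "positive")
  expect_equal(r20$implicated_freqs, 20)

  r_adj <- tinnitus_test(base, up(c("16", "20")))
  expect_equal(r_adj$decision, "positive")
  expect_equal(r_adj$implicated_freqs, c(16, 20))

  expect_equal(tinnitus_test(base, up(c("4", "16")))$decision, "negative")
  expect_equal(tinnitus_test(base, up(c("4", "12.5", "20")))$decision,
               "negative")
  # a uniform ratio decrease (better inhibition) is never a deficit
  expect_equal(tinnitus_test(base, up(c("4", "8", "12.5", "16", "20"),
                                      delta = -0.3))$decision, "negative")
})

test_that("a planted one-carrier gap-ratio delta is recovered in >= 90% of subjects", {
  cfg <- cohort_config(seed = 53)
  hits <- 0
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    s <- one_subject(tin = TRUE, tin_freq = 20)
    base <- gap_ratio_table(simulate_gpias_day(s, "baseline", cfg, seed = 2 * i))
    w2 <- gap_ratio_table(simulate_gpias_day(s, "w2", cfg, seed = 2 * i + 1))
    r <- tinnitus_test(base, w2)
    hits <- hits + (r$decision == "positive" && 20 %in% r$implicated_freqs)
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("detection is monotone in the planted effect sizes", {
  n_rep <- 120
  det_h <- vapply(c(1, 1.06, 1.2), function(gain) {
    cfg <- cohort_config(hyperacusis_gain = max(gain, 1), seed = 54)
    hits <- 0
    for (i in seq_len(n_rep)) {
      s <- one_subject(hyper = TRUE)
      base <- simulate_io_session(s, "baseline", cfg, seed = 2 * i)
      w2 <- simulate_io_session(s, "w2", cfg, seed = 2 * i + 1)
      hits <- hits + (hyperacusis_test(base, w2)$decision == "positive")
    }
    hits / n_rep
  }, numeric(1))
  expect_true(all(diff(det_h) >= -0.06))  # nondecreasing up to Monte-Carlo noise
  expect_gt(det_h[3], det_h[1])

  det_t <- vapply(c(0, 0.12, 0.3), function(delta) {
    cfg <- cohort_config(tinnitus_ratio_delta = delta, seed = 55)
    hits <- 0
    for (i in seq_len(n_rep)) {
      s <- one_subject(tin = TRUE, tin_freq = 20)
      base <- gap_ratio_table(simulate_gpias_day(s, "baseline", cfg, seed = 2 * i))
      w2 <- gap_ratio_table(simulate_gpias_day(s, "w2", cfg, seed = 2 * i + 1))
      hits <- hits + (tinnitus_test(base, w2)$decision == "positive")
    }
    hits / n_rep
  }, numeric(1))
  expect_true(all(diff(det_t) >= -0.06))
  expect_gt(det_t[3], det_t[1])
})

test_that("baseline GPIAS inclusion applies the mean best-ratio criterion", {
  good <- data.frame(carrier_khz = c(4, 8, 12.5, 16, 20), best_ratio = 0.5)
  expect_true(gpias_inclusion(good)$include)
  bad <- data.frame(carrier_khz = c(4, 8, 12.5, 16, 20), best_ratio = 1.0)
  inc <- gpias_inclusion(bad)
  expect_false(inc$include)
  expect_match(inc$reason, "mean baseline")
  empty <- data.frame(carrier_khz = numeric(), best_ratio = numeric())
  expect_false(gpias_inclusion(empty)$include)
})

test_that("phenotype incidence reports percentages with retained denominators", {
  calls <- data.frame(subject_id = sprintf("S%02d", 1:27), epoch = "w2",
                      decision = c(rep("positive", 9), rep("negative", 16),
                                   rep("excluded", 2)))
  inc <- phenotype_incidence(calls)
  expect_equal(inc$positives, 9L)
  expect_equal(inc$n, 25L)
  expect_equal(inc$percent, 36.0)
  none <- data.frame(subject_id = "S1", epoch = "w2", decision = "excluded")
  expect_true(is.na(phenotype_incidence(none)$percent))
})

test_that("overall phenotype calls equal the union of per-epoch positives", {
  cfg <- small_config()
  co <- simulate_cohort(cfg)
  h <- classify_hyperacusis(co$startle_trials, cfg$epochs)
  for (sid in h$overall$subject_id) {
    per_epoch <- h$calls$decision[h$calls$subject_id == sid]
    expect_identical(unname(h$overall$positive[h$overall$subject_id == sid]),
                     any(per_epoch == "positive"))
  }
  tt <- classify_tinnitus(co$startle_trials, cfg$epochs)
  for (sid in unique(tt$calls$subject_id)) {
    per_epoch <- tt$calls$decision[tt$calls$subject_id == sid]
    expect_identical(unname(tt$overall$positive[tt$overall$subject_id == sid]),
                     any(per_epoch == "positive"))
  }
})
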