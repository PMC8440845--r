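test_that("template matching is exact on self-matches and invariant to scale and offset", {
  tpl <- startle_template()
  trace <- c(rep(0, 40), tpl$samples, rep(0, 60))
  r <- classify_trial(trace, tpl)
  expect_equal(r$score, 1, tolerance = 1e-9)
  expect_true(r$startle)
  r2 <- classify_trial(7.3 * trace + 2.1, tpl)
  expect_equal(r2$score, r$score, tolerance = 1e-9)
  expect_equal(classify_trial(rep(0, 300), tpl)$score, 0)
  expect_false(classify_trial(rep(4.2, 300), tpl)$startle)
})

test_that("template matching rejects short or non-finite traces", {
  tpl <- startle_template()
  expect_error(classify_trial(rep(0, 10), tpl), "shorter")
  expect_error(classify_trial(c(rep(0, 200), NA), tpl), "non-finite")
})

test_that("template-matching scores agree with an all-alignment correlation oracle", {
  tpl <- startle_template()
  oracle_score <- function(trace) {
    m <- length(tpl$samples)
    best <- 0
    for (i in 1:(length(trace) - m + 1)) {
      w <- trace[i:(i + m - 1)]
      if (sd(w) == 0) next
      best <- max(best, cor(w, tpl$samples))
    }
    best
  }
  set.seed(42)
  n_match <- 0
  for (k in 1:150) {
    is_st <- k %% 2 == 0
    trace <- simulate_force_waveform(runif(1, 0.5, 5), is_startle = is_st,
                                     noise_sd = 0.02)
    r <- classify_trial(trace, tpl)
    expect_equal(r$score, oracle_score(trace), tolerance = 1e-8)
    n_match <- n_match + (r$startle == is_st)
  }
  expect_gte(n_match / 150, 0.99)  # labels recovered at this SNR
})

test_that("force-to-CMD conversion matches the closed-form half-sine solution", {
  m_g <- 20; tau <- 0.03; F0 <- 0.1; sr <- 1000
  t <- seq(0, 0.35, 1 / sr)
  f <- ifelse(t >= 0.1 & t <= 0.1 + tau, F0 * sin(pi * (t - 0.1) / tau), 0)
  # double integral of a half-sine pulse, then constant-velocity coasting
  m_kg <- m_g / 1000
  x_end <- (F0 * tau^2 / (m_kg * pi) + 2 * F0 * tau / (m_kg * pi) * (0.1 - tau)) * 1000
  expect_equal(force_to_cmd(f, m_g, sr), x_end, tolerance = 0.005)
  expect_equal(force_to_cmd(rep(0, 351), m_g, sr), 0)
  expect_equal(force_to_cmd(2 * f, m_g, sr), 2 * force_to_cmd(f, m_g, sr),
               tolerance = 1e-12)
  expect_error(force_to_cmd(f, 0, sr), "mass")
  expect_error(force_to_cmd(f, m_g, -1), "sample_rate")
})

test_that("force-to-CMD is additive and homogeneous over traces with a common baseline", {
  set.seed(9)
  sr <- 1000
  for (k in 1:15) {
    f1 <- c(rep(0, 100), rnorm(250, 0, 0.05))
    a <- runif(1, 0.2, 3)
    expect_equal(force_to_cmd(a * f1, 25, sr), a * force_to_cmd(f1, 25, sr),
                 tolerance = 1e-10)
  }
})

test_that("I/O functions aggregate valid trials per level", {
  trials <- data.frame(level_db = rep(seq(60, 100, 5), each = 15),
                       cmd_mm = 2.0, valid = TRUE)
  io <- build_io_function(trials)
  expect_equal(nrow(io), 9)
  expect_true(all(io$mean_cmd == 2.0))
  expect_true(all(io$sd_cmd == 0))
  expect_true(all(io$n == 15))

  trials$valid[trials$level_db == 100][1:3] <- FALSE
  io2 <- build_io_function(trials)
  expect_equal(io2$n[io2$level_db == 100], 12)
  expect_true(all(io2$n[io2$level_db < 100] == 15))

  trials$valid[trials$level_db == 60] <- FALSE
  io3 <- build_io_function(trials)
  expect_equal(io3$n[io3$level_db == 60], 0)
  expect_true(is.na(io3$mean_cmd[io3$level_db == 60]))
})

test_that("default simulated I/O session yields 9 levels of 15 trials", {
  io <- build_io_function(simulate_io_session(one_subject(), "baseline",
                                              cohort_config(seed = 2)))
  expect_equal(nrow(io), 9)
  expect_true(all(io$n == 15))
})

test_that("gap ratios divide mean GAP by mean SO per carrier", {
  mk <- function(type, carrier, cmd)
    data.frame(trial_type = type, carrier_khz = carrier, cmd_mm = cmd,
               valid = TRUE)
  sess <- rbind(mk("SO", 8, rep(4, 10)), mk("GAP", 8, rep(2, 10)),
                mk("SO", 16, rep(3, 10)), mk("GAP", 16, rep(3, 10)))
  r <- compute_gap_ratios(sess)
  expect_equal(r$ratio[r$carrier_khz == 8], 0.5)
  expect_equal(r$ratio[r$carrier_khz == 16], 1.0)
  # order invariance and duplication invariance
  r2 <- compute_gap_ratios(sess[sample(nrow(sess)), ])
  expect_equal(r2$ratio, r$ratio)
  r3 <- compute_gap_ratios(rbind(sess, sess))
  expect_equal(r3$ratio, r$ratio)
  # missing propagation: SO mean of zero, or absent trials
  zero <- rbind(mk("SO", 4, rep(0, 5)), mk("GAP", 4, rep(1, 5)))
  expect_true(is.na(compute_gap_ratios(zero)$ratio))
  gaponly <- mk("GAP", 4, rep(1, 5))
  expect_true(is.na(compute_gap_ratios(gaponly)$ratio))
})

test_that("the best daily ratio is the minimum over available sessions", {
  sr <- data.frame(carrier_khz = rep(c(8, 16, 20), each = 3),
                   session = rep(1:3, 3),
                   ratio = c(0.9, 0.5, 0.7, 0.8, NA, NA, NA, NA, NA))
  b <- best_daily_ratio(sr)
  expect_equal(b$best_ratio[b$carrier_khz == 8], 0.5)
  expect_equal(b$best_ratio[b$carrier_khz == 16], 0.8)
  expect_true(is.na(b$best_ratio[b$carrier_khz == 20]))
  expect_equal(b$n_sessions, c(3L, 1L, 0L))
})

test_that("best daily ratio is a monotone envelope of session ratios", {
  set.seed(31)
  for (k in 1:20) {
    sr <- data.frame(carrier_khz = rep(c(4, 8, 12.5, 16, 20), each = 3),
                     session = rep(1:3, 5),
                     ratio = runif(15, 0.2, 1.4))
    b <- best_daily_ratio(sr)
    for (cc in b$carrier_khz)
      expect_true(all(b$best_ratio[b$carrier_khz == cc] <=
                        sr$ratio[sr$carrier_khz == cc]))
  }
})

test_that("gap_ratio_table matches per-session computation and flags the best session", {
  cfg <- small_config()
  s <- one_subject()
  day <- simulate_gpias_day(s, "w2", cfg)
  tab <- gap_ratio_table(day)
  for (sess in 1:3) {
    direct <- compute_gap_ratios(day[day$day_session == sess, ])
    got <- tab[tab$session == sess, ]
    got <- got[order(got$carrier_khz), ]
    expect_equal(got$ratio, direct$ratio, tolerance = 1e-12)
  }
  best <- tab[tab$best_flag, ]
  expect_equal(nrow(best), 5)  # one best session per carrier
  for (cc in best$carrier_khz)
    expect_equal(best$ratio[best$carrier_khz == cc],
                 min(tab$ratio[tab$carrier_khz == cc]))
})
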