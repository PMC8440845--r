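# Synthetic cohort generator. Internal .sim_* helpers return lists of column
# vectors (one data.frame is assembled per cohort, not per session) because
# the calibration and recovery suites simulate hundreds of cohorts.

round5 <- function(x) {
  # nearest multiple of 5, ties away from zero (thresholds are read in 5 dB steps)
  sign(x) * 5 * floor(abs(x) / 5 + 0.5)
}

group_shift_multiplier <- function(group, cfg) {
  switch(group, control = 0, vehicle = 1, ebselen = cfg$ebselen_multiplier,
         stop("unknown group: ", group))
}

# saturating (logistic) startle growth function of stimulus level
startle_growth <- function(level_db, cfg) {
  cfg$startle_max_mm /
    (1 + exp(-(level_db - cfg$startle_midpoint_db) / cfg$startle_slope_db))
}

subject_stream <- function(cfg, subject_id, ...) {
  derive_seed(cfg$seed, sum(utf8ToInt(subject_id) * seq_along(utf8ToInt(subject_id))), ...)
}

epoch_multiplier <- function(subject, epoch, cfg) {
  pos <- match(epoch, cfg$epochs)
  mult <- cfg$habituation_rate^(pos - 1)
  if (isTRUE(subject$true_hyperacusis) && epoch %in% cfg$hyperacusis_epochs)
    mult <- mult * cfg$hyperacusis_gain
  mult
}

.sim_io_session <- function(subject, epoch, cfg) {
  levels <- sample(rep(cfg$io_levels_db, each = cfg$io_reps_per_level))
  n <- length(levels)
  cmd <- startle_growth(levels, cfg) * epoch_multiplier(subject, epoch, cfg) *
    lnorm_noise(n, cfg$trial_noise_cv)
  list(subject_id = rep(subject$subject_id, n), group = rep(subject$group, n),
       epoch = rep(epoch, n), day_session = rep(1L, n), block = rep(NA_integer_, n),
       trial_index = seq_len(n), trial_type = rep("IO", n),
       carrier_khz = rep(NA_real_, n), level_db = levels, cmd_mm = cmd,
       valid = rep(TRUE, n))
}

.sim_gpias_day <- function(subject, epoch, cfg) {
  carriers <- cfg$gpias_carriers_khz
  nb <- cfg$gpias_blocks
  tpb <- cfg$gpias_trials_per_block
  mult <- epoch_multiplier(subject, epoch, cfg)
  so_mean <- startle_growth(100, cfg) * mult

  # true gap ratio per carrier: baseline inhibition, plus a planted deficit at
  # the subject's tinnitus carrier during affected epochs
  r_true <- rep(cfg$baseline_gap_ratio, length(carriers))
  if (isTRUE(subject$true_tinnitus) && epoch %in% cfg$tinnitus_epochs)
    r_true[carriers %in% subject$tinnitus_freq_khz] <-
      cfg$baseline_gap_ratio + cfg$tinnitus_ratio_delta

  out <- vector("list", cfg$gpias_sessions_per_day + 1L)
  for (s in seq_len(cfg$gpias_sessions_per_day)) {
    block_carrier <- sample(rep(carriers, each = nb / length(carriers)))
    carrier <- rep(block_carrier, each = tpb)
    # pseudorandom SO/GAP order within each block (vectorized within-block shuffle)
    types <- rep(rep(c("SO", "GAP"), each = tpb / 2), nb)
    perm <- order(rep(seq_len(nb), each = tpb), runif(nb * tpb))
    types <- types[perm]
    n <- nb * tpb
    mean_cmd <- ifelse(types == "GAP",
                       so_mean * r_true[match(carrier, carriers)], so_mean)
    out[[s]] <- list(subject_id = rep(subject$subject_id, n),
                     group = rep(subject$group, n), epoch = rep(epoch, n),
                     day_session = rep(s, n), block = rep(seq_len(nb), each = tpb),
                     trial_index = seq_len(n), trial_type = types,
                     carrier_khz = carrier, level_db = rep(100, n),
                     cmd_mm = mean_cmd * lnorm_noise(n, cfg$trial_noise_cv),
                     valid = rep(TRUE, n))
  }
  # startles in silence, used only to monitor habituation
  nh <- cfg$habituation_startles
  out[[cfg$gpias_sessions_per_day + 1L]] <-
    list(subject_id = rep(subject$subject_id, nh), group = rep(subject$group, nh),
         epoch = rep(epoch, nh), day_session = rep(0L, nh),
         block = rep(NA_integer_, nh), trial_index = seq_len(nh),
         trial_type = rep("SILENCE", nh), carrier_khz = rep(NA_real_, nh),
         level_db = rep(100, nh),
         cmd_mm = so_mean * lnorm_noise(nh, cfg$trial_noise_cv),
         valid = rep(TRUE, nh))
  out
}

.sim_abr_thresholds <- function(subject, cfg) {
  freqs <- cfg$abr_freqs_khz
  epochs <- cfg$epochs
  nf <- length(freqs)
  ne <- length(epochs)
  rho <- cfg$ear_correlation
  gmult <- group_shift_multiplier(subject$group, cfg)
  # latent baseline: subject-level component shared by both ears (corr rho)
  u <- rnorm(nf, 0, cfg$baseline_threshold_sd * sqrt(rho))
  grid_n <- nf * ne
  cols <- list()
  for (ear in c("L", "R")) {
    e <- rnorm(nf, 0, cfg$baseline_threshold_sd * sqrt(1 - rho))
    latent <- cfg$baseline_threshold_mean + u + e
    # per-epoch measurement noise at every epoch (baseline included), so a
    # zero shift profile leaves all epochs identically distributed
    eps <- matrix(rnorm(grid_n, 0, cfg$shift_sd), nf, ne)
    thr <- round5(latent + gmult * cfg$shift_profile + eps)
    thr <- pmin(pmax(thr, 0), 80)
    cols[[ear]] <- list(subject_id = rep(subject$subject_id, grid_n),
                        group = rep(subject$group, grid_n),
                        ear = rep(ear, grid_n),
                        freq_khz = rep(freqs, ne),
                        epoch = rep(epochs, each = nf),
                        threshold_db = as.vector(thr))
  }
  cols
}

.sim_wave_amps <- function(subject, cfg) {
  freqs <- cfg$abr_freqs_khz
  epochs <- cfg$epochs
  levels <- cfg$wave_levels_db
  gmult <- group_shift_multiplier(subject$group, cfg)
  peak <- max(cfg$shift_profile)
  w <- if (peak > 0) cfg$shift_profile / peak else cfg$shift_profile * 0
  out <- vector("list", 2)
  i <- 0
  for (ear in c("L", "R")) {
    # stable per-ear/per-frequency individuality shared across epochs
    indiv <- lnorm_noise(length(freqs), 0.3)
    grid <- expand.grid(freq_i = seq_along(freqs), level = levels,
                        epoch_i = seq_along(epochs))
    n <- nrow(grid)
    wfe <- w[cbind(grid$freq_i, grid$epoch_i)]
    lvl_scale <- grid$level / max(levels)
    a1 <- cfg$wave1_baseline_uv * indiv[grid$freq_i] * lvl_scale *
      (1 - cfg$wave1_decline * wfe * gmult) * lnorm_noise(n, cfg$wave_noise_cv)
    a3 <- cfg$wave3_baseline_uv * indiv[grid$freq_i] * lvl_scale *
      (1 + cfg$wave3_rise * wfe * gmult) * lnorm_noise(n, cfg$wave_noise_cv)
    i <- i + 1
    out[[i]] <- list(subject_id = rep(subject$subject_id, n),
                     group = rep(subject$group, n), ear = rep(ear, n),
                     freq_khz = freqs[grid$freq_i], level_db = grid$level,
                     epoch = epochs[grid$epoch_i],
                     amp_wave1_uv = pmax(a1, 0), amp_wave3_uv = pmax(a3, 0))
  }
  out
}

bind_cols_list <- function(pieces) {
  nm <- names(pieces[[1]])
  as.data.frame(setNames(lapply(nm, function(k)
    unlist(lapply(pieces, `[[`, k), use.names = FALSE)), nm),
    stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic ototoxicity cohort
#'
#' Generates subjects with ground-truth phenotype flags, per-ear ABR
#' thresholds for every frequency and epoch, ABR wave I/III amplitudes, and
#' the full startle protocol (one I/O session and one GPIAS day of
#' `gpias_sessions_per_day` sessions plus silence startles, per subject per
#' epoch). Control subjects never carry planted effects; treated subjects
#' draw hyperacusis and tinnitus status independently at the configured
#' prevalences (scaled by `ebselen_multiplier` in the ebselen group). The
#' result is a deterministic function of the configuration, including its
#' seed.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: a list with `subjects`,
#'   `abr_thresholds`, `wave_amps`, `startle_trials` data frames and the
#'   `config` used. Ground-truth flags live only in `subjects`; no analysis
#'   function reads them.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  groups <- rep(c("control", "vehicle", "ebselen"),
                c(cfg$n_control, cfg$n_treated_vehicle, cfg$n_treated_ebselen))
  n <- length(groups)
  if (n == 0) stop("cohort has no subjects", call. = FALSE)
  prefix <- c(control = "C", vehicle = "V", ebselen = "E")
  ids <- sprintf("%s%02d", prefix[groups],
                 stats::ave(seq_len(n), groups, FUN = seq_along))

  subjects <- with_stream(derive_seed(cfg$seed, 0), {
    prev_h <- ifelse(groups == "vehicle", cfg$hyperacusis_prevalence,
                     ifelse(groups == "ebselen",
                            cfg$hyperacusis_prevalence * cfg$ebselen_multiplier, 0))
    prev_t <- ifelse(groups == "vehicle", cfg$tinnitus_prevalence,
                     ifelse(groups == "ebselen",
                            cfg$tinnitus_prevalence * cfg$ebselen_multiplier, 0))
    th <- rbinom(n, 1, prev_h) == 1
    tt <- rbinom(n, 1, prev_t) == 1
    tf <- ifelse(tt, cfg$tinnitus_freqs[sample.int(length(cfg$tinnitus_freqs),
                                                   n, replace = TRUE)], NA_real_)
    data.frame(subject_id = ids, sex = rep_len(c("M", "F"), n), group = groups,
               true_hyperacusis = th, true_tinnitus = tt,
               tinnitus_freq_khz = tf, stringsAsFactors = FALSE)
  })

  abr <- list(); wamps <- list(); trials <- list()
  for (i in seq_len(n)) {
    subj <- as.list(subjects[i, ])
    abr_i <- with_stream(subject_stream(cfg, subj$subject_id, 1),
                         .sim_abr_thresholds(subj, cfg))
    wamps_i <- with_stream(subject_stream(cfg, subj$subject_id, 2),
                           .sim_wave_amps(subj, cfg))
    abr[[i]] <- bind_cols_list(abr_i)
    wamps[[i]] <- bind_cols_list(wamps_i)
    tr <- vector("list", length(cfg$epochs))
    for (j in seq_along(cfg$epochs)) {
      ep <- cfg$epochs[j]
      io <- with_stream(subject_stream(cfg, subj$subject_id, 3, j),
                        .sim_io_session(subj, ep, cfg))
      gp <- with_stream(subject_stream(cfg, subj$subject_id, 4, j),
                        .sim_gpias_day(subj, ep, cfg))
      tr[[j]] <- c(list(io), gp)
    }
    trials[[i]] <- bind_cols_list(unlist(tr, recursive = FALSE))
  }

  out <- list(subjects = subjects,
              abr_thresholds = bind_cols_list(abr),
              wave_amps = bind_cols_list(wamps),
              startle_trials = bind_cols_list(trials),
              config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d subjects (%s)\n", nrow(x$subjects),
              paste(sprintf("%d %s", table(x$subjects$group)[unique(x$subjects$group)],
                            unique(x$subjects$group)), collapse = ", ")))
  cat(sprintf("  %d ABR threshold records, %d wave-amplitude records, %d startle trials\n",
              nrow(x$abr_thresholds), nrow(x$wave_amps), nrow(x$startle_trials)))
  invisible(x)
}

#' Simulate one input/output startle session
#'
#' Emits exactly `io_reps_per_level` trials at each stimulus level in
#' pseudorandom order. Trial magnitude is the saturating growth function of
#' level, scaled by long-term habituation (and the hyperacusis gain for an
#' affected subject at an affected epoch), under multiplicative lognormal
#' noise.
#'
#' @param subject a one-row data frame or list with `subject_id`, `group`,
#'   and optionally `true_hyperacusis`.
#' @param epoch epoch label (must be one of `config$epochs`).
#' @param config a [cohort_config()].
#' @param seed optional integer; defaults to the subject/epoch substream of
#'   the configured cohort seed.
#' @return a `startle_trials`-schema data frame.
#' @export
simulate_io_session <- function(subject, epoch, config, seed = NULL) {
  stopifnot(epoch %in% config$epochs)
  subject <- as.list(subject)
  if (is.null(seed))
    seed <- subject_stream(config, subject$subject_id, 3, match(epoch, config$epochs))
  bind_cols_list(list(with_stream(seed, .sim_io_session(subject, epoch, config))))
}

#' Simulate one GPIAS test day
#'
#' Runs `gpias_sessions_per_day` sessions. Each session has `gpias_blocks`
#' blocks of `gpias_trials_per_block` trials (half startle-only, half
#' gap-preceded, pseudorandom within block); each carrier frequency is
#' assigned to exactly `gpias_blocks / n_carriers` blocks per session. The
#' day additionally carries `habituation_startles` startles in silence
#' (`day_session = 0`), which ratio computation ignores.
#'
#' @inheritParams simulate_io_session
#' @return a `startle_trials`-schema data frame.
#' @export
simulate_gpias_day <- function(subject, epoch, config, seed = NULL) {
  stopifnot(epoch %in% config$epochs)
  subject <- as.list(subject)
  if (is.null(seed))
    seed <- subject_stream(config, subject$subject_id, 4, match(epoch, config$epochs))
  bind_cols_list(with_stream(seed, .sim_gpias_day(subject, epoch, config)))
}

#' Simulate per-ear ABR thresholds for one subject
#'
#' Latent baseline thresholds are Normal around
#' `baseline_threshold_mean` with a subject-level component shared between
#' ears (`ear_correlation`); each epoch adds the group-scaled shift profile
#' and Normal measurement noise (`shift_sd`) before rounding to the nearest
#' 5 dB (ties away from zero) and clamping to [0, 80] dB SPL.
#'
#' @inheritParams simulate_io_session
#' @return an `abr_thresholds`-schema data frame (both ears, all frequencies
#'   and epochs).
#' @export
simulate_abr_thresholds <- function(subject, config, seed = NULL) {
  subject <- as.list(subject)
  if (is.null(seed)) seed <- subject_stream(config, subject$subject_id, 1)
  bind_cols_list(with_stream(seed, .sim_abr_thresholds(subject, config)))
}
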