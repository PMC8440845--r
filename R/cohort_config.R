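#' Default per-frequency, per-epoch mean threshold-shift profile (dB)
#'
#' Mean ABR threshold elevation planted in treated ears, by test frequency and
#' epoch. The default peaks at 16 kHz (12.5 dB at weeks 2 and 6, the
#' mid-range of the 10-15 dB elevation typical of a 14-day aminoglycoside
#' course in a resistant mouse strain), spreads mildly to the neighboring
#' frequencies, decays over the recovery epochs and resolves by week 18.
#'
#' @param freqs_khz ABR test frequencies (kHz).
#' @param epochs epoch labels; the first is baseline and carries zero shift.
#' @return numeric matrix `length(freqs_khz)` x `length(epochs)` with
#'   dimnames, in dB.
#' @export
default_shift_profile <- function(freqs_khz = c(4, 8, 16, 20),
                                  epochs = c("baseline", "w2", "w6", "w10", "w14", "w18")) {
  prof <- matrix(0, length(freqs_khz), length(epochs),
                 dimnames = list(as.character(freqs_khz), epochs))
  put <- function(f, shifts) {
    key <- as.character(f)
    if (key %in% rownames(prof)) prof[key, -1] <<- shifts
  }
  put(4,  c(2.5, 2.5, 0, 0, 0))
  put(8,  c(5, 5, 2.5, 0, 0))
  put(16, c(12.5, 12.5, 7.5, 5, 0))
  put(20, c(7.5, 7.5, 5, 2.5, 0))
  prof
}

#' Configuration of a synthetic ototoxicity cohort
#'
#' Collects every parameter of the simulated study: group sizes, the epoch
#' and stimulus grids of the ABR, input/output (I/O) and GPIAS protocols,
#' the planted treatment effects (threshold-shift profile, hyperacusis gain,
#' tinnitus gap-ratio delta and their prevalences), behavioral nuisance
#' structure (long-term startle habituation, trial-level noise), and the seed.
#' The defaults are the conditions of a 36-mouse, three-group, six-epoch
#' tobramycin/ebselen study.
#'
#' @param n_control,n_treated_vehicle,n_treated_ebselen group sizes.
#' @param epochs ordered epoch labels; the first is baseline.
#' @param abr_freqs_khz ABR test frequencies (kHz), ordered.
#' @param gpias_carriers_khz GPIAS narrowband carrier frequencies (kHz).
#' @param io_levels_db startle stimulus levels for I/O sessions (dB SPL).
#' @param io_reps_per_level trials per level in one I/O session.
#' @param gpias_blocks blocks per GPIAS session (must be divisible by the
#'   number of carriers).
#' @param gpias_trials_per_block trials per block (half startle-only, half
#'   gap-preceded).
#' @param gpias_sessions_per_day GPIAS sessions run per test day.
#' @param habituation_startles startles presented in silence per GPIAS day,
#'   used only to monitor habituation.
#' @param shift_profile matrix of mean treated-ear threshold shifts (dB),
#'   frequencies x epochs; see [default_shift_profile()].
#' @param shift_sd SD (dB) of the per-ear, per-epoch threshold measurement
#'   noise added before rounding.
#' @param baseline_threshold_mean,baseline_threshold_sd Normal parameters
#'   (dB SPL) of the latent baseline threshold before rounding to 5 dB.
#' @param ear_correlation correlation of left/right latent thresholds within
#'   a subject (shared subject-level random effect).
#' @param hyperacusis_prevalence probability a tobramycin/vehicle subject is a
#'   true hyperacusis case.
#' @param hyperacusis_gain multiplicative startle-magnitude gain (> 1) in
#'   affected subjects during `hyperacusis_epochs`.
#' @param hyperacusis_epochs epochs at which the hyperacusis gain applies.
#' @param tinnitus_prevalence probability a tobramycin/vehicle subject is a
#'   true tinnitus case.
#' @param tinnitus_freqs carrier subset (kHz) from which each tinnitus
#'   subject's affected carrier is drawn.
#' @param tinnitus_ratio_delta additive increase of the true gap ratio at the
#'   affected carrier during `tinnitus_epochs` (less inhibition).
#' @param tinnitus_epochs epochs at which the tinnitus deficit applies.
#' @param habituation_rate per-epoch multiplicative decay of startle
#'   magnitude in (0, 1]; 1 disables habituation.
#' @param baseline_gap_ratio true GAP/SO startle ratio in (0, 1) of a
#'   normal-hearing animal.
#' @param trial_noise_cv coefficient of variation of the multiplicative
#'   lognormal trial-level startle noise.
#' @param ebselen_multiplier multiplier in [0, 1] applied to the shift
#'   profile and to both phenotype prevalences for the ebselen group
#'   (otoprotection strength).
#' @param startle_max_mm,startle_midpoint_db,startle_slope_db parameters of
#'   the saturating (logistic) startle growth function of stimulus level.
#' @param wave_levels_db stimulus levels (dB SPL) at which ABR wave
#'   amplitudes are emitted.
#' @param wave1_baseline_uv,wave3_baseline_uv mean baseline wave I / wave III
#'   amplitudes (uV).
#' @param wave1_decline peak fractional decline of wave I in treated ears
#'   (applied along the normalized shift-profile time course).
#' @param wave3_rise peak fractional rise of wave III in treated ears.
#' @param wave_noise_cv CV of the lognormal noise on wave amplitudes.
#' @param sample_rate_hz sampling rate used when force waveforms are
#'   simulated.
#' @param seed integer seed; identical (config, seed) gives a bit-identical
#'   cohort.
#' @return an object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_control = 8,
                          n_treated_vehicle = 14,
                          n_treated_ebselen = 14,
                          epochs = c("baseline", "w2", "w6", "w10", "w14", "w18"),
                          abr_freqs_khz = c(4, 8, 16, 20),
                          gpias_carriers_khz = c(4, 8, 12.5, 16, 20),
                          io_levels_db = seq(60, 100, by = 5),
                          io_reps_per_level = 15,
                          gpias_blocks = 15,
                          gpias_trials_per_block = 10,
                          gpias_sessions_per_day = 3,
                          habituation_startles = 15,
                          shift_profile = default_shift_profile(abr_freqs_khz, epochs),
                          shift_sd = 5,
                          baseline_threshold_mean = 25,
                          baseline_threshold_sd = 5,
                          ear_correlation = 0.5,
                          hyperacusis_prevalence = 0.5,
                          hyperacusis_gain = 3,
                          hyperacusis_epochs = c("w2", "w6", "w10"),
                          tinnitus_prevalence = 0.36,
                          tinnitus_freqs = c(16, 20),
                          tinnitus_ratio_delta = 0.3,
                          tinnitus_epochs = c("w2", "w6", "w10"),
                          habituation_rate = 0.9,
                          baseline_gap_ratio = 0.65,
                          trial_noise_cv = 0.35,
                          ebselen_multiplier = 0.3,
                          startle_max_mm = 5,
                          startle_midpoint_db = 85,
                          startle_slope_db = 8,
                          wave_levels_db = c(40, 80),
                          wave1_baseline_uv = 2,
                          wave3_baseline_uv = 1.5,
                          wave1_decline = 0.3,
                          wave3_rise = 0.1,
                          wave_noise_cv = 0.25,
                          sample_rate_hz = 1000,
                          seed = 1L) {
  cfg <- as.list(environment())
  cfg$shift_profile <- as.matrix(shift_profile)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min || v != round(v))
      config_error(field, sprintf("must be an integer >= %d", min))
  }
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      config_error(field, "must be a fraction in [0, 1]")
  }
  for (f in c("n_control", "n_treated_vehicle", "n_treated_ebselen"))
    chk_count(f, 0)
  for (f in c("io_reps_per_level", "gpias_blocks", "gpias_trials_per_block",
              "gpias_sessions_per_day", "habituation_startles"))
    chk_count(f, 1)
  for (f in c("hyperacusis_prevalence", "tinnitus_prevalence",
              "ebselen_multiplier", "ear_correlation"))
    chk_frac(f)
  if (length(cfg$epochs) < 2 || anyDuplicated(cfg$epochs))
    config_error("epochs", "must be >= 2 distinct labels (baseline first)")
  if (cfg$gpias_blocks %% length(cfg$gpias_carriers_khz) != 0)
    config_error("gpias_blocks",
                 "must be divisible by the number of GPIAS carriers")
  if (cfg$gpias_trials_per_block %% 2 != 0)
    config_error("gpias_trials_per_block", "must be even (half SO, half GAP)")
  if (cfg$habituation_rate <= 0 || cfg$habituation_rate > 1)
    config_error("habituation_rate", "must lie in (0, 1]")
  if (cfg$baseline_gap_ratio <= 0 || cfg$baseline_gap_ratio >= 1)
    config_error("baseline_gap_ratio", "must lie in (0, 1)")
  if (cfg$hyperacusis_gain < 1)
    config_error("hyperacusis_gain", "must be >= 1")
  if (cfg$trial_noise_cv < 0) config_error("trial_noise_cv", "must be >= 0")
  if (cfg$shift_sd < 0) config_error("shift_sd", "must be >= 0")
  if (!all(dim(cfg$shift_profile) ==
           c(length(cfg$abr_freqs_khz), length(cfg$epochs))))
    config_error("shift_profile",
                 "must be a freqs x epochs matrix matching the configured grids")
  if (!all(cfg$tinnitus_freqs %in% cfg$gpias_carriers_khz))
    config_error("tinnitus_freqs", "must be a subset of gpias_carriers_khz")
  if (!all(cfg$hyperacusis_epochs %in% cfg$epochs))
    config_error("hyperacusis_epochs", "must be a subset of epochs")
  if (!all(cfg$tinnitus_epochs %in% cfg$epochs))
    config_error("tinnitus_epochs", "must be a subset of epochs")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    config_error("seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  groups: %d control / %d vehicle / %d ebselen\n",
              x$n_control, x$n_treated_vehicle, x$n_treated_ebselen))
  cat(sprintf("  epochs: %s\n", paste(x$epochs, collapse = ", ")))
  cat(sprintf("  planted: hyperacusis %.2f (gain %.1fx), tinnitus %.2f (delta +%.2f at %s kHz)\n",
              x$hyperacusis_prevalence, x$hyperacusis_gain,
              x$tinnitus_prevalence, x$tinnitus_ratio_delta,
              paste(x$tinnitus_freqs, collapse = "/")))
  cat(sprintf("  seed: %d\n", as.integer(x$seed)))
  invisible(x)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' The document mirrors the argument names of [cohort_config()]; fields that
#' are absent keep their defaults. `shift_profile` may be given as a list of
#' per-frequency numeric vectors (one value per epoch).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    config_error(bad[1], "is not a recognized configuration field")
  if (!is.null(raw$shift_profile) && !is.matrix(raw$shift_profile)) {
    raw$shift_profile <- do.call(rbind, lapply(raw$shift_profile, as.numeric))
    rownames(raw$shift_profile) <- NULL
  }
  do.call(cohort_config, raw)
}
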