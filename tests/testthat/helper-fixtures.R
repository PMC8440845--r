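# Shared fixtures: reduced cohorts keep unit tests fast; the protocol
# geometry (levels, blocks, carriers) stays at study defaults unless a test
# exercises geometry itself.

config_with <- function(defaults, dots) {
  defaults[names(dots)] <- dots
  do.call(cohort_config, defaults)
}

small_config <- function(...) {
  config_with(list(n_control = 2, n_treated_vehicle = 3,
                   n_treated_ebselen = 3, seed = 101L), list(...))
}

null_config <- function(...) {
  # no planted effects, no habituation: groups are exchangeable
  config_with(list(hyperacusis_prevalence = 0, tinnitus_prevalence = 0,
                   habituation_rate = 1,
                   shift_profile = matrix(0, 4, 6,
                                          dimnames = list(c(4, 8, 16, 20),
                                                          c("baseline", "w2", "w6",
                                                            "w10", "w14", "w18")))),
              list(...))
}

one_subject <- function(group = "vehicle", hyper = FALSE, tin = FALSE,
                        tin_freq = NA_real_) {
  list(subject_id = "S01", group = group, true_hyperacusis = hyper,
       true_tinnitus = tin, tinnitus_freq_khz = tin_freq)
}

# trial table for one subject at baseline + selected epochs, IO and GPIAS
subject_trials <- function(cfg, subject, epochs = cfg$epochs) {
  do.call(rbind, lapply(epochs, function(e)
    rbind(simulate_io_session(subject, e, cfg),
          simulate_gpias_day(subject, e, cfg))))
}
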