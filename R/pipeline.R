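# End-to-end orchestration: simulate -> process -> abr -> classify -> stats,
# with input validation and a reproducibility manifest.

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Validate the tabular inputs of the analysis stages
#'
#' Schema, range, and referential checks over the three study tables.
#' Warnings flag suspicious but usable records (e.g. a threshold that is not
#' a multiple of 5); fatal findings (unknown subjects, unknown epochs,
#' missing columns) make the data unusable.
#'
#' @param thresholds `abr_thresholds`-schema data frame, or `NULL`.
#' @param trials `startle_trials`-schema data frame, or `NULL`.
#' @param wave_amps `wave_amps`-schema data frame, or `NULL`.
#' @param subjects optional data frame with `subject_id` for referential
#'   checks.
#' @param epochs optional epoch labels every record must belong to.
#' @return data frame with `severity` ("warning"/"fatal"), `table`,
#'   `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(thresholds = NULL, trials = NULL,
                            wave_amps = NULL, subjects = NULL,
                            epochs = NULL) {
  findings <- list()
  add <- function(severity, table, message)
    findings[[length(findings) + 1]] <<-
      data.frame(severity = severity, table = table, message = message)
  need <- function(df, table, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      add("fatal", table, paste("missing columns:", paste(miss, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  chk_ref <- function(df, table) {
    if (!is.null(subjects)) {
      bad <- setdiff(unique(df$subject_id), subjects$subject_id)
      if (length(bad))
        add("fatal", table, paste("unknown subject_id:", paste(bad, collapse = ", ")))
    }
    if (!is.null(epochs)) {
      bad <- setdiff(unique(df$epoch), epochs)
      if (length(bad))
        add("fatal", table, paste("unknown epoch:", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(thresholds) &&
      need(thresholds, "abr_thresholds",
           c("subject_id", "ear", "freq_khz", "epoch", "threshold_db"))) {
    chk_ref(thresholds, "abr_thresholds")
    odd <- which(thresholds$threshold_db %% 5 != 0 |
                   thresholds$threshold_db < 0 | thresholds$threshold_db > 80)
    for (i in head(odd, 20))
      add("warning", "abr_thresholds",
          sprintf("row %d: threshold %g dB is not a multiple of 5 in [0, 80]",
                  i, thresholds$threshold_db[i]))
    if (!all(thresholds$ear %in% c("L", "R")))
      add("fatal", "abr_thresholds", "ear must be 'L' or 'R'")
  }
  if (!is.null(trials) &&
      need(trials, "startle_trials",
           c("subject_id", "epoch", "trial_type", "cmd_mm", "valid"))) {
    chk_ref(trials, "startle_trials")
    bad_type <- setdiff(unique(trials$trial_type), c("SO", "GAP", "IO", "SILENCE"))
    if (length(bad_type))
      add("fatal", "startle_trials",
          paste("unknown trial_type:", paste(bad_type, collapse = ", ")))
    neg <- which(!is.na(trials$cmd_mm) & trials$cmd_mm < 0)
    for (i in head(neg, 20))
      add("warning", "startle_trials",
          sprintf("row %d: negative cmd_mm (%g)", i, trials$cmd_mm[i]))
    no_carrier <- trials$trial_type %in% c("SO", "GAP") & is.na(trials$carrier_khz)
    if (any(no_carrier))
      add("fatal", "startle_trials", "SO/GAP trials must carry a carrier_khz")
  }
  if (!is.null(wave_amps) &&
      need(wave_amps, "wave_amps",
           c("subject_id", "ear", "freq_khz", "level_db", "epoch",
             "amp_wave1_uv", "amp_wave3_uv"))) {
    chk_ref(wave_amps, "wave_amps")
    neg <- which(wave_amps$amp_wave1_uv < 0 | wave_amps$amp_wave3_uv < 0)
    for (i in head(neg, 20))
      add("warning", "wave_amps", sprintf("row %d: negative amplitude", i))
  }
  out <- if (length(findings)) do.call(rbind, findings) else
    data.frame(severity = character(), table = character(),
               message = character())
  rownames(out) <- NULL
  out
}

crc_group_stats <- function(incidence, g1 = "vehicle", g2 = "ebselen",
                            conf_level = 0.95) {
  epochs <- unique(incidence$epoch)
  rows <- lapply(epochs, function(ep) {
    r1 <- incidence[incidence$group == g1 & incidence$epoch == ep, ]
    r2 <- incidence[incidence$group == g2 & incidence$epoch == ep, ]
    if (nrow(r1) != 1 || nrow(r2) != 1 || r1$n == 0 || r2$n == 0) return(NULL)
    a <- r1$positives; b <- r1$n - r1$positives
    c_ <- r2$positives; d <- r2$n - r2$positives
    p <- fisher_exact_2x2(a, b, c_, d)
    rr <- koopman_rr_ci(a, b, c_, d, conf_level)
    data.frame(epoch = ep, group1 = g1, group2 = g2,
               pos1 = a, n1 = r1$n, pos2 = c_, n2 = r2$n,
               fisher_p = p, rr = rr$rr, rr_low = rr$ci_low,
               rr_high = rr$ci_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

contingency_summary <- function(overall, g1 = "vehicle", g2 = "ebselen") {
  o1 <- overall[overall$group == g1 & !is.na(overall$positive), ]
  o2 <- overall[overall$group == g2 & !is.na(overall$positive), ]
  if (nrow(o1) == 0 || nrow(o2) == 0) return(NULL)
  a <- sum(o1$positive); b <- nrow(o1) - a
  c_ <- sum(o2$positive); d <- nrow(o2) - c_
  rr <- koopman_rr_ci(a, b, c_, d)
  data.frame(group1 = g1, group2 = g2, pos1 = a, neg1 = b, pos2 = c_,
             neg2 = d, fisher_p = fisher_exact_2x2(a, b, c_, d),
             rr = rr$rr, rr_low = rr$ci_low, rr_high = rr$ci_high)
}

#' Run the whole phenotyping pipeline on a synthetic cohort
#'
#' Simulates a cohort from `config`, validates it, and runs every analysis
#' stage: I/O functions and gap ratios, per-ear threshold shifts with CRC
#' responder calls and incidence (plus vehicle-vs-ebselen Fisher exact p and
#' Koopman relative-risk interval per epoch), wave III/I ratio trajectories,
#' per-animal hyperacusis and tinnitus classification with per-epoch
#' incidence and overall 2x2 contingency statistics. All result tables are
#' written to `out_dir` as CSV together with a JSON manifest of file digests;
#' re-running with the same configuration reproduces identical digests.
#'
#' @param config a [cohort_config()] (or path to a YAML/JSON config file).
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param seed optional seed overriding `config$seed`.
#' @param alpha significance level used by the classifiers.
#' @return (invisibly) a list with every stage's tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, alpha = 0.05) {
  if (is.character(config)) config <- read_cohort_config(config)
  if (!is.null(seed)) { config$seed <- as.integer(seed); validate_cohort_config(config) }
  cohort <- simulate_cohort(config)
  epochs <- config$epochs

  report <- validate_inputs(cohort$abr_thresholds, cohort$startle_trials,
                            cohort$wave_amps, subjects = cohort$subjects,
                            epochs = epochs)
  if (any(report$severity == "fatal"))
    stop("input validation failed: ",
         paste(report$message[report$severity == "fatal"], collapse = "; "),
         call. = FALSE)

  # startle processing
  io <- cohort$startle_trials[cohort$startle_trials$trial_type == "IO", ]
  io_key <- interaction(io$subject_id, io$epoch, drop = TRUE)
  io_functions <- do.call(rbind, lapply(split(io, io_key), build_io_function))
  rownames(io_functions) <- NULL
  gap_ratios <- gap_ratio_table(cohort$startle_trials)

  # ABR stage
  shifts <- threshold_shift(cohort$abr_thresholds, epochs,
                            config$abr_freqs_khz)
  gmap <- setNames(cohort$subjects$group, cohort$subjects$subject_id)
  crc_results <- crc_classify_table(shifts, config$abr_freqs_khz, gmap)
  crc_inc <- crc_incidence(crc_results)
  crc_stats <- crc_group_stats(crc_inc)
  wave_ratios <- wave_ratio_table(cohort$wave_amps, epochs)

  # behavior stage (treated groups carry the phenotypes; classify everyone)
  hyper <- classify_hyperacusis(cohort$startle_trials, epochs, alpha)
  tin <- classify_tinnitus(cohort$startle_trials, epochs, alpha)
  treated <- function(df) df[df$group %in% c("vehicle", "ebselen"), ]
  incidence <- rbind(
    cbind(phenotype = "hyperacusis",
          phenotype_incidence(treated(hyper$calls))),
    cbind(phenotype = "tinnitus", phenotype_incidence(treated(tin$calls))))
  contingency <- rbind(
    cbind(phenotype = "hyperacusis", contingency_summary(hyper$overall)),
    cbind(phenotype = "tinnitus", contingency_summary(tin$overall)))

  result <- list(cohort = cohort, validation = report,
                 io_functions = io_functions, gap_ratios = gap_ratios,
                 shifts = shifts, crc_results = crc_results,
                 crc_incidence = crc_inc, crc_stats = crc_stats,
                 wave_ratios = wave_ratios,
                 hyperacusis = hyper, tinnitus = tin,
                 incidence_by_epoch = incidence, contingency = contingency)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_table(cohort$subjects, out_dir, "subjects.csv"),
      write_table(cohort$abr_thresholds, out_dir, "abr_thresholds.csv"),
      write_table(cohort$startle_trials, out_dir, "startle_trials.csv"),
      write_table(cohort$wave_amps, out_dir, "wave_amps.csv"),
      write_table(io_functions, out_dir, "io_functions.csv"),
      write_table(gap_ratios, out_dir, "gap_ratios.csv"),
      write_table(crc_results, out_dir, "crc_results.csv"),
      write_table(crc_inc, out_dir, "crc_incidence.csv"),
      write_table(crc_stats, out_dir, "crc_stats.csv"),
      write_table(wave_ratios, out_dir, "wave_ratios.csv"),
      write_table(rbind(cbind(phenotype = "hyperacusis",
                              hyper$overall[, c("subject_id", "group", "positive")]),
                        cbind(phenotype = "tinnitus",
                              tin$overall[, c("subject_id", "group", "positive")])),
                  out_dir, "phenotype_calls.csv"),
      write_table(incidence, out_dir, "incidence_by_epoch.csv"),
      write_table(contingency, out_dir, "phenotype_contingency.csv"))
    manifest <- list(
      seed = as.integer(config$seed),
      alpha = alpha,
      n_subjects = nrow(cohort$subjects),
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  invisible(result)
}
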