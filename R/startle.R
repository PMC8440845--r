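# Trial tables -> input/output functions and gap-detection ratios.

#' Build the input/output (I/O) startle function for one subject and epoch
#'
#' Per-level mean, SD and count of startle magnitude (CMD, mm). Invalid
#' trials are excluded before aggregation; a level left with no valid trial
#' is reported with `n = 0` and a missing mean.
#'
#' @param trials data frame of I/O trials (`trial_type == "IO"`) for a single
#'   subject and epoch, with `level_db`, `cmd_mm`, `valid`.
#' @param levels optional vector of stimulus levels to report (defaults to
#'   the levels present).
#' @return data frame with `level_db`, `mean_cmd`, `sd_cmd`, `n`, sorted by
#'   level, plus `subject_id`/`epoch` columns when present in the input.
#' @export
build_io_function <- function(trials, levels = NULL) {
  stopifnot(all(c("level_db", "cmd_mm", "valid") %in% names(trials)))
  if (is.null(levels)) levels <- sort(unique(trials$level_db))
  ok <- trials[trials$valid & is.finite(trials$cmd_mm), , drop = FALSE]
  lv <- factor(ok$level_db, levels = levels)
  out <- data.frame(
    level_db = levels,
    mean_cmd = as.numeric(tapply(ok$cmd_mm, lv, mean)),
    sd_cmd   = as.numeric(tapply(ok$cmd_mm, lv, sd)),
    n        = as.integer(table(lv)))
  out$mean_cmd[out$n == 0] <- NA_real_
  if (!is.null(trials$subject_id) && length(unique(trials$subject_id)) == 1)
    out <- cbind(subject_id = trials$subject_id[1], out)
  if (!is.null(trials$epoch) && length(unique(trials$epoch)) == 1)
    out <- cbind(out, epoch = trials$epoch[1])
  out
}

#' Gap-detection ratios of one GPIAS session
#'
#' For each carrier frequency, the ratio of the mean valid GAP startle
#' magnitude to the mean valid startle-only (SO) magnitude. A ratio is
#' missing when either side has no valid trials or the SO mean is zero.
#' Silence (habituation) trials are ignored. Invariant to trial order.
#'
#' @param trials data frame of one session's trials with `trial_type`
#'   (`"SO"`/`"GAP"`), `carrier_khz`, `cmd_mm`, `valid`.
#' @param carriers optional carrier frequencies to report (defaults to those
#'   present).
#' @return data frame with `carrier_khz`, `ratio`, `n_so`, `n_gap`.
#' @export
compute_gap_ratios <- function(trials, carriers = NULL) {
  stopifnot(all(c("trial_type", "carrier_khz", "cmd_mm", "valid") %in% names(trials)))
  tr <- trials[trials$trial_type %in% c("SO", "GAP") & trials$valid &
                 is.finite(trials$cmd_mm), , drop = FALSE]
  if (is.null(carriers)) carriers <- sort(unique(tr$carrier_khz))
  cf <- factor(tr$carrier_khz, levels = carriers)
  agg <- function(type, fun) {
    sel <- tr$trial_type == type
    as.numeric(tapply(tr$cmd_mm[sel], cf[sel], fun))
  }
  so_mean <- agg("SO", mean); gap_mean <- agg("GAP", mean)
  n_so <- as.integer(table(cf[tr$trial_type == "SO"]))
  n_gap <- as.integer(table(cf[tr$trial_type == "GAP"]))
  ratio <- ifelse(n_so > 0 & n_gap > 0 & !is.na(so_mean) & so_mean > 0,
                  gap_mean / so_mean, NA_real_)
  data.frame(carrier_khz = carriers, ratio = ratio, n_so = n_so, n_gap = n_gap)
}

#' Best daily gap-detection ratio per carrier
#'
#' The best of the (up to three) session ratios is the minimum: a lower
#' GAP/SO ratio means stronger inhibition, i.e. better gap detection. All
#' sessions missing at a carrier propagates a missing best ratio.
#'
#' @param session_ratios data frame with `carrier_khz`, `session`, `ratio`
#'   (one row per session x carrier; `ratio` may be `NA`).
#' @return data frame with `carrier_khz`, `best_ratio`, `n_sessions` (count
#'   of non-missing session ratios).
#' @export
best_daily_ratio <- function(session_ratios) {
  stopifnot(all(c("carrier_khz", "ratio") %in% names(session_ratios)))
  carriers <- sort(unique(session_ratios$carrier_khz))
  cf <- factor(session_ratios$carrier_khz, levels = carriers)
  best <- as.numeric(tapply(session_ratios$ratio, cf, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) NA_real_ else min(r)
  }))
  n <- as.integer(tapply(!is.na(session_ratios$ratio), cf, sum))
  data.frame(carrier_khz = carriers, best_ratio = best, n_sessions = n)
}

#' Per-session and best-of-day gap ratios for a whole trial table
#'
#' Applies [compute_gap_ratios()] to every subject x epoch x session and
#' [best_daily_ratio()] across each day's sessions.
#'
#' @param trials a `startle_trials`-schema data frame (any number of
#'   subjects/epochs); silence and I/O trials are ignored.
#' @param carriers optional carrier set to report.
#' @return data frame with `subject_id`, `epoch`, `carrier_khz`, `session`,
#'   `ratio`, `best_flag` (TRUE on the row that is the day's best for that
#'   carrier).
#' @export
gap_ratio_table <- function(trials, carriers = NULL) {
  gp <- trials[trials$trial_type %in% c("SO", "GAP") & trials$valid &
                 is.finite(trials$cmd_mm), , drop = FALSE]
  if (is.null(carriers)) carriers <- sort(unique(gp$carrier_khz))
  gp <- gp[gp$carrier_khz %in% carriers, , drop = FALSE]
  # one grouped pass over the whole table (SO and GAP means per cell)
  cell <- interaction(gp$subject_id, gp$epoch, gp$day_session, gp$carrier_khz,
                      drop = TRUE, sep = "\r")
  is_so <- gp$trial_type == "SO"
  sum_so <- tapply(ifelse(is_so, gp$cmd_mm, 0), cell, sum)
  n_so <- tapply(is_so, cell, sum)
  sum_gap <- tapply(ifelse(is_so, 0, gp$cmd_mm), cell, sum)
  n_gap <- tapply(!is_so, cell, sum)
  keys <- do.call(rbind, strsplit(names(sum_so), "\r", fixed = TRUE))
  so_mean <- as.numeric(sum_so) / as.numeric(n_so)
  gap_mean <- as.numeric(sum_gap) / as.numeric(n_gap)
  ratio <- ifelse(n_so > 0 & n_gap > 0 & is.finite(so_mean) & so_mean > 0,
                  gap_mean / so_mean, NA_real_)
  out <- data.frame(subject_id = keys[, 1], epoch = keys[, 2],
                    carrier_khz = as.numeric(keys[, 4]),
                    session = as.integer(keys[, 3]), ratio = as.numeric(ratio),
                    stringsAsFactors = FALSE)
  day <- interaction(out$subject_id, out$epoch, out$carrier_khz, drop = TRUE)
  best <- stats::ave(out$ratio, day, FUN = function(r)
    if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  out$best_flag <- !is.na(out$ratio) & !is.na(best) & out$ratio == best
  # a tie marks only the first session as best
  dup <- duplicated(paste(day, out$best_flag)) & out$best_flag
  out$best_flag[dup] <- FALSE
  out[order(out$subject_id, out$epoch, out$carrier_khz, out$session), ]
}
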