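# Threshold shifts, clinically-relevant-change (CRC) responder criteria, and
# wave III / wave I amplitude-ratio trajectories.

#' Per-ear ABR threshold shifts from baseline
#'
#' Shift = threshold(epoch) - threshold(baseline), per frequency, for every
#' post-baseline epoch. Ears missing a baseline at a frequency get a missing
#' shift there; an ear with no baseline at all is excluded (attribute
#' `excluded` collects the reasons).
#'
#' @param records `abr_thresholds`-schema data frame (any number of ears)
#'   with `subject_id`, `ear`, `freq_khz`, `epoch`, `threshold_db`.
#' @param epochs ordered epoch labels; the first is baseline.
#' @param freqs frequency order of the shift vectors (defaults to sorted
#'   frequencies present).
#' @return data frame with `subject_id`, `ear`, `epoch`, `freq_khz`,
#'   `shift_db` for post-baseline epochs, in the given frequency order.
#' @export
threshold_shift <- function(records, epochs, freqs = NULL) {
  stopifnot(all(c("subject_id", "ear", "freq_khz", "epoch", "threshold_db")
                %in% names(records)))
  if (is.null(freqs)) freqs <- sort(unique(records$freq_khz))
  baseline <- epochs[1]
  post <- epochs[-1]
  records <- records[records$epoch %in% epochs & records$freq_khz %in% freqs, ]
  ek <- paste(records$subject_id, records$ear, sep = "\r")
  ears <- unique(ek)
  base <- records[records$epoch == baseline, ]
  bkey <- paste(base$subject_id, base$ear, base$freq_khz, sep = "\r")
  bmap <- setNames(base$threshold_db, bkey)
  excluded <- character(0)
  out <- vector("list", length(ears))
  for (i in seq_along(ears)) {
    sel <- records[ek == ears[i] & records$epoch != baseline, ]
    parts <- strsplit(ears[i], "\r", fixed = TRUE)[[1]]
    bthr <- bmap[paste(parts[1], parts[2], freqs, sep = "\r")]
    if (all(is.na(bthr))) {
      excluded <- c(excluded, sprintf("%s ear %s: no baseline thresholds",
                                      parts[1], parts[2]))
      next
    }
    grid <- expand.grid(freq_khz = freqs, epoch = post,
                        stringsAsFactors = FALSE)
    thr <- sel$threshold_db[match(paste(grid$epoch, grid$freq_khz),
                                  paste(sel$epoch, sel$freq_khz))]
    out[[i]] <- data.frame(subject_id = parts[1], ear = parts[2],
                           epoch = grid$epoch, freq_khz = grid$freq_khz,
                           shift_db = thr - rep(bthr, length(post)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(subject_id = character(), ear = character(),
                      epoch = character(), freq_khz = numeric(),
                      shift_db = numeric())
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Clinically-relevant-change classification of one shift vector
#'
#' A per-ear, per-epoch responder criterion for ototoxic threshold change,
#' adapted from clinical pure-tone-audiometry guidelines. The ear is positive
#' when any of three rules holds on the ordered tested frequencies
#' (adjacency = consecutive positions):
#'
#' * `rule20any` - a shift >= 20 dB at any one tested frequency;
#' * `rule15two` - shifts >= 15 dB at two adjacent tested frequencies;
#' * `rule10three` - shifts >= 10 dB at three adjacent tested frequencies.
#'
#' Shifts are signed; only elevations count. Missing frequencies cannot
#' satisfy a rule; a fully missing vector gives a missing result.
#'
#' @param shift numeric vector of shifts (dB) in tested-frequency order
#'   (typically 4, 8, 16, 20 kHz); `NA` allowed.
#' @return a list with `positive` (logical, `NA` if all shifts missing) and
#'   `rules_triggered` (character subset of the three rule names).
#' @export
crc_classify <- function(shift) {
  if (is.logical(shift) && all(is.na(shift))) shift <- as.numeric(shift)
  stopifnot(is.numeric(shift))
  if (all(is.na(shift)))
    return(list(positive = NA, rules_triggered = character(0)))
  s <- ifelse(is.na(shift), -Inf, shift)
  k <- length(s)
  runs_at_least <- function(cut, len) {
    if (k < len) return(FALSE)
    hit <- s >= cut
    any(vapply(seq_len(k - len + 1),
               function(i) all(hit[i:(i + len - 1)]), logical(1)))
  }
  rules <- c(rule20any = runs_at_least(20, 1),
             rule15two = runs_at_least(15, 2),
             rule10three = runs_at_least(10, 3))
  list(positive = any(rules), rules_triggered = names(rules)[rules])
}

#' CRC classification of a whole shift table
#'
#' @param shifts output of [threshold_shift()] (long format), plus optional
#'   `group` metadata to carry through (a `subject_id -> group` map).
#' @param freqs tested-frequency order used for adjacency.
#' @param group_map optional named vector mapping subject_id to group.
#' @return data frame with one row per ear x epoch: `subject_id`, `ear`,
#'   `epoch`, `positive`, `rules_triggered` (comma-separated), and `group`
#'   when a map is given.
#' @export
crc_classify_table <- function(shifts, freqs, group_map = NULL) {
  key <- interaction(shifts$subject_id, shifts$ear, shifts$epoch, drop = TRUE,
                     sep = "\r")
  nf <- length(freqs)
  m <- matrix(NA_real_, nlevels(key), nf)
  m[cbind(as.integer(key), match(shifts$freq_khz, freqs))] <- shifts$shift_db
  all_na <- rowSums(!is.na(m)) == 0
  s <- m
  s[is.na(s)] <- -Inf
  run_hit <- function(cut, len) {
    h <- s >= cut
    if (nf < len) return(rep(FALSE, nrow(s)))
    acc <- rep(FALSE, nrow(s))
    for (i in seq_len(nf - len + 1)) {
      blk <- h[, i, drop = TRUE]
      for (j in seq_len(len - 1)) blk <- blk & h[, i + j, drop = TRUE]
      acc <- acc | blk
    }
    acc
  }
  r20 <- run_hit(20, 1); r15 <- run_hit(15, 2); r10 <- run_hit(10, 3)
  rules <- cbind(rule20any = r20, rule15two = r15, rule10three = r10)
  triggered <- apply(rules, 1, function(z)
    paste(colnames(rules)[z], collapse = ","))
  keys <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(subject_id = keys[, 1], ear = keys[, 2], epoch = keys[, 3],
                    positive = ifelse(all_na, NA, r20 | r15 | r10),
                    rules_triggered = ifelse(all_na, "", triggered),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(group_map)) out$group <- unname(group_map[out$subject_id])
  out
}

#' Percentage of ears meeting the CRC criteria, by group and epoch
#'
#' Ears with a missing call at an epoch drop out of that epoch's denominator
#' only (denominators may therefore fluctuate across epochs).
#'
#' @param results output of [crc_classify_table()] including a `group`
#'   column.
#' @return data frame with `group`, `epoch`, `positives`, `n`, `percent`
#'   (one decimal). Empty cells give a missing percentage.
#' @export
crc_incidence <- function(results) {
  stopifnot(all(c("group", "epoch", "positive") %in% names(results)))
  ok <- results[!is.na(results$positive), ]
  g <- interaction(ok$group, ok$epoch, drop = FALSE,
                   sep = "\r")
  pos <- tapply(ok$positive, g, sum)
  n <- tapply(ok$positive, g, length)
  keys <- do.call(rbind, strsplit(names(pos), "\r", fixed = TRUE))
  out <- data.frame(group = keys[, 1], epoch = keys[, 2],
                    positives = as.integer(ifelse(is.na(pos), 0, pos)),
                    n = as.integer(ifelse(is.na(n), 0, n)),
                    stringsAsFactors = FALSE)
  out$percent <- ifelse(out$n > 0, round(100 * out$positives / out$n, 1),
                        NA_real_)
  rownames(out) <- NULL
  out
}

#' Wave III / wave I amplitude-ratio trajectory, normalized to baseline
#'
#' For one ear x frequency x stimulus-level series, the raw ratio
#' r(e) = wave III / wave I per epoch is expressed as a percentage of the
#' baseline ratio (baseline = 100%). The series is missing when the baseline
#' wave I amplitude is zero (ratio undefined).
#'
#' @param amps data frame with `epoch`, `amp_wave1_uv`, `amp_wave3_uv` for a
#'   single series.
#' @param epochs ordered epoch labels; first is baseline.
#' @return data frame with `epoch`, `ratio`, `normalized_pct`, or `NULL` when
#'   the baseline ratio is undefined.
#' @export
wave_ratio_trajectory <- function(amps, epochs) {
  stopifnot(all(c("epoch", "amp_wave1_uv", "amp_wave3_uv") %in% names(amps)))
  amps <- amps[match(epochs, amps$epoch), ]
  ratio <- ifelse(amps$amp_wave1_uv > 0,
                  amps$amp_wave3_uv / amps$amp_wave1_uv, NA_real_)
  if (is.na(ratio[1]) || !is.finite(ratio[1])) return(NULL)
  data.frame(epoch = epochs, ratio = ratio,
             normalized_pct = 100 * ratio / ratio[1])
}

#' Wave-ratio trajectories for a whole amplitude table
#'
#' @param wave_amps `wave_amps`-schema data frame.
#' @param epochs ordered epoch labels; first is baseline.
#' @return long data frame with `subject_id`, `ear`, `freq_khz`, `level_db`,
#'   `epoch`, `ratio`, `normalized_pct`; series with an undefined baseline
#'   ratio are omitted.
#' @export
wave_ratio_table <- function(wave_amps, epochs) {
  key <- interaction(wave_amps$subject_id, wave_amps$ear, wave_amps$freq_khz,
                     wave_amps$level_db, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(wave_amps)), key), function(idx) {
    d <- wave_amps[idx, ]
    tr <- wave_ratio_trajectory(d, epochs)
    if (is.null(tr)) return(NULL)
    cbind(data.frame(subject_id = d$subject_id[1], ear = d$ear[1],
                     freq_khz = d$freq_khz[1], level_db = d$level_db[1],
                     stringsAsFactors = FALSE), tr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
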