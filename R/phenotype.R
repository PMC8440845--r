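# Per-animal statistical phenotype classification: hyperacusis from I/O
# startle functions, tinnitus from GPIAS gap ratios, both tested against the
# animal's own baseline.

#' Per-epoch hyperacusis decision for one subject
#'
#' Trial-level two-way ANOVA (time: baseline vs epoch x stimulus intensity)
#' on startle magnitude. The epoch is called positive only when the time main
#' effect is significant at `alpha` *and* the epoch's marginal mean CMD
#' exceeds baseline's: hyperacusis is a directional phenotype, so a
#' significant decrease (ordinary habituation) can never be positive.
#'
#' @param io_baseline,io_epoch trial-level data frames for one subject
#'   (`level_db`, `cmd_mm`, `valid`), baseline and comparison epoch.
#' @param alpha significance level.
#' @return list with `decision` ("positive"/"negative"/"excluded"),
#'   `statistic` (time-effect F), `p.value`, `mean_baseline`, `mean_epoch`,
#'   and an `exclusion_reason` when excluded.
#' @export
hyperacusis_test <- function(io_baseline, io_epoch, alpha = 0.05) {
  pick <- function(d) d[d$valid & is.finite(d$cmd_mm), , drop = FALSE]
  b <- pick(io_baseline); e <- pick(io_epoch)
  if (length(unique(b$level_db)) < 2 || length(unique(e$level_db)) < 2)
    return(list(decision = "excluded", statistic = NA_real_,
                p.value = NA_real_, mean_baseline = NA_real_,
                mean_epoch = NA_real_,
                exclusion_reason = "fewer than 2 intensities with valid trials"))
  y <- c(b$cmd_mm, e$cmd_mm)
  time <- rep(c("baseline", "epoch"), c(nrow(b), nrow(e)))
  lvl <- c(b$level_db, e$level_db)
  an <- two_way_anova(y, time, lvl)
  p_time <- an$p.value[an$term == "a"]
  f_time <- an$statistic[an$term == "a"]
  mb <- mean(b$cmd_mm); me <- mean(e$cmd_mm)
  positive <- !is.na(p_time) && p_time < alpha && me > mb
  list(decision = if (positive) "positive" else "negative",
       statistic = f_time, p.value = p_time,
       mean_baseline = mb, mean_epoch = me)
}

#' Per-epoch tinnitus decision for one subject
#'
#' Protected per-carrier contrasts on session-level gap ratios. Each carrier
#' gets a one-sided pooled-t contrast of the epoch's session ratios against
#' baseline's (an *increase* in ratio is a gap-detection deficit), with the
#' pooled error variance taken from the epoch x carrier two-way fit. Two
#' protection flavors are available:
#'
#' * `method = "sidak"` (default): per-carrier one-sided p-values are
#'   Sidak-adjusted over the carriers, and a carrier is significant when its
#'   adjusted p is below `alpha`; the reported omnibus p is the smallest
#'   adjusted p (a max-t union-intersection omnibus). This keeps the
#'   family-wise null rate at `alpha` while retaining power for a deficit
#'   confined to a single carrier.
#' * `method = "lsd"`: Fisher-style protection - a single joint F test of
#'   all epoch-involving terms (epoch main effect plus epoch x carrier
#'   interaction) gates unadjusted per-carrier contrasts.
#'
#' The epoch is positive when the significant carriers form a set of exactly
#' one, or exactly two at adjacent positions in the carrier order (the
#' frequency-specificity rule for a tinnitus percept).
#'
#' @param ratios_baseline,ratios_epoch data frames of session-level ratios
#'   (`carrier_khz`, `ratio`; typically 3 sessions per carrier) for baseline
#'   and the comparison epoch.
#' @param alpha significance level.
#' @param carriers carrier order defining adjacency (defaults to the sorted
#'   union present).
#' @param method contrast protection flavor, `"sidak"` or `"lsd"`.
#' @return list with `decision`, `p_omnibus`, per-carrier `contrasts`
#'   (data frame with `carrier_khz`, `estimate`, `statistic`, `p.value`,
#'   `significant`), `implicated_freqs`, and `exclusion_reason` when
#'   excluded.
#' @export
tinnitus_test <- function(ratios_baseline, ratios_epoch, alpha = 0.05,
                          carriers = NULL, method = c("sidak", "lsd")) {
  method <- match.arg(method)
  b <- ratios_baseline[!is.na(ratios_baseline$ratio), , drop = FALSE]
  e <- ratios_epoch[!is.na(ratios_epoch$ratio), , drop = FALSE]
  shared <- intersect(unique(b$carrier_khz), unique(e$carrier_khz))
  if (is.null(carriers)) carriers <- sort(shared) else
    carriers <- carriers[carriers %in% shared]
  if (length(carriers) < 2)
    return(list(decision = "excluded", p_omnibus = NA_real_,
                contrasts = NULL, implicated_freqs = numeric(0),
                exclusion_reason = "fewer than 2 carriers with ratios on both sides"))
  b <- b[b$carrier_khz %in% carriers, ]; e <- e[e$carrier_khz %in% carriers, ]
  y <- c(b$ratio, e$ratio)
  epoch <- rep(c(0, 1), c(nrow(b), nrow(e)))
  carrier <- factor(c(b$carrier_khz, e$carrier_khz), levels = carriers)
  X_full <- model.matrix(~ factor(epoch) * carrier)
  X_null <- model.matrix(~carrier)
  rss_f <- rss_fit(y, X_full)
  rss_0 <- rss_fit(y, X_null)
  df_num <- qr(X_full)$rank - qr(X_null)$rank
  df_err <- length(y) - qr(X_full)$rank
  if (df_err < 1 || df_num < 1)
    return(list(decision = "excluded", p_omnibus = NA_real_,
                contrasts = NULL, implicated_freqs = numeric(0),
                exclusion_reason = "insufficient replication for the omnibus test"))
  msr <- rss_f / df_err
  scale <- max(mean(y^2), .Machine$double.xmin) * 1e-12
  if (msr <= scale) {
    p_om <- if ((rss_0 - rss_f) / max(df_num, 1) <= scale) 1 else 0
  } else {
    f_om <- ((rss_0 - rss_f) / df_num) / msr
    p_om <- pf(f_om, df_num, df_err, lower.tail = FALSE)
  }
  mb <- tapply(b$ratio, factor(b$carrier_khz, levels = carriers), mean)
  me <- tapply(e$ratio, factor(e$carrier_khz, levels = carriers), mean)
  nb <- table(factor(b$carrier_khz, levels = carriers))
  ne <- table(factor(e$carrier_khz, levels = carriers))
  se <- sqrt(msr * (1 / as.numeric(nb) + 1 / as.numeric(ne)))
  tt <- ifelse(se > 0, (me - mb) / se, 0)
  p_one <- pt(tt, df_err, lower.tail = FALSE)  # one-sided: increase = deficit
  if (method == "sidak") {
    p_adj <- sidak_adjust(p_one, length(carriers))
    p_om <- min(p_adj)
    sig <- p_adj < alpha
  } else {
    sig <- (p_om <= alpha) & (p_one < alpha)
  }
  contrasts <- data.frame(carrier_khz = carriers,
                          estimate = as.numeric(me - mb),
                          statistic = as.numeric(tt),
                          p.value = as.numeric(p_one), significant = sig)
  idx <- which(sig)
  positive <- length(idx) == 1 ||
    (length(idx) == 2 && diff(idx) == 1)
  list(decision = if (positive) "positive" else "negative",
       p_omnibus = p_om, contrasts = contrasts,
       implicated_freqs = if (positive) carriers[idx] else numeric(0))
}

#' Baseline GPIAS inclusion criterion
#'
#' An animal enters tinnitus analysis only if its baseline gap detection is
#' adequate: the mean best daily ratio across carriers must not exceed the
#' inclusion threshold (an animal whose gaps barely suppress its startle at
#' baseline cannot show a deficit).
#'
#' @param baseline_best data frame with `carrier_khz`, `best_ratio` at
#'   baseline (output of [best_daily_ratio()]).
#' @param threshold maximum acceptable mean baseline best ratio.
#' @return list with `include` (logical) and `reason`.
#' @export
gpias_inclusion <- function(baseline_best, threshold = 0.8) {
  r <- baseline_best$best_ratio
  r <- r[!is.na(r)]
  if (length(r) == 0)
    return(list(include = FALSE, reason = "no baseline gap ratios"))
  m <- mean(r)
  if (m <= threshold) list(include = TRUE, reason = "")
  else list(include = FALSE,
            reason = sprintf("mean baseline best ratio %.3f > %.2f", m, threshold))
}

#' Per-epoch phenotype incidence
#'
#' Percentage of analyzable subjects called positive at each epoch
#' (numerators and denominators retained). Excluded subject-epochs leave the
#' denominator.
#'
#' @param calls data frame with `subject_id`, `epoch`, `decision`
#'   ("positive"/"negative"/"excluded").
#' @return data frame with `epoch`, `positives`, `n`, `percent` (one
#'   decimal; missing when the denominator is zero).
#' @export
phenotype_incidence <- function(calls) {
  ok <- calls[calls$decision != "excluded", , drop = FALSE]
  epochs <- unique(calls$epoch)
  f <- factor(ok$epoch, levels = epochs)
  pos <- tapply(ok$decision == "positive", f, sum)
  n <- tapply(ok$decision == "positive", f, length)
  out <- data.frame(epoch = epochs,
                    positives = as.integer(ifelse(is.na(pos), 0, pos)),
                    n = as.integer(ifelse(is.na(n), 0, n)))
  out$percent <- ifelse(out$n > 0, round(100 * out$positives / out$n, 1),
                        NA_real_)
  rownames(out) <- NULL
  out
}

#' Classify hyperacusis for every subject in a trial table
#'
#' Runs [hyperacusis_test()] per subject for every post-baseline epoch; a
#' subject is overall-positive when any epoch is positive.
#'
#' @param trials `startle_trials`-schema data frame (all subjects).
#' @param epochs ordered epoch labels; first is baseline.
#' @param alpha significance level.
#' @return list with `calls` (one row per subject x post epoch: `subject_id`,
#'   `group`, `epoch`, `decision`, `statistic`, `p.value`) and `overall`
#'   (`subject_id`, `group`, `positive`, `n_positive_epochs`).
#' @export
classify_hyperacusis <- function(trials, epochs, alpha = 0.05) {
  io <- trials[trials$trial_type == "IO", , drop = FALSE]
  post <- epochs[-1]
  subjects <- unique(io[, c("subject_id", "group")])
  calls <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    si <- io[io$subject_id == sid, , drop = FALSE]
    base <- si[si$epoch == epochs[1], , drop = FALSE]
    rows <- lapply(post, function(ep) {
      r <- hyperacusis_test(base, si[si$epoch == ep, , drop = FALSE], alpha)
      data.frame(subject_id = sid, group = subjects$group[i], epoch = ep,
                 decision = r$decision, statistic = r$statistic,
                 p.value = r$p.value, stringsAsFactors = FALSE)
    })
    calls[[i]] <- do.call(rbind, rows)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  key <- interaction(calls$subject_id, calls$group, drop = TRUE, sep = "\r")
  npos <- tapply(calls$decision == "positive", key, sum)
  nok <- tapply(calls$decision != "excluded", key, sum)
  keys <- do.call(rbind, strsplit(names(npos), "\r", fixed = TRUE))
  overall <- data.frame(subject_id = keys[, 1], group = keys[, 2],
                        n_positive_epochs = as.integer(npos),
                        analyzable = nok > 0,
                        positive = ifelse(nok > 0, npos > 0, NA),
                        stringsAsFactors = FALSE)
  overall <- overall[order(overall$subject_id), ]
  rownames(overall) <- NULL
  list(calls = calls, overall = overall)
}

#' Classify tinnitus for every subject in a trial table
#'
#' Computes session-level gap ratios, applies the baseline inclusion
#' criterion, then runs [tinnitus_test()] per included subject for every
#' post-baseline epoch. Subjects failing inclusion are excluded with a
#' reason; overall-positive = any positive epoch.
#'
#' @param trials `startle_trials`-schema data frame.
#' @param epochs ordered epoch labels; first is baseline.
#' @param alpha significance level.
#' @param inclusion_threshold baseline mean best-ratio criterion
#'   (see [gpias_inclusion()]).
#' @param carriers carrier order for adjacency (defaults to sorted carriers
#'   present).
#' @param method contrast protection flavor passed to [tinnitus_test()].
#' @return list with `calls` (subject x epoch rows incl. implicated
#'   frequencies), `overall` (`subject_id`, `group`, `analyzable`,
#'   `positive`), and `exclusions`.
#' @export
classify_tinnitus <- function(trials, epochs, alpha = 0.05,
                              inclusion_threshold = 0.8, carriers = NULL,
                              method = c("sidak", "lsd")) {
  method <- match.arg(method)
  ratios <- gap_ratio_table(trials)
  if (is.null(carriers)) carriers <- sort(unique(ratios$carrier_khz))
  post <- epochs[-1]
  subjects <- unique(trials[trials$trial_type %in% c("SO", "GAP"),
                            c("subject_id", "group")])
  calls <- list(); overall <- list(); exclusions <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    ri <- ratios[ratios$subject_id == sid, , drop = FALSE]
    rb <- ri[ri$epoch == epochs[1], , drop = FALSE]
    best_b <- best_daily_ratio(rb)
    inc <- gpias_inclusion(best_b, inclusion_threshold)
    if (!inc$include) {
      exclusions[[sid]] <- data.frame(subject_id = sid,
                                      group = subjects$group[i],
                                      reason = inc$reason)
      overall[[sid]] <- data.frame(subject_id = sid, group = subjects$group[i],
                                   analyzable = FALSE, positive = NA)
      next
    }
    rows <- lapply(post, function(ep) {
      r <- tinnitus_test(rb, ri[ri$epoch == ep, , drop = FALSE], alpha,
                         carriers, method)
      data.frame(subject_id = sid, group = subjects$group[i], epoch = ep,
                 decision = r$decision, p_omnibus = r$p_omnibus,
                 implicated_freqs = paste(r$implicated_freqs, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    calls[[sid]] <- rows
    overall[[sid]] <- data.frame(subject_id = sid, group = subjects$group[i],
                                 analyzable = TRUE,
                                 positive = any(rows$decision == "positive"))
  }
  calls <- do.call(rbind, calls)
  overall <- do.call(rbind, overall)
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(subject_id = character(), group = character(),
               reason = character())
  rownames(calls) <- rownames(overall) <- rownames(exclusions) <- NULL
  list(calls = calls, overall = overall, exclusions = exclusions)
}
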