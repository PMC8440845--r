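# Shared ANOVA engines. two_way_anova computes Type-II sums of squares from
# least-squares projections directly (.lm.fit) because the per-animal
# classifiers call it tens of thousands of times in the calibration suites.

rss_fit <- function(y, X) {
  if (is.null(X)) return(sum((y - mean(y))^2))
  f <- stats::.lm.fit(X, y)
  sum(f$residuals^2)
}

anova_row <- function(term, ss, df1, msr, dfr, scale) {
  ms <- ss / df1
  # degenerate designs (zero residual variance): all-equal data reports F = 0
  if (msr <= scale) {
    if (ms <= scale) return(data.frame(term = term, df = df1, sumsq = 0,
                                       meansq = 0, statistic = 0, p.value = 1))
    return(data.frame(term = term, df = df1, sumsq = ss, meansq = ms,
                      statistic = Inf, p.value = 0))
  }
  f <- ms / msr
  data.frame(term = term, df = df1, sumsq = ss, meansq = ms, statistic = f,
             p.value = pf(f, df1, dfr, lower.tail = FALSE))
}

#' Two-way (or one-way) fixed-effects ANOVA with Type-II sums of squares
#'
#' Main effects are each adjusted for the other main effect; the interaction
#' is adjusted for both (Type-II, appropriate for unbalanced data with no
#' a-priori factor ordering). With `b = NULL` it reduces to a one-way ANOVA.
#' Completely constant data reports F = 0, p = 1 for every term.
#'
#' @param y numeric response vector.
#' @param a,b factors (or vectors coercible to factors); `b` optional.
#' @return an `anova_result` data frame: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`, with a `Residuals` row.
#' @export
two_way_anova <- function(y, a, b = NULL) {
  a <- droplevels(as.factor(a))
  if (nlevels(a) < 2) stop("factor 'a' needs >= 2 levels", call. = FALSE)
  n <- length(y)
  stopifnot(length(a) == n, is.null(b) || length(b) == n)
  scale <- max(mean(y^2), .Machine$double.xmin) * 1e-12
  if (is.null(b)) {
    Xa <- model.matrix(~a)
    ss_res <- rss_fit(y, Xa)
    ss_a <- rss_fit(y, NULL) - ss_res
    dfr <- n - ncol(Xa)
    out <- rbind(anova_row("a", ss_a, nlevels(a) - 1, ss_res / dfr, dfr, scale),
                 data.frame(term = "Residuals", df = dfr, sumsq = ss_res,
                            meansq = ss_res / max(dfr, 1), statistic = NA,
                            p.value = NA))
    class(out) <- c("anova_result", "data.frame")
    return(out)
  }
  b <- droplevels(as.factor(b))
  if (nlevels(b) < 2) stop("factor 'b' needs >= 2 levels", call. = FALSE)
  Xab <- model.matrix(~ a * b)
  Xa_b <- model.matrix(~ a + b)
  Xa <- model.matrix(~a)
  Xb <- model.matrix(~b)
  rss_full <- rss_fit(y, Xab)
  rss_add <- rss_fit(y, Xa_b)
  ss_a <- rss_fit(y, Xb) - rss_add
  ss_b <- rss_fit(y, Xa) - rss_add
  ss_ab <- rss_add - rss_full
  dfr <- n - qr(Xab)$rank
  if (dfr < 1) stop("no residual degrees of freedom", call. = FALSE)
  msr <- rss_full / dfr
  out <- rbind(
    anova_row("a", ss_a, nlevels(a) - 1, msr, dfr, scale),
    anova_row("b", ss_b, nlevels(b) - 1, msr, dfr, scale),
    anova_row("a:b", ss_ab, (nlevels(a) - 1) * (nlevels(b) - 1), msr, dfr, scale),
    data.frame(term = "Residuals", df = dfr, sumsq = rss_full, meansq = msr,
               statistic = NA, p.value = NA))
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Greenhouse-Geisser epsilon of a within-subject covariance matrix
#'
#' Computed from the double-centered covariance of the k within-factor
#' levels; bounded to [1/(k-1), 1]. Covariances are estimated with pairwise
#' complete observations, so subjects with incomplete profiles still
#' contribute.
#'
#' @param M numeric matrix, subjects x within levels (cell means), `NA`
#'   allowed.
#' @return epsilon in [1/(k-1), 1].
#' @export
gg_epsilon <- function(M) {
  k <- ncol(M)
  if (k < 2) stop("need >= 2 within-subject levels", call. = FALSE)
  if (k == 2) return(1)  # sphericity trivially holds
  S <- cov(M, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  H <- diag(k) - 1 / k
  Sc <- H %*% S %*% H
  denom <- (k - 1) * sum(Sc * Sc)
  if (denom <= 0) return(1)
  eps <- sum(diag(Sc))^2 / denom
  min(1, max(eps, 1 / (k - 1)))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate repeated-measures ANOVA (optionally split-plot with one
#' between-subject factor) whose within-subject tests have their degrees of
#' freedom multiplied by the Greenhouse-Geisser epsilon estimated from the
#' (pairwise-complete) within-level covariance matrix. Replicate
#' observations per subject x level are averaged to cell means before the
#' subject-level analysis. Serves as a sphericity-robust stand-in for a
#' mixed-effects model when profiles are mildly incomplete: subjects missing
#' a level are dropped from the sums of squares (with a warning) but still
#' inform epsilon.
#'
#' @param y numeric response.
#' @param subject subject identifier (factor).
#' @param within within-subject factor (>= 2 levels per subject).
#' @param between optional between-subject factor (constant within subject).
#' @return an `anova_result` data frame with fractional GG-corrected df for
#'   within-subject terms and an `epsilon` attribute.
#' @export
rm_anova_gg <- function(y, subject, within, between = NULL) {
  subject <- droplevels(as.factor(subject))
  within <- droplevels(as.factor(within))
  k <- nlevels(within)
  if (k < 2) stop("within factor needs >= 2 levels", call. = FALSE)
  # cell means per subject x level
  cm <- tapply(y, list(subject, within), mean)
  eps <- gg_epsilon(cm)
  complete <- complete.cases(cm)
  if (!all(complete))
    warning(sprintf("%d subject(s) with incomplete within profiles dropped from SS",
                    sum(!complete)))
  cm2 <- cm[complete, , drop = FALSE]
  ns <- nrow(cm2)
  if (ns < 2) stop("need >= 2 subjects with complete profiles", call. = FALSE)
  subj_keep <- rownames(cm2)
  yl <- as.vector(cm2)
  sl <- factor(rep(subj_keep, k))
  wl <- factor(rep(colnames(cm), each = ns), levels = colnames(cm))
  scale <- max(mean(yl^2), .Machine$double.xmin) * 1e-12
  if (is.null(between)) {
    ss_total <- sum((yl - mean(yl))^2)
    ss_subj <- k * sum((rowMeans(cm2) - mean(yl))^2)
    ss_w <- ns * sum((colMeans(cm2) - mean(yl))^2)
    ss_err <- ss_total - ss_subj - ss_w
    df_w <- (k - 1) * eps
    df_e <- (ns - 1) * (k - 1) * eps
    msr <- ss_err / ((ns - 1) * (k - 1))
    ms_w <- ss_w / (k - 1)
    if (msr <= scale) {
      f <- if (ms_w <= scale) 0 else Inf
      p <- if (ms_w <= scale) 1 else 0
    } else {
      f <- ms_w / msr
      p <- pf(f, df_w, df_e, lower.tail = FALSE)
    }
    out <- data.frame(
      term = c("within", "Residuals"),
      df = c(df_w, df_e),
      sumsq = c(ss_w, ss_err),
      meansq = c(ms_w, msr),
      statistic = c(f, NA), p.value = c(p, NA))
  } else {
    bmap <- tapply(as.character(between), subject, function(x) x[1])
    bl <- factor(bmap[as.character(sl)])
    fit <- aov(yl ~ bl * wl + Error(sl))
    sm <- summary(fit)
    btab <- as.data.frame(sm[["Error: sl"]][[1]])
    wtab <- as.data.frame(sm[["Error: Within"]][[1]])
    rownames(btab) <- trimws(rownames(btab))
    rownames(wtab) <- trimws(rownames(wtab))
    gg_p <- function(row, dfe) {
      f <- wtab[row, "F value"]
      pf(f, wtab[row, "Df"] * eps, dfe * eps, lower.tail = FALSE)
    }
    dfe <- wtab["Residuals", "Df"]
    out <- data.frame(
      term = c("between", "subjects(between)", "within", "between:within",
               "Residuals"),
      df = c(btab$Df[1], btab$Df[2], wtab[1, "Df"] * eps,
             wtab[2, "Df"] * eps, dfe * eps),
      sumsq = c(btab$`Sum Sq`, wtab[1:2, "Sum Sq"], wtab["Residuals", "Sum Sq"]),
      meansq = c(btab$`Mean Sq`, wtab[1:2, "Mean Sq"],
                 wtab["Residuals", "Mean Sq"]),
      statistic = c(btab$`F value`[1], NA, wtab[1, "F value"],
                    wtab[2, "F value"], NA),
      p.value = c(btab$`Pr(>F)`[1], NA, gg_p(1, dfe), gg_p(2, dfe), NA))
  }
  rownames(out) <- NULL
  attr(out, "epsilon") <- eps
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clamped to [0, 1].
#'
#' @param p vector of raw p-values in [0, 1].
#' @param m number of comparisons in the family (default `length(p)`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Dunnett-style family-wise p-values by Monte Carlo
#'
#' Family-wise adjusted p-values for k treatment-vs-control contrasts:
#' the null distribution of max|t| over the k correlated contrasts is sampled
#' (multivariate normal numerator with the contrast correlation, shared
#' chi-square denominator), and each contrast's adjusted p is the tail
#' probability of its |t| under that maximum. Reproducible given `seed`;
#' never smaller than the unadjusted two-sided t p-value.
#'
#' @param t_stats observed contrast t statistics.
#' @param df error degrees of freedom.
#' @param corr common contrast correlation (scalar, default 0.5 as with a
#'   shared control group of equal size) or a full k x k matrix.
#' @param n_mc Monte-Carlo draws (warning below 1000).
#' @param seed integer seed for the draws.
#' @return data frame with `t`, `p_unadjusted`, `p_adjusted`.
#' @export
dunnett_mc <- function(t_stats, df, corr = 0.5, n_mc = 1e5, seed = 1) {
  k <- length(t_stats)
  stopifnot(k >= 1, df > 0)
  if (n_mc < 1000) warning("n_mc < 1000: adjusted p-values will be noisy")
  R <- if (is.matrix(corr)) corr else {
    m <- matrix(corr, k, k); diag(m) <- 1; m
  }
  maxabs <- with_stream(as.integer(seed), {
    Z <- MASS::mvrnorm(n_mc, mu = rep(0, k), Sigma = R)
    if (k == 1) Z <- matrix(Z, ncol = 1)
    denom <- sqrt(rchisq(n_mc, df) / df)
    apply(abs(Z / denom), 1, max)
  })
  p_un <- 2 * pt(-abs(t_stats), df)
  p_mc <- vapply(abs(t_stats), function(t0) mean(maxabs >= t0), numeric(1))
  data.frame(t = t_stats, p_unadjusted = p_un,
             p_adjusted = pmax(p_mc, p_un))
}

#' Fisher's (protected) least-significant-difference contrasts
#'
#' Pairwise group contrasts using the pooled error mean square of the omnibus
#' one-way ANOVA; p-values are reported unadjusted, and every contrast is
#' flagged `protected = FALSE` when the omnibus p exceeds `alpha` (the LSD
#' protection rule: contrasts are only interpretable after a significant
#' omnibus test). With two groups the LSD p equals the pooled-variance
#' t-test p exactly.
#'
#' @param y numeric response.
#' @param group group factor.
#' @param alpha protection level for the omnibus gate.
#' @param control optional group name: only contrasts vs this group are
#'   produced.
#' @return data frame of class `contrast_result`: `comparison`, `estimate`,
#'   `statistic`, `df`, `p.value`, `protected`, with the omnibus p as an
#'   attribute.
#' @export
fisher_lsd <- function(y, group, alpha = 0.05, control = NULL) {
  group <- droplevels(as.factor(group))
  om <- two_way_anova(y, group)
  p_om <- om$p.value[1]
  msr <- om$meansq[om$term == "Residuals"]
  dfr <- om$df[om$term == "Residuals"]
  means <- tapply(y, group, mean)
  ns <- tapply(y, group, length)
  lv <- levels(group)
  pairs <- if (is.null(control)) {
    t(utils::combn(lv, 2))
  } else {
    stopifnot(control %in% lv)
    cbind(setdiff(lv, control), control)
  }
  est <- means[pairs[, 1]] - means[pairs[, 2]]
  se <- sqrt(msr * (1 / ns[pairs[, 1]] + 1 / ns[pairs[, 2]]))
  tt <- ifelse(se > 0, est / se, 0)
  out <- data.frame(
    comparison = paste(pairs[, 1], "-", pairs[, 2]),
    estimate = as.numeric(est), statistic = as.numeric(tt), df = dfr,
    p.value = 2 * pt(-abs(tt), dfr),
    protected = !is.na(p_om) && p_om <= alpha)
  rownames(out) <- NULL
  attr(out, "omnibus_p") <- p_om
  class(out) <- c("contrast_result", "data.frame")
  out
}
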