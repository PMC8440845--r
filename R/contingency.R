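# Exact 2x2 incidence inference: two-sided Fisher exact test, Koopman
# asymptotic-score relative-risk intervals, and count recovery from printed
# percentages.

check_2x2 <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("2x2 table entries must be non-negative integers", call. = FALSE)
  if (a + b < 1 || c + d < 1)
    stop("both row margins must be >= 1", call. = FALSE)
  invisible(v)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins; the two-sided p-value is the sum of the
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed the observed table's probability (with a
#' relative tolerance of 1e-7 to guard floating-point ties, the mainstream
#' convention). Probabilities are computed in log space, so large tables do
#' not overflow.
#'
#' @param a,b group-1 positives and negatives.
#' @param c,d group-2 positives and negatives.
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  n1 <- a + b; n2 <- c + d; m <- a + c; n <- n1 + n2
  lo <- max(0, m - n2); hi <- min(m, n1)
  x <- lo:hi
  logp <- lchoose(n1, x) + lchoose(n2, m - x) - lchoose(n, m)
  lp_obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= lp_obs + log1p(1e-7)])))
}

koopman_score <- function(rho, x1, n1, x2, n2) {
  # chi-square score statistic for H0: p1 = rho * p2, at the constrained MLE
  A <- rho * (n1 + n2)
  B <- -(rho * (n1 + x2) + x1 + n2)
  C <- x1 + x2
  p2 <- (-B - sqrt(pmax(B^2 - 4 * A * C, 0))) / (2 * A)
  p1 <- rho * p2
  d1 <- x1 - n1 * p1
  d2 <- x2 - n2 * p2
  # guard the boundary 0/0 cases (e.g. x1 = n1 with p1 -> 1): a vanishing
  # deviation contributes nothing even when its variance term vanishes too
  t1 <- ifelse(d1 == 0, 0, d1^2 / (n1 * p1 * (1 - p1)))
  t2 <- ifelse(d2 == 0, 0, d2^2 / (n2 * p2 * (1 - p2)))
  t1 + t2
}

#' Koopman asymptotic-score confidence interval for a relative risk
#'
#' The point estimate is `(a/n1) / (c/n2)`; the interval bounds are the two
#' roots in rho of the score statistic for H0: p1 = rho * p2 (evaluated at
#' the constrained maximum-likelihood estimates) equal to the chi-square
#' quantile. Roots are found by bracketed search on log(rho) (the score
#' function is monotone on each side of the point estimate). `a = 0` gives a
#' zero lower bound; `c = 0` gives an infinite upper bound; `a = c = 0` is
#' undefined.
#'
#' @param a,b,c,d table counts as in [fisher_exact_2x2()].
#' @param conf_level confidence level (default 0.95).
#' @return a list with `rr`, `ci_low`, `ci_high`, `conf_level`, and
#'   `method = "koopman"`; all `NA` (with a `reason`) when `a = c = 0`.
#' @export
koopman_rr_ci <- function(a, b, c, d, conf_level = 0.95) {
  check_2x2(a, b, c, d)
  x1 <- a; n1 <- a + b; x2 <- c; n2 <- c + d
  if (x1 == 0 && x2 == 0)
    return(list(rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                conf_level = conf_level, method = "koopman",
                reason = "no positives in either group"))
  crit <- qchisq(conf_level, 1)
  f <- function(lr) koopman_score(exp(lr), x1, n1, x2, n2) - crit
  rr <- if (x2 == 0) Inf else (x1 / n1) / (x2 / n2)
  # an interior point near the score minimum (the constrained MLE)
  lmid <- if (x1 == 0) log(1e-8) else if (!is.finite(rr)) log(1e8) else log(rr)
  lower <- if (x1 == 0) 0 else {
    lo <- lmid - 1
    while (f(lo) < 0) lo <- lo - 1
    exp(uniroot(f, c(lo, lmid), tol = 1e-12)$root)
  }
  upper <- if (x2 == 0) Inf else {
    hi <- lmid + 1
    while (f(hi) < 0) hi <- hi + 1
    exp(uniroot(f, c(lmid, hi), tol = 1e-12)$root)
  }
  list(rr = rr, ci_low = lower, ci_high = upper, conf_level = conf_level,
       method = "koopman")
}

#' Recover counts behind a printed percentage
#'
#' Scans candidate denominators for all `(numerator, denominator)` pairs
#' whose percentage rounds (one decimal) to the printed value, ranked by the
#' absolute discrepancy. An empty result means no candidate matches; callers
#' must not silently guess.
#'
#' @param pct printed percentage with one decimal (e.g. 39.3).
#' @param candidate_denominators vector of plausible denominators (>= 1).
#' @return data frame with `numerator`, `denominator`, `pct_exact`,
#'   `abs_error`, ordered by `abs_error` (possibly zero rows).
#' @export
counts_from_percent <- function(pct, candidate_denominators) {
  stopifnot(length(candidate_denominators) >= 1,
            all(candidate_denominators >= 1))
  rows <- lapply(sort(unique(candidate_denominators)), function(n) {
    aa <- 0:n
    p <- 100 * aa / n
    keep <- round(p, 1) == round(pct, 1)
    if (!any(keep)) return(NULL)
    data.frame(numerator = aa[keep], denominator = n, pct_exact = p[keep],
               abs_error = abs(p[keep] - pct))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(numerator = integer(), denominator = integer(),
                      pct_exact = numeric(), abs_error = numeric()))
  out <- out[order(out$abs_error, out$denominator), ]
  rownames(out) <- NULL
  out
}
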