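# Load-cell force traces: canonical startle template, template-matching trial
# validation, and force -> center-of-mass-displacement (CMD) conversion.

#' Canonical startle waveform template
#'
#' A damped sinusoid (the stereotyped whole-body startle transient on a
#' load-cell platform), stored zero-mean and unit-norm together with the
#' similarity threshold used by [classify_trial()].
#'
#' @param sample_rate_hz sampling rate of the traces it will be matched to.
#' @param duration_s template length in seconds.
#' @param freq_hz oscillation frequency of the startle transient.
#' @param tau_s exponential decay time constant.
#' @param threshold decision threshold on the normalized cross-correlation
#'   score, in (0, 1).
#' @return an object of class `startle_template`.
#' @export
startle_template <- function(sample_rate_hz = 1000, duration_s = 0.1,
                             freq_hz = 40, tau_s = 0.03, threshold = 0.5) {
  stopifnot(sample_rate_hz > 0, duration_s > 0, threshold > 0, threshold < 1)
  t <- seq(0, duration_s, by = 1 / sample_rate_hz)
  w <- exp(-t / tau_s) * sin(2 * pi * freq_hz * t)
  w <- w - mean(w)
  w <- w / sqrt(sum(w^2))
  structure(list(samples = w, threshold = threshold,
                 sample_rate_hz = sample_rate_hz),
            class = "startle_template")
}

#' Classify a force trace as startle or non-startle by template matching
#'
#' The similarity score is the maximum Pearson correlation between the
#' template and every same-length window of the trace (normalized
#' cross-correlation over all alignments), so the decision is invariant to
#' scaling and offset of the trace. Windows with zero variance score 0: a
#' flat trace is definitionally a non-startle.
#'
#' @param trace numeric force samples, at least as long as the template.
#' @param template a [startle_template()].
#' @return a list with `startle` (logical), `score` in [-1, 1], and the
#'   `threshold` applied.
#' @export
classify_trial <- function(trace, template) {
  stopifnot(inherits(template, "startle_template"))
  if (any(!is.finite(trace)))
    stop("trace contains non-finite samples", call. = FALSE)
  m <- length(template$samples)
  if (length(trace) < m)
    stop("trace is shorter than the template", call. = FALSE)
  tpl <- template$samples  # zero-mean, unit-norm by construction
  W <- stats::embed(trace, m)[, m:1, drop = FALSE]  # windows, in time order
  num <- as.vector(W %*% tpl)                       # sum(w * tpl), tpl centered
  ssq <- rowSums(W^2) - m * rowMeans(W)^2           # centered sum of squares
  score <- ifelse(ssq > m * .Machine$double.eps * max(1, max(W^2)),
                  num / sqrt(ssq), 0)
  s <- max(score)
  list(startle = s >= template$threshold, score = s,
       threshold = template$threshold)
}

#' Convert a load-cell force trace to center-of-mass displacement (mm)
#'
#' Acceleration is (force - pre-stimulus baseline mean) / mass; displacement
#' follows by trapezoidal double integration. The reported CMD is the
#' peak-to-peak (max - min) displacement inside the response window. Linear
#' in force amplitude.
#'
#' @param trace force samples in newtons.
#' @param mass_g animal mass in grams (> 0).
#' @param sample_rate_hz sampling rate (> 0).
#' @param baseline_s length of the pre-stimulus baseline window at the start
#'   of the trace (seconds).
#' @param response_s length of the post-onset response window scored for CMD
#'   (seconds); capped at the trace end.
#' @return CMD in millimetres (>= 0).
#' @export
force_to_cmd <- function(trace, mass_g, sample_rate_hz,
                         baseline_s = 0.1, response_s = 0.1) {
  if (!is.numeric(mass_g) || mass_g <= 0)
    stop("mass_g must be positive", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive", call. = FALSE)
  nb <- max(1L, min(length(trace) - 1L, round(baseline_s * sample_rate_hz)))
  accel <- (trace - mean(trace[seq_len(nb)])) / (mass_g / 1000)  # m/s^2
  dt <- 1 / sample_rate_hz
  vel <- pracma::cumtrapz(accel) * dt
  disp <- pracma::cumtrapz(vel) * dt                              # metres
  i0 <- nb + 1L
  i1 <- min(length(trace), nb + round(response_s * sample_rate_hz) + 1L)
  win <- disp[i0:i1]
  as.numeric(max(win) - min(win)) * 1000
}

#' Simulate a load-cell force waveform for one trial
#'
#' Startle traces are the damped-sinusoid template scaled so that
#' [force_to_cmd()] recovers the trial's nominal CMD exactly when
#' `noise_sd = 0`; non-startle traces are slow drift with no template
#' component. The trace starts with `baseline_s` of pre-stimulus baseline.
#'
#' @param cmd_mm nominal CMD of the trial (mm).
#' @param is_startle logical; simulate a true startle or a non-startle trial.
#' @param mass_g,sample_rate_hz,baseline_s,response_s as in [force_to_cmd()].
#' @param template a [startle_template()] providing the canonical shape.
#' @param noise_sd additive Gaussian force noise SD (newtons).
#' @param total_s total trace duration (seconds).
#' @return numeric force trace (newtons).
#' @export
simulate_force_waveform <- function(cmd_mm, is_startle = TRUE, mass_g = 25,
                                    sample_rate_hz = 1000, baseline_s = 0.1,
                                    response_s = 0.1,
                                    template = startle_template(sample_rate_hz),
                                    noise_sd = 0, total_s = 0.35) {
  n <- round(total_s * sample_rate_hz)
  nb <- round(baseline_s * sample_rate_hz)
  trace <- numeric(n)
  if (is_startle) {
    pulse <- template$samples
    idx <- nb + seq_along(pulse)
    idx <- idx[idx <= n]
    unit <- numeric(n)
    unit[idx] <- pulse[seq_along(idx)]
    cmd_unit <- force_to_cmd(unit, mass_g, sample_rate_hz, baseline_s, response_s)
    trace <- unit * (cmd_mm / cmd_unit)
  } else {
    t <- seq_len(n) / sample_rate_hz
    trace <- 0.02 * sin(2 * pi * 1.5 * t)   # slow postural drift, no template
  }
  if (noise_sd > 0) trace <- trace + rnorm(n, 0, noise_sd)
  trace
}
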