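#' Exponential photobleaching correction
#'
#' Fits `a * exp(-t / tau) + c` to a single fluorescence channel by least
#' squares and divides the trace by the fitted curve (multiplicative
#' detrend: bleaching scales fluorescence, so a perfectly exponential
#' channel is flattened to 1). Near-constant input takes the `a -> 0`
#' branch and is returned unchanged; a failed fit returns the identity
#' correction with a warning flag.
#'
#' @param trace Numeric fluorescence channel (>= 100 samples).
#' @param time Sample times in seconds (same length).
#' @return List with `corrected`, fit parameters `a`, `tau`, `c`,
#'   `fitted`, and `failed` flag.
#' @export
bleach_correct <- function(trace, time) {
  n <- length(trace)
  if (n < 100L) stop("bleach correction needs >= 100 samples")
  if (length(time) != n) stop("time and trace lengths differ")
  if (stats::sd(trace) < 1e-12 * (abs(mean(trace)) + 1)) {
    return(list(corrected = trace, a = 0, tau = NA_real_, c = mean(trace),
                fitted = rep(mean(trace), n), failed = FALSE))
  }
  t0 <- time - time[1]
  span <- max(t0)
  st <- list(a = trace[1] - trace[n], tau = span / 3,
             c = min(trace[n], trace[1]))
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-tt / tau) + c,
               data = data.frame(y = trace, tt = t0), start = st,
               control = stats::nls.control(warnOnly = TRUE, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-tt / tau) + c,
                        data = data.frame(y = trace, tt = t0), start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    warning("bleaching fit failed; identity correction applied")
    return(list(corrected = trace, a = NA_real_, tau = NA_real_,
                c = NA_real_, fitted = rep(1, n), failed = TRUE))
  }
  cf <- stats::coef(fit)
  fitted <- cf[["a"]] * exp(-t0 / cf[["tau"]]) + cf[["c"]]
  # a degenerate fit (flat or noisy channels) must not distort the trace:
  # the fitted curve has to stay well inside the data's own scale
  lo <- if (min(trace) > 0) 0.5 * min(trace) else 1e-9 * max(abs(trace))
  if (any(!is.finite(fitted)) || min(fitted) < lo ||
      max(abs(fitted)) > 5 * max(abs(trace))) {
    warning("bleaching fit degenerate; identity correction applied")
    return(list(corrected = trace, a = cf[["a"]], tau = cf[["tau"]],
                c = cf[["c"]], fitted = rep(1, n), failed = TRUE))
  }
  list(corrected = trace / fitted, a = unname(cf["a"]),
       tau = unname(cf["tau"]), c = unname(cf["c"]), fitted = fitted,
       failed = FALSE)
}

#' Ratiometric fluorescence change
#'
#' `dF/F = (F_sig - F_iso) / F_iso`, pointwise, on bleach-corrected
#' channels; the isosbestic channel is the calcium-insensitive control.
#'
#' @param F_sig Signal-channel fluorescence.
#' @param F_iso Isosbestic-channel fluorescence (bounded away from 0).
#' @return Numeric dF/F trace.
#' @export
dff <- function(F_sig, F_iso) {
  if (length(F_sig) != length(F_iso)) stop("channel lengths differ")
  bad <- which(abs(F_iso) < 1e-9)
  if (length(bad) > 0L)
    stop(sprintf("near-zero isosbestic samples at indices: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  (F_sig - F_iso) / F_iso
}

#' Z-score a trace against a baseline definition
#'
#' @param trace Numeric trace.
#' @param time Sample times in seconds (required for `"window"` and
#'   `"per_event"` baselines).
#' @param baseline `"whole"` (whole-trace statistics), `"window"` (mean/sd
#'   from `t0 <= time <= t1`, e.g. the 0-200 s session baseline), or
#'   `"per_event"` (additionally subtracts the event-local window mean
#'   around each event before session-level scaling).
#' @param t0,t1 Baseline window bounds (seconds) for `"window"`.
#' @param events Event times in seconds for `"per_event"`.
#' @param pre,post Event-local window half-widths in seconds (default the
#'   -2 to +2 s convention).
#' @return Z-scored trace.
#' @export
zscore_trace <- function(trace, time = NULL,
                         baseline = c("whole", "window", "per_event"),
                         t0 = 0, t1 = 200, events = NULL, pre = 2, post = 2) {
  baseline <- match.arg(baseline)
  if (baseline != "whole" && is.null(time))
    stop("time required for window / per_event baselines")
  if (baseline == "window") {
    sel <- time >= t0 & time <= t1
    if (sum(sel) < 2L) stop("degenerate baseline window")
    mu <- mean(trace[sel]); s <- stats::sd(trace[sel])
  } else {
    mu <- mean(trace); s <- stats::sd(trace)
  }
  if (!is.finite(s) || s == 0) stop("zero baseline variance")
  out <- trace - mu
  if (baseline == "per_event") {
    if (is.null(events)) stop("per_event baseline requires event times")
    for (te in events) {
      sel <- time >= te - pre & time <= te + post
      if (any(sel)) out[sel] <- out[sel] - mean(out[sel])
    }
  }
  out / s
}

#' Zero-phase low-pass filter
#'
#' Second-order Butterworth filter applied forward and backward
#' (`signal::filtfilt`), so filtered events are not shifted in time. The
#' 0.3 Hz default isolates the slow oscillatory component of calcium
#' traces.
#'
#' @param trace Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), `0 < cutoff < fs/2`.
#' @return Filtered trace.
#' @export
lowpass <- function(trace, fs, cutoff = 0.3) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must satisfy 0 < cutoff < fs/2")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  # odd-reflection padding so the forward-backward pass settles before the
  # data starts (filtfilt itself applies zero initial conditions)
  n <- length(trace)
  pad <- min(n - 1L, ceiling(6 * fs / cutoff))
  left <- 2 * trace[1] - trace[seq(pad + 1L, 2L)]
  right <- 2 * trace[n] - trace[seq(n - 1L, n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(left, trace, right)))
  y[seq(pad + 1L, pad + n)]
}

# Topographic prominence of local extrema at positions idx of y (maxima).
peak_prominence <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    h <- y[i]
    lmin <- h; k <- i
    while (k > 1L) { k <- k - 1L; if (y[k] > h) break; lmin <- min(lmin, y[k]) }
    left_ok <- k >= 1L && y[k] > h
    rmin <- h; k <- i
    while (k < n) { k <- k + 1L; if (y[k] > h) break; rmin <- min(rmin, y[k]) }
    right_ok <- k <= n && y[k] > h
    # key saddle: towards higher ground where it exists, else global descent
    base <- if (left_ok && right_ok) max(lmin, rmin)
    else if (left_ok) lmin
    else if (right_ok) rmin
    else min(lmin, rmin)
    h - base
  }, numeric(1))
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Classify a slow event-aligned signal as trough, state-change, or peak
#'
#' Searches the classification window (the -1 to +1 s convention around
#' licking onset) for local extrema with topographic prominence at least
#' `prominence_z` (computed on the full trace). The qualifying extremum of
#' largest absolute value decides the class by its sign: negative gives
#' `"trough"`, positive gives `"peak"`. A trace with no prominent extremum
#' in the window -- e.g. a smooth polarity reversal -- is a
#' `"state_change"` signal.
#'
#' @param trace Aligned mean trace (z units).
#' @param rel_time Relative time of each sample (seconds, 0 at event).
#' @param window Classification window `c(lo, hi)` (default `c(-1, 1)`).
#' @param prominence_z Prominence threshold in z units (default 1).
#' @return One of `"trough"`, `"state_change"`, `"peak"`.
#' @export
classify_slow_signal <- function(trace, rel_time, window = c(-1, 1),
                                 prominence_z = 1) {
  if (length(trace) != length(rel_time))
    stop("trace and rel_time lengths differ")
  if (min(rel_time) > window[1] || max(rel_time) < window[2])
    stop("rel_time does not cover the classification window")
  in_win <- rel_time >= window[1] & rel_time <= window[2]
  cand <- data.frame(idx = integer(0), val = numeric(0))
  mx <- local_maxima(trace)
  mx <- mx[in_win[mx]]
  if (length(mx) > 0L) {
    keep <- peak_prominence(trace, mx) >= prominence_z
    cand <- rbind(cand, data.frame(idx = mx[keep], val = trace[mx[keep]]))
  }
  mn <- local_maxima(-trace)
  mn <- mn[in_win[mn]]
  if (length(mn) > 0L) {
    keep <- peak_prominence(-trace, mn) >= prominence_z
    cand <- rbind(cand, data.frame(idx = mn[keep], val = trace[mn[keep]]))
  }
  if (nrow(cand) == 0L) return("state_change")
  best <- cand$val[which.max(abs(cand$val))]
  if (best < 0) "trough" else "peak"
}

#' Least-squares slopes over reward-aligned epochs
#'
#' Fits a line to the trace within each epoch (default the pre-reward
#' -4 to 0 s, reward 0 to 4 s, and post-reward 4 to 8 s periods) and
#' returns the slope in z/s. Epochs not covered by the trace give `NA`.
#'
#' @param trace Aligned mean trace.
#' @param rel_time Relative time (seconds).
#' @param epochs List of `c(lo, hi)` pairs.
#' @return Named numeric vector of slopes.
#' @export
epoch_slopes <- function(trace, rel_time,
                         epochs = list(pre = c(-4, 0), reward = c(0, 4),
                                       post = c(4, 8))) {
  out <- vapply(epochs, function(ep) {
    sel <- rel_time >= ep[1] & rel_time <= ep[2]
    if (sum(sel) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(trace[sel] ~ rel_time[sel]))[2])
  }, numeric(1))
  if (any(is.na(out))) warning("some epochs not covered by the trace")
  out
}

#' Fast-transient amplitude per event occurrence
#'
#' For each event of the requested label: maximal z in the (0, +1 s]
#' post-event window minus the mean z in the [-1 s, 0) pre-event baseline.
#'
#' @param trace Z-scored trace.
#' @param time Sample times (seconds).
#' @param events Data frame with columns `label`, `time_s`.
#' @param label Event label to quantify.
#' @param window `c(pre, post)` extent in seconds (default `c(-1, 1)`).
#' @return Numeric vector, one amplitude per occurrence.
#' @export
fast_transient_amplitude <- function(trace, time, events, label,
                                     window = c(-1, 1)) {
  te <- events$time_s[events$label == label]
  if (length(te) == 0L) stop(sprintf("no events with label '%s'", label))
  vapply(te, function(e) {
    pre <- trace[time >= e + window[1] & time < e]
    post <- trace[time > e & time <= e + window[2]]
    if (length(pre) == 0L || length(post) == 0L) return(NA_real_)
    max(post) - mean(pre)
  }, numeric(1))
}

#' Sum of peak and trough mean traces, compared to a reference
#'
#' The population-integration property: summing the average peak-class and
#' trough-class traces yields a composite whose rank (Spearman)
#' correlation against a reference (typically the mean state-change trace)
#' is reported.
#'
#' @param peak_trace,trough_trace Mean traces on a common relative-time
#'   grid.
#' @param reference Optional reference trace on the same grid.
#' @return List with `composite` and `spearman` (NA if no reference).
#' @export
composite_sum <- function(peak_trace, trough_trace, reference = NULL) {
  if (length(peak_trace) != length(trough_trace))
    stop("trace grids differ in length")
  comp <- peak_trace + trough_trace
  r <- NA_real_
  if (!is.null(reference)) {
    if (length(reference) != length(comp))
      stop("reference grid differs in length")
    r <- stats::cor(comp, reference, method = "spearman")
  }
  list(composite = comp, spearman = r)
}

# Slow-class waveforms (time in seconds relative to lick onset):
# peak rises into the onset and dips after the reward window; trough is its
# temporal mirror with a late positive rebound; state-change is defined as
# the exact peak + trough mixture, a smooth polarity reversal across the
# onset (its transition extrema sit near +/-1.7 s, outside the -1..+1 s
# classification window) with a second reversal after the reward epoch.
slow_template <- function(t, class, amplitude = 1) {
  g <- function(mu, sig) exp(-(t - mu)^2 / (2 * sig^2))
  peak <- g(-0.5, 1.5) - 0.4 * g(4, 2)
  trough <- -g(0.5, 1.5) + 0.6 * g(6, 2)
  base <- switch(class,
    peak = peak,
    trough = trough,
    state_change = peak + trough,
    stop("unknown signal class"))
  amplitude * base
}

#' Specification for the synthetic two-channel photometry generator
#'
#' @param fs Sampling rate in Hz (default 20; the arithmetic is
#'   rate-independent, this keeps simulations fast).
#' @param n_trials Number of simulated trials.
#' @param trial_length Seconds per trial including the inter-trial baseline
#'   (default 24; task events occupy the first ~11 s).
#' @param signal_class Planted slow-signal class: `"trough"`,
#'   `"state_change"` (constructed as the peak + trough mixture), or
#'   `"peak"`.
#' @param slow_amplitude Slow-template amplitude in dF/F units.
#' @param fast_events Data frame (`label`, `amplitude`, `decay_s`) of
#'   event-locked exponential-decay transients (dF/F units), or NULL.
#' @param bleach_tau Photobleaching time constant (seconds).
#' @param bleach_frac Fraction of fluorescence lost asymptotically
#'   (`[0, 1)`; 0 disables bleaching).
#' @param noise_sd Additive Gaussian noise sd per channel (fluorescence
#'   units; baseline fluorescence is 1).
#' @param seed Optional seed for reproducible generation.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(fs = 20, n_trials = 20L, trial_length = 24,
                       signal_class = c("state_change", "trough", "peak"),
                       slow_amplitude = 0.05, fast_events = NULL,
                       bleach_tau = 300, bleach_frac = 0.3,
                       noise_sd = 0.01, seed = NULL) {
  signal_class <- match.arg(signal_class)
  if (bleach_frac < 0 || bleach_frac >= 1) stop("bleach_frac in [0, 1)")
  if (fs <= 0.6) stop("fs must exceed twice the 0.3 Hz low-pass cutoff")
  spec <- list(fs = fs, n_trials = as.integer(n_trials),
               trial_length = trial_length, signal_class = signal_class,
               slow_amplitude = slow_amplitude, fast_events = fast_events,
               bleach_tau = bleach_tau, bleach_frac = bleach_frac,
               noise_sd = noise_sd, seed = seed)
  class(spec) <- "synth_spec"
  spec
}

#' Generate a synthetic two-channel photometry session
#'
#' Simulates the trial structure of the sequence task (trigger entry/exit,
#' reward-zone entry/exit, reward onset, lick onset per trial), plants the
#' requested slow-class waveform around each lick onset plus optional fast
#' exponential-decay transients at chosen events, multiplies both channels
#' by an exponential photobleaching profile, and adds independent Gaussian
#' noise per channel. The isosbestic channel carries bleaching and noise
#' but no signal. Ground truth (clean dF/F, class, spec) is stored
#' alongside.
#'
#' @param spec A [synth_spec()].
#' @return A `trace_set`: `time`, `F_sig`, `F_iso`, `events` (data frame
#'   `label`, `time_s`), `fs`, and `truth`.
#' @export
generate_traces <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lead <- 10
  duration <- lead + spec$n_trials * spec$trial_length + 10
  time <- seq(0, duration, by = 1 / spec$fs)
  n <- length(time)
  starts <- lead + (seq_len(spec$n_trials) - 1L) * spec$trial_length
  offs <- c(trigger_entry = 1, trigger_exit = 3, reward_zone_entry = 5,
            reward_onset = 7, lick_onset = 7.2, reward_zone_exit = 11)
  events <- do.call(rbind, lapply(starts, function(s0) {
    data.frame(label = names(offs), time_s = s0 + unname(offs),
               stringsAsFactors = FALSE)
  }))
  sig <- numeric(n)
  for (tl in events$time_s[events$label == "lick_onset"]) {
    sel <- abs(time - tl) <= 8
    sig[sel] <- sig[sel] + slow_template(time[sel] - tl, spec$signal_class,
                                         spec$slow_amplitude)
  }
  if (!is.null(spec$fast_events)) {
    for (i in seq_len(nrow(spec$fast_events))) {
      fe <- spec$fast_events[i, ]
      for (te in events$time_s[events$label == fe$label]) {
        sel <- time >= te & time <= te + 6 * fe$decay_s
        sig[sel] <- sig[sel] + fe$amplitude * exp(-(time[sel] - te) / fe$decay_s)
      }
    }
  }
  bleach <- (1 - spec$bleach_frac) + spec$bleach_frac * exp(-time / spec$bleach_tau)
  F0 <- 1
  F_sig <- F0 * (1 + sig) * bleach + stats::rnorm(n, 0, spec$noise_sd)
  F_iso <- F0 * bleach + stats::rnorm(n, 0, spec$noise_sd)
  structure(list(time = time, F_sig = F_sig, F_iso = F_iso, events = events,
                 fs = spec$fs,
                 truth = list(dff = sig, class = spec$signal_class,
                              spec = spec)),
            class = "trace_set")
}

#' Standard analysis pipeline for a two-channel trace set
#'
#' Bleach-corrects each channel, forms dF/F, z-scores (whole-session
#' baseline), isolates the slow component with the 0.3 Hz zero-phase
#' low-pass, aligns to an event, averages across occurrences, and
#' classifies the slow signal.
#'
#' @param ts A `trace_set` (from [generate_traces()] or [read_traces()]).
#' @param align Event label to align on (default `"lick_onset"`).
#' @param window Alignment window in seconds `c(pre, post)`; the default
#'   `c(4, 4)` covers the reward epoch so extremum prominence is measured
#'   against the waveform's full local descent.
#' @param prominence_z Classifier prominence threshold.
#' @param do_lowpass Apply the 0.3 Hz zero-phase low-pass before alignment
#'   (default TRUE; disable to classify on the broadband trace).
#' @return List with `class`, `mean_trace`, `rel_time`, `z`, `aligned`.
#' @export
photometry_pipeline <- function(ts, align = "lick_onset", window = c(4, 4),
                                prominence_z = 1, do_lowpass = TRUE) {
  bs <- bleach_correct(ts$F_sig, ts$time)
  bi <- bleach_correct(ts$F_iso, ts$time)
  d <- dff(bs$corrected, bi$corrected)
  z <- zscore_trace(d, ts$time, baseline = "whole")
  if (do_lowpass) z <- lowpass(z, ts$fs, 0.3)
  te <- ts$events$time_s[ts$events$label == align]
  rel <- seq(-window[1], window[2], by = 1 / ts$fs)
  mat <- t(vapply(te, function(e) {
    stats::approx(ts$time, z, xout = e + rel, rule = 1)$y
  }, numeric(length(rel))))
  m <- colMeans(mat, na.rm = TRUE)
  cls <- classify_slow_signal(m, rel, window = c(-1, 1),
                              prominence_z = prominence_z)
  list(class = cls, mean_trace = m, rel_time = rel, z = z, aligned = mat)
}

#' Write / read trace sets as CSV
#'
#' Traces: columns `time_s`, `F_sig`, `F_iso`; events: `label`, `time_s`.
#'
#' @param ts A `trace_set`.
#' @param traces_path,events_path Output CSV paths.
#' @export
write_traces <- function(ts, traces_path, events_path) {
  utils::write.csv(data.frame(time_s = ts$time, F_sig = ts$F_sig,
                              F_iso = ts$F_iso),
                   traces_path, row.names = FALSE)
  utils::write.csv(ts$events, events_path, row.names = FALSE)
  invisible(c(traces_path, events_path))
}

#' @rdname write_traces
#' @param fs Sampling rate; inferred from timestamps when NULL.
#' @return `read_traces` returns a `trace_set`.
#' @export
read_traces <- function(traces_path, events_path, fs = NULL) {
  tr <- utils::read.csv(traces_path)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  if (is.null(fs)) fs <- 1 / stats::median(diff(tr$time_s))
  if (any(diff(tr$time_s) <= 0)) stop("time must be strictly increasing")
  if (any(ev$time_s < min(tr$time_s) | ev$time_s > max(tr$time_s)))
    stop("event timestamps outside trace span")
  structure(list(time = tr$time_s, F_sig = tr$F_sig, F_iso = tr$F_iso,
                 events = ev, fs = fs, truth = NULL), class = "trace_set")
}
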