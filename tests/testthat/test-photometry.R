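test_that("bleaching correction flattens exponentials and spares constants", {
  t_ <- seq(0, 600, by = 0.1)
  pure <- 2.5 * exp(-t_ / 150)
  bc <- bleach_correct(pure, t_)
  expect_false(bc$failed)
  expect_equal(bc$corrected, rep(1, length(t_)), tolerance = 1e-6)
  expect_equal(bc$tau, 150, tolerance = 1e-3)

  const <- rep(3, 200)
  bc2 <- bleach_correct(const, seq_along(const))
  expect_equal(bc2$a, 0)
  expect_identical(bc2$corrected, const)
  expect_error(bleach_correct(1:50, 1:50), "100 samples")
})

test_that("planted bleaching constants are recovered from the generator", {
  spec <- synth_spec(n_trials = 40, bleach_tau = 300, bleach_frac = 0.4,
                     noise_sd = 0.005, seed = 5)
  ts <- generate_traces(spec)
  bc <- bleach_correct(ts$F_iso, ts$time)
  expect_false(bc$failed)
  expect_lt(abs(bc$tau - 300) / 300, 0.10)
})

test_that("the ratiometric formula is exact and scale-invariant", {
  expect_equal(dff(c(1.2, 0.9, 1), c(1, 1, 1)), c(0.2, -0.1, 0))
  x <- runif(50, 0.8, 1.2); y <- runif(50, 0.9, 1.1)
  expect_equal(dff(x, y), dff(3.7 * x, 3.7 * y), tolerance = 1e-12)
  expect_equal(dff(y, y), rep(0, 50))
  expect_error(dff(c(1, 1), c(1, 0)), "isosbestic")
})

test_that("z-scoring honors its baseline definitions", {
  tr <- c(rep(5, 50), 9, rep(5, 49))
  tm <- seq_along(tr)
  z <- zscore_trace(tr, tm, baseline = "window", t0 = 1, t1 = 100)
  mu <- mean(tr[1:100]); s <- sd(tr[1:100])
  expect_equal(z[51], (9 - mu) / s)

  set.seed(6)
  x <- rnorm(500)
  z2 <- zscore_trace(x)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)

  # per-event mode removes constant per-trial offsets
  tm3 <- seq(0, 40, by = 0.1)
  off <- ifelse(tm3 < 20, 1.5, -1.5)
  base <- sin(tm3 / 2)
  z3 <- zscore_trace(base + off, tm3, baseline = "per_event",
                     events = c(10, 30), pre = 2, post = 2)
  seg1 <- z3[tm3 >= 8 & tm3 <= 12]; seg2 <- z3[tm3 >= 28 & tm3 <= 32]
  expect_equal(mean(seg1), mean(seg2), tolerance = 1e-10)
  expect_error(zscore_trace(rep(1, 10)), "variance")
})

test_that("the zero-phase low-pass keeps slow and kills fast components", {
  fs <- 20
  t_ <- seq(0, 200, by = 1 / fs)
  expect_equal(lowpass(rep(2, 1000), fs, 0.3), rep(2, 1000),
               tolerance = 1e-6)
  slow <- sin(2 * pi * 0.05 * t_)
  ls <- lowpass(slow, fs, 0.3)
  mid <- t_ > 50 & t_ < 150
  expect_gt(max(abs(ls[mid])) / max(abs(slow[mid])), 0.95)
  fast <- sin(2 * pi * 5 * t_)
  lf <- lowpass(fast, fs, 0.3)
  expect_lt(max(abs(lf[mid])) / max(abs(fast[mid])), 0.1)
  expect_error(lowpass(slow, fs, 11), "cutoff")
})

test_that("template extrema drive the slow-signal classes", {
  rel <- seq(-3, 3, by = 0.05)
  expect_equal(classify_slow_signal(-2 * exp(-rel^2 / 2), rel), "trough")
  expect_equal(classify_slow_signal(2 * exp(-rel^2 / 2), rel), "peak")
  ramp <- -1.5 * tanh(rel)  # smooth polarity reversal, no extremum
  expect_equal(classify_slow_signal(ramp, rel), "state_change")
  expect_error(classify_slow_signal(ramp, rel, window = c(-5, 5)), "cover")
})

test_that("classification survives constant offsets through z-scoring", {
  spec <- synth_spec(n_trials = 10, signal_class = "trough",
                     slow_amplitude = 0.05, bleach_frac = 0,
                     noise_sd = 0.005, seed = 7)
  ts <- generate_traces(spec)
  out1 <- photometry_pipeline(ts)
  ts2 <- ts
  ts2$F_sig <- ts2$F_sig + 0.5
  ts2$F_iso <- ts2$F_iso + 0.5
  # identical additive offset on both channels shifts dF/F by a constant
  # scale only; session z-scoring absorbs it
  out2 <- photometry_pipeline(ts2)
  expect_identical(out1$class, out2$class)
  expect_identical(out1$class, "trough")
})

test_that("planted slow classes are recovered at moderate SNR", {
  # z-SNR 2: template amplitude twice the dF/F noise sd
  amp <- 0.05
  noise <- amp / (2 * sqrt(2))  # per channel; dF/F noise is sqrt(2) larger
  n_per <- 20
  hits <- 0; total <- 0
  for (cls in c("trough", "state_change", "peak")) {
    for (k in seq_len(n_per)) {
      ts <- generate_traces(synth_spec(n_trials = 12, signal_class = cls,
                                       slow_amplitude = amp,
                                       bleach_frac = 0, noise_sd = noise,
                                       seed = 1000 + 10 * k +
                                         match(cls, c("trough",
                                                      "state_change",
                                                      "peak"))))
      out <- photometry_pipeline(ts)
      hits <- hits + (out$class == cls)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("epoch slopes are exact least squares", {
  rel <- seq(-4, 8, by = 0.1)
  expect_equal(unname(epoch_slopes(rel, rel)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(unname(epoch_slopes(rep(2, length(rel)), rel)), c(0, 0, 0))
  piece <- ifelse(rel < 0, 0.5 * rel,
                  ifelse(rel < 4, -0.25 * rel, -1))
  sl <- epoch_slopes(piece, rel)
  expect_equal(unname(sl), c(0.5, -0.25, 0), tolerance = 1e-9)
  expect_warning(epoch_slopes(piece[rel <= 4], rel[rel <= 4]), "covered")
})

test_that("fast transients are quantified as post-peak minus pre-baseline", {
  fs <- 20
  t_ <- seq(0, 100, by = 1 / fs)
  ev <- data.frame(label = "trigger_exit", time_s = c(20, 50, 80))
  z <- numeric(length(t_))
  for (e in ev$time_s) {
    sel <- t_ >= e
    z[sel] <- z[sel] + 3 * exp(-(t_[sel] - e) / 0.5)
  }
  amp <- fast_transient_amplitude(z, t_, ev, "trigger_exit")
  expect_equal(amp, rep(3, 3) * exp(-(1 / fs) / 0.5), tolerance = 1e-9)
  expect_equal(fast_transient_amplitude(rep(0, length(t_)), t_, ev,
                                        "trigger_exit"), rep(0, 3))
  expect_error(fast_transient_amplitude(z, t_, ev, "lick_onset"), "label")
})

test_that("transient amplitudes recover from the generator within error", {
  fe <- data.frame(label = "trigger_exit", amplitude = 0.04, decay_s = 0.4)
  ts <- generate_traces(synth_spec(n_trials = 50, slow_amplitude = 0,
                                   fast_events = fe, bleach_frac = 0,
                                   noise_sd = 0.004, seed = 8))
  bs <- bleach_correct(ts$F_sig, ts$time)
  bi <- bleach_correct(ts$F_iso, ts$time)
  d <- dff(bs$corrected, bi$corrected)
  amps <- fast_transient_amplitude(d, ts$time, ts$events, "trigger_exit")
  # in dF/F units: planted 0.04 (sampled one step after onset)
  target <- 0.04 * exp(-(1 / ts$fs) / 0.4)
  sem <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - target), 3 * sem + 1e-4)
})

test_that("composite traces behave algebraically", {
  x <- sin(seq(0, 6, by = 0.1))
  cs <- composite_sum(x, -x)
  expect_equal(cs$composite, rep(0, length(x)))
  self <- composite_sum(x, 0 * x, reference = x)
  expect_equal(self$spearman, 1)
  expect_error(composite_sum(x, x[-1]), "length")
})

test_that("the generator is silent and deterministic when asked", {
  ts <- generate_traces(synth_spec(slow_amplitude = 0, bleach_frac = 0,
                                   noise_sd = 0, seed = 9))
  expect_equal(ts$F_sig, ts$F_iso)
  expect_equal(dff(ts$F_sig, ts$F_iso), rep(0, length(ts$time)))
  a <- generate_traces(synth_spec(seed = 10))
  b <- generate_traces(synth_spec(seed = 10))
  expect_identical(a$F_sig, b$F_sig)
  expect_identical(a$events, b$events)
})
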