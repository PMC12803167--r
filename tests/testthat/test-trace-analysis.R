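test_that("principal components match an eigen-decomposition oracle", {
  set.seed(1)
  # rank-one data: PC1 explains everything
  t_ <- seq(0, 1, length.out = 40)
  line <- cbind(2 * t_, -t_, 0.5 * t_)
  r <- pca_project(line, 2)
  expect_equal(r$explained_variance[1], 1, tolerance = 1e-12)

  # small hand matrix against covariance eigenvectors
  m <- matrix(c(1, 2, 0, 4, 1, -1, 2, 0, 3, 1, 1, 1, 0, 2, 2), 5, 3)
  r <- pca_project(m, 3)
  ev <- eigen(stats::cov(m))
  for (k in 1:3) {
    a <- r$basis$rotation[, k]; b <- ev$vectors[, k]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)  # same axis, any sign
  }
  # sign convention: largest-magnitude loading positive
  for (k in 1:3) {
    a <- r$basis$rotation[, k]
    expect_gt(a[which.max(abs(a))], 0)
  }
  # full basis reconstructs the centered data
  rec <- r$projections %*% t(r$basis$rotation)
  expect_equal(rec, sweep(m, 2, colMeans(m)), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_warning(pca_project(matrix(1, 10, 3), 2), "zero-variance")
})

test_that("shared-basis projections stitch across trials", {
  set.seed(2)
  trials <- lapply(1:4, function(i) matrix(rnorm(30), 10, 3))
  concat <- do.call(rbind, trials)
  joint <- pca_project(concat, 2)
  per_trial <- lapply(trials, function(tr)
    pca_project(tr, 2, basis = joint$basis)$projections)
  expect_equal(do.call(rbind, per_trial), joint$projections,
               tolerance = 1e-12)
})

test_that("event alignment indexes correctly and marks edges missing", {
  steps <- data.frame(t = 1:20, trial = rep(1:2, each = 10),
                      phase = "TRANSIT", action = "move",
                      events = "", success = TRUE)
  steps$events[10] <- "enter_reward_zone"
  steps$events[12] <- "enter_reward_zone"
  rec <- structure(list(steps = steps, x = matrix(1:20, 20, 1),
                        z = matrix(101:120, 20, 1)), class = "state_recording")
  at <- align_to_event(rec, "enter_reward_zone", c(2, 2), source = "z")
  expect_equal(nrow(at$values), 2)
  expect_equal(at$rel_time, -2:2)
  # second occurrence at step 12 (trial 2 starts at step 11): steps 10..14,
  # but step 10 belongs to trial 1 -> missing
  expect_equal(at$values[2, ], c(NA, 111, 112, 113, 114))
  # first occurrence at step 10: steps 11, 12 are in trial 2 -> missing
  expect_equal(at$values[1, ], c(108, 109, 110, NA, NA))

  expect_warning(align_to_event(rec, "reward_delivered", c(1, 1)), "absent")
})

test_that("alignment is translation-consistent", {
  mk <- function(shift) {
    n <- 30
    ev <- rep("", n); ev[15 + shift] <- "reward_delivered"
    steps <- data.frame(t = 1:n, trial = 1, phase = "x", action = "wait",
                        events = ev, success = TRUE)
    z <- matrix(sin((1:n - shift) / 3), n, 1)
    structure(list(steps = steps, x = z, z = z), class = "state_recording")
  }
  a0 <- align_to_event(mk(0), "reward_delivered", c(3, 3))
  a5 <- align_to_event(mk(5), "reward_delivered", c(3, 3))
  expect_equal(a0$values, a5$values, tolerance = 1e-12)
})

test_that("pre/post comparison is null for identical or silent recordings", {
  set.seed(3)
  agent <- agent_init("asnen", network = asnen_params(Nx = 4, Nz = 4))
  rec <- suppressWarnings(record_rollouts(agent, task_config(),
                                          n_success_trials = 2,
                                          max_attempts = 8))
  expect_true(all(rec$steps$phase != ""))
  cmp <- pre_post_compare(rec, rec, event = "enter_trigger")
  expect_equal(cmp$difference, 0)

  silent <- rec
  silent$z <- matrix(0, nrow(rec$z), ncol(rec$z))
  cmp0 <- suppressWarnings(pre_post_compare(silent, silent,
                                            event = "enter_trigger"))
  expect_equal(cmp0$trained_amplitude, 0)
  expect_equal(cmp0$untrained_amplitude, 0)
})

test_that("recordings are well-formed and reproducible under a seed", {
  go <- function(seed) {
    set.seed(seed)
    agent <- agent_init("asnen", network = asnen_params(Nx = 4, Nz = 4))
    suppressWarnings(record_rollouts(agent, task_config(),
                                     n_success_trials = 3,
                                     max_attempts = 10))
  }
  r1 <- go(9); r2 <- go(9)
  expect_identical(r1$steps, r2$steps)
  expect_identical(r1$z, r2$z)
  expect_equal(nrow(r1$steps), nrow(r1$z))
  expect_true(all(tapply(r1$steps$phase, r1$steps$trial, function(p)
    p[length(p)] %in% c("SUCCESS", "FAILURE"))))
})

test_that("unit profiles classify planted waveforms through the shared rule", {
  n <- 120
  ev <- rep("", n); ev[seq(10, 110, by = 20)] <- "reward_delivered"
  steps <- data.frame(t = 1:n, trial = rep(1:6, each = 20), phase = "x",
                      action = "wait", events = ev, success = TRUE)
  occ <- seq(10, 110, by = 20)
  peaky <- numeric(n); for (o in occ) peaky <- peaky +
    2 * exp(-((1:n) - o)^2 / 8)
  const <- rep(0.3, n)
  rec <- structure(list(steps = steps, x = cbind(peaky, const),
                        z = cbind(peaky, const)), class = "state_recording")
  up <- unit_profiles(rec, "reward_delivered", window = c(6, 6))
  expect_equal(as.character(up$classes[1]), "peak")
  expect_equal(as.character(up$classes[2]), "state_change")
  expect_equal(dim(up$profiles), c(2, 13))
})

test_that("peak + trough unit mixtures compose into the state-change trace", {
  # synthetic recording built from peak-class and trough-class units whose
  # sum is the planted state-change waveform
  rel <- seq(-8, 8, by = 0.25)
  peak_m <- asnen:::slow_template(rel, "peak", 2)
  trough_m <- asnen:::slow_template(rel, "trough", 2)
  state_m <- asnen:::slow_template(rel, "state_change", 2)
  set.seed(4)
  noisy_peak <- peak_m + rnorm(length(rel), 0, 0.05)
  noisy_trough <- trough_m + rnorm(length(rel), 0, 0.05)
  cs <- composite_sum(noisy_peak, noisy_trough, reference = state_m)
  expect_gte(cs$spearman, 0.8)
})
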