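test_that("moving average matches a brute-force window mean", {
  expect_equal(moving_average(rep(3, 5), 2), rep(3, 5))
  expect_equal(moving_average(c(0, 1), 2), c(0, 0.5))
  expect_identical(moving_average(numeric(0), 3), numeric(0))
  set.seed(1)
  x <- rnorm(57)
  naive <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 9):i])
  }, numeric(1))
  expect_equal(moving_average(x, 10), naive)
})

test_that("generalized advantages reduce to closed forms", {
  mk <- function(reward, value, done, last_value = 0) {
    list(reward = reward, value = value, done = done,
         last_value = last_value, horizon = length(reward))
  }
  b <- compute_advantages(mk(rep(0, 4), rep(0, 4), c(F, F, F, T)),
                          0.9, 0.8, normalize = FALSE)
  expect_equal(b$advantages, rep(0, 4))

  b <- compute_advantages(mk(2.5, 0.7, TRUE), 0.9, 0.8, normalize = FALSE)
  expect_equal(b$advantages, 2.5 - 0.7)

  # lambda = 1, discount = 1: advantage is the Monte-Carlo return minus value
  r <- c(1, -2, 3); v <- c(0.5, -0.5, 0.25)
  b <- compute_advantages(mk(r, v, c(F, F, T)), 1, 1, normalize = FALSE)
  mc <- rev(cumsum(rev(r)))
  expect_equal(b$advantages, mc - v)
  expect_equal(b$returns, b$advantages + v)
})

test_that("rollouts have the required length, boundaries and determinism", {
  set.seed(2)
  agent <- agent_init("asnen", network = asnen_params(Nx = 4, Nz = 4))
  env <- sequence_task(task_config())
  buf <- collect_rollout(agent, env, 64)
  expect_length(buf$reward, 64)
  expect_gte(sum(buf$reset_before), 3)  # 64 steps, episodes of <= 20
  expect_true(all(is.finite(buf$logp)))

  # a policy that always waits fails every episode
  wait_agent <- agent
  wait_agent$params$Wpi <- matrix(c(rep(-50, 4), rep(50, 4)), 2,
                                  byrow = TRUE)
  env2 <- sequence_task(task_config())
  set.seed(3)
  buf2 <- collect_rollout(wait_agent, env2, 64)
  expect_true(any(buf2$done))
  expect_true(all(!buf2$success[buf2$done]))

  roll <- function(seed) {
    set.seed(seed)
    a <- agent_init("asnen", network = asnen_params(Nx = 4, Nz = 4))
    collect_rollout(a, sequence_task(task_config()), 32)
  }
  r1 <- roll(7); r2 <- roll(7)
  expect_identical(r1$obs, r2$obs)
  expect_identical(r1$actions, r2$actions)
  expect_identical(r1$reward, r2$reward)
})

test_that("the clipped surrogate takes its closed-form values", {
  expect_equal(ppo_surrogate(1.5, 1, 0.2), 1.2)
  expect_equal(ppo_surrogate(1.1, 1, 0.2), 1.1)
  expect_equal(ppo_surrogate(0.5, -2, 0.2), -1.6)
  expect_equal(ppo_surrogate(1, 3, 0.2), 3)
})

test_that("analytic gradients match central differences for all cores", {
  for (arch in c("asnen", "vrnn", "lstm")) {
    set.seed(11)
    agent <- if (arch == "asnen") {
      agent_init("asnen", network = asnen_params(Nx = 3, Nz = 3,
        gamma = 0.2, tau = 0.5, scale = 0.4, w_density = 0.5))
    } else agent_init(arch, hidden_size = 5)
    buf <- small_buffer(agent)
    cfg <- train_config(minibatch_size = 12, rollout_horizon = 12,
                        entropy_coef = 0.03)
    g <- asnen:::segment_grads(agent, buf, 1:12, cfg)
    set.seed(12)
    for (nm in agent$trainable) {
      for (ii in sample(length(agent$params[[nm]]),
                        min(4, length(agent$params[[nm]])))) {
        num <- numeric_grad(agent, buf, cfg, nm, ii)
        ana <- as.numeric(g$grads[[nm]])[ii]
        expect_equal(ana, num, tolerance = 5e-4,
                     label = sprintf("%s grad %s[%d]", arch, nm, ii))
      }
    }
  }
})

test_that("zero advantages, no entropy, exact values give a null update", {
  set.seed(13)
  agent <- agent_init("asnen", network = asnen_params(Nx = 3, Nz = 3))
  buf <- small_buffer(agent)
  buf$advantages <- rep(0, buf$horizon)
  buf$returns <- buf$value
  cfg <- train_config(entropy_coef = 0, minibatch_size = 12,
                      rollout_horizon = 12, ppo_epochs = 2)
  upd <- ppo_update(agent, buf, cfg)
  for (nm in agent$trainable)
    expect_identical(upd$agent$params[[nm]], agent$params[[nm]])
})

test_that("the surrogate gradient vanishes where clipping binds", {
  set.seed(14)
  agent <- agent_init("asnen", network = asnen_params(Nx = 3, Nz = 3))
  buf <- small_buffer(agent)
  cfg <- train_config(entropy_coef = 0, value_coef = 0,
                      minibatch_size = 12, rollout_horizon = 12)
  # push every ratio far above 1 + eps with positive advantages:
  # min(rho A, clip A) picks the constant clipped branch -> zero gradient
  buf$logp <- buf$logp - 1    # old log-probs much lower => rho = e > 1.2
  buf$advantages <- rep(1, buf$horizon)
  buf$returns <- buf$value
  g <- asnen:::segment_grads(agent, buf, 1:12, cfg)
  for (nm in agent$trainable)
    expect_equal(max(abs(g$grads[[nm]])), 0)
})

test_that("an update raises log-probabilities of advantaged actions", {
  set.seed(15)
  agent <- agent_init("asnen", network = asnen_params(Nx = 4, Nz = 4))
  buf <- small_buffer(agent, horizon = 16)
  buf$advantages <- rep(1, 16)  # every taken action advantaged
  cfg <- train_config(minibatch_size = 16, rollout_horizon = 16,
                      entropy_coef = 0, policy_lr = 0.01, ppo_epochs = 1)
  logp_of <- function(ag) {
    -asnen:::segment_grads(ag, buf, 1:16,
      train_config(minibatch_size = 16, rollout_horizon = 16,
                   entropy_coef = 0, value_coef = 0,
                   clip_epsilon = 0.99))$policy_loss
  }
  before <- logp_of(agent)
  upd <- ppo_update(agent, buf, cfg)
  after <- logp_of(upd$agent)
  expect_gt(after, before)
})

test_that("training bookkeeping is seed-deterministic and window-averaged", {
  run <- function(seed) {
    train_agent(task_config(),
                train_config(n_episodes = 25, seed = seed,
                             rollout_horizon = 32, minibatch_size = 32,
                             ppo_epochs = 2, eval_window = 10),
                "asnen")
  }
  r0 <- train_agent(task_config(), train_config(n_episodes = 0), "asnen")
  expect_equal(nrow(r0$metrics), 0)
  r1 <- run(21); r2 <- run(21)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(r1$metrics$moving_success,
               moving_average(r1$metrics$success, 10))
  expect_true(all(r1$metrics$success %in% c(0, 1)))
})

test_that("a strong entropy bonus drives the policy toward uniform", {
  set.seed(16)
  agent <- agent_init("asnen", network = asnen_params(Nx = 3, Nz = 3))
  agent$params$Wpi <- matrix(rnorm(6, sd = 2), 2, 3)  # skewed policy
  buf <- small_buffer(agent)
  buf$advantages <- rep(0, buf$horizon)
  buf$returns <- buf$value
  cfg <- train_config(entropy_coef = 5, value_coef = 0, policy_lr = 0.05,
                      minibatch_size = 12, rollout_horizon = 12,
                      ppo_epochs = 10)
  st <- agent_reset_state(agent)
  st <- agent_step(agent, st, c(1, 1, 0))
  gap_before <- abs(diff(agent_policy_value(agent, st)$probs))
  upd <- ppo_update(agent, buf, cfg)
  st2 <- agent_reset_state(upd$agent)
  st2 <- agent_step(upd$agent, st2, c(1, 1, 0))
  gap_after <- abs(diff(agent_policy_value(upd$agent, st2)$probs))
  expect_lt(gap_after, gap_before)
})

test_that("baselines share interfaces and report parameter counts", {
  set.seed(17)
  v <- agent_init("vrnn", hidden_size = 8)
  l <- agent_init("lstm", hidden_size = 8)
  for (ag in list(v, l)) {
    st <- agent_reset_state(ag)
    st <- agent_step(ag, st, c(1, 1, 0))
    pv <- agent_policy_value(ag, st)
    expect_equal(sum(pv$probs), 1, tolerance = 1e-12)
    expect_true(all(pv$probs > 0))
    expect_length(pv$value, 1)
  }
  expect_equal(parameter_count(v), 8 * 8 + 8 * 3 + 8 + 2 * 8 + 8)
  expect_equal(parameter_count(l), 4 * 8 * 3 + 4 * 8 * 8 + 4 * 8 + 2 * 8 + 8)
})
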