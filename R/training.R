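#' Training configuration for clipped-surrogate policy optimization
#'
#' Reference values follow the simulation settings table of the study
#' conditions: policy learning rate 0.001, clip 0.2, entropy coefficient
#' 0.05, rollout horizon 64, 16 epochs per update, minibatch 64, 10,000
#' training episodes, 100-episode evaluation window. Discount, advantage
#' smoothing, value-loss weight and gradient clipping are standard
#' implementer defaults.
#'
#' @param policy_lr Adam learning rate for all parameters.
#' @param clip_epsilon Probability-ratio clip half-width (0 < eps < 1).
#' @param entropy_coef Entropy bonus coefficient.
#' @param rollout_horizon Steps collected per update (spans episode
#'   boundaries).
#' @param ppo_epochs Optimization passes over each rollout.
#' @param minibatch_size Contiguous segment length per gradient step
#'   (<= rollout_horizon; recurrent replay restarts from stored states at
#'   segment boundaries).
#' @param n_episodes Total training episodes.
#' @param discount Discount factor.
#' @param gae_lambda Advantage smoothing parameter.
#' @param value_coef Value-loss weight.
#' @param grad_clip Global gradient-norm clip.
#' @param normalize_adv Normalize advantages per update.
#' @param eval_window Moving-average window (episodes).
#' @param seed Integer seed controlling every random stream of a run.
#' @param hidden_size Hidden dimension for baseline architectures.
#' @return A `train_config` list.
#' @export
train_config <- function(policy_lr = 0.001, clip_epsilon = 0.2,
                         entropy_coef = 0.05, rollout_horizon = 64L,
                         ppo_epochs = 16L, minibatch_size = 64L,
                         n_episodes = 10000L, discount = 0.99,
                         gae_lambda = 0.95, value_coef = 0.5,
                         grad_clip = 0.5, normalize_adv = TRUE,
                         eval_window = 100L, seed = 1L,
                         hidden_size = 128L) {
  cfg <- list(policy_lr = policy_lr, clip_epsilon = clip_epsilon,
              entropy_coef = entropy_coef,
              rollout_horizon = as.integer(rollout_horizon),
              ppo_epochs = as.integer(ppo_epochs),
              minibatch_size = as.integer(minibatch_size),
              n_episodes = as.integer(n_episodes), discount = discount,
              gae_lambda = gae_lambda, value_coef = value_coef,
              grad_clip = grad_clip, normalize_adv = normalize_adv,
              eval_window = as.integer(eval_window), seed = as.integer(seed),
              hidden_size = as.integer(hidden_size))
  if (cfg$clip_epsilon <= 0 || cfg$clip_epsilon >= 1)
    stop("invalid train config: clip_epsilon in (0, 1)")
  if (cfg$discount <= 0 || cfg$discount > 1)
    stop("invalid train config: discount in (0, 1]")
  if (cfg$minibatch_size > cfg$rollout_horizon)
    stop("invalid train config: minibatch_size must be <= rollout_horizon")
  class(cfg) <- "train_config"
  cfg
}

#' Trailing moving average
#'
#' Mean over the last `window` entries; a shorter prefix is averaged over
#' the entries available so far.
#'
#' @param x Numeric series.
#' @param window Window length in entries (>= 1).
#' @return Numeric series of the same length (empty input gives empty
#'   output).
#' @export
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  out <- numeric(n)
  idx <- seq_len(n)
  full <- idx >= window
  out[!full] <- cs[!full] / idx[!full]
  if (any(full)) {
    i <- idx[full]
    out[full] <- (cs[i] - c(0, cs)[i - window + 1L]) / window
  }
  out
}

#' Collect a fixed-horizon rollout from one persistent environment
#'
#' Exactly `horizon` transitions are gathered; episodes that terminate
#' inside the rollout reset both the environment and the agent's dynamical
#' state. The agent consumes the latest observation, then samples the
#' action from its policy readout. Pre-step recurrent states are stored so
#' minibatched re-evaluation can replay dynamics from segment starts.
#'
#' @param agent An [agent_init()] object.
#' @param env A [sequence_task()] handle (mutated in place).
#' @param horizon Number of transitions to collect.
#' @param agent_state Current agent state, or NULL to force a reset.
#' @return A rollout buffer (list of aligned per-step vectors/matrices,
#'   final bootstrap value, and the carried agent state).
#' @export
collect_rollout <- function(agent, env, horizon, agent_state = NULL) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1")
  obs_m <- matrix(0, horizon, 3L)
  actions <- integer(horizon)
  logp <- numeric(horizon); value <- numeric(horizon)
  reward <- numeric(horizon)
  done <- logical(horizon); reset_before <- logical(horizon)
  success <- logical(horizon)
  states <- vector("list", horizon)

  for (t in seq_len(horizon)) {
    if (is.null(agent_state) || env$done()) {
      env$reset()
      agent_state <- agent_reset_state(agent)
      reset_before[t] <- TRUE
    }
    states[[t]] <- agent_state
    o <- env$observation()
    obs_m[t, ] <- o
    agent_state <- agent_step(agent, agent_state, o)
    pv <- agent_policy_value(agent, agent_state)
    a <- sample.int(2L, 1L, prob = pv$probs)
    actions[t] <- a
    logp[t] <- log(max(pv$probs[a], 1e-12))
    value[t] <- pv$value
    res <- env$step(c("move", "wait")[a])
    reward[t] <- res$reward
    done[t] <- res$done
    success[t] <- res$success
  }
  last_value <- 0
  if (!done[horizon]) {
    peek <- agent_step(agent, agent_state, env$observation())
    last_value <- agent_policy_value(agent, peek)$value
  }
  list(obs = obs_m, actions = actions, logp = logp, value = value,
       reward = reward, done = done, reset_before = reset_before,
       success = success, states = states, last_value = last_value,
       agent_state = agent_state, horizon = horizon)
}

#' Generalized advantage estimation over a rollout buffer
#'
#' Lambda-weighted temporal-difference residuals, truncated at episode
#' boundaries, bootstrapping the stored value of the state following the
#' rollout when it ends mid-episode.
#'
#' @param buffer Output of [collect_rollout()].
#' @param discount Discount factor.
#' @param gae_lambda Smoothing parameter.
#' @param normalize Normalize advantages to zero mean / unit sd.
#' @return The buffer with `advantages` and `returns` fields added.
#' @export
compute_advantages <- function(buffer, discount = 0.99, gae_lambda = 0.95,
                               normalize = TRUE) {
  T <- buffer$horizon
  adv <- numeric(T)
  next_adv <- 0
  next_value <- buffer$last_value
  for (t in rev(seq_len(T))) {
    nonterm <- 1 - as.numeric(buffer$done[t])
    delta <- buffer$reward[t] + discount * next_value * nonterm -
      buffer$value[t]
    next_adv <- delta + discount * gae_lambda * nonterm * next_adv
    adv[t] <- next_adv
    next_value <- buffer$value[t]
  }
  buffer$returns <- adv + buffer$value
  if (normalize && T > 1L) {
    s <- stats::sd(adv)
    adv <- (adv - mean(adv)) / (s + 1e-8)
  }
  buffer$advantages <- adv
  buffer
}

#' Clipped-surrogate objective value for one sample
#'
#' `min(ratio * adv, clip(ratio, 1-eps, 1+eps) * adv)` -- exposed for
#' inspection and testing of the update rule.
#'
#' @param ratio New-to-old probability ratio.
#' @param adv Advantage estimate.
#' @param clip_epsilon Clip half-width.
#' @return Scalar surrogate contribution.
#' @export
ppo_surrogate <- function(ratio, adv, clip_epsilon = 0.2) {
  pmin(ratio * adv, pmax(pmin(ratio, 1 + clip_epsilon), 1 - clip_epsilon) * adv)
}

adam_init <- function(params, trainable) {
  list(m = lapply(params[trainable], function(p) array(0, dim = c(length(p)))),
       v = lapply(params[trainable], function(p) array(0, dim = c(length(p)))),
       t = 0L)
}

adam_step <- function(params, grads, opt, trainable, lr, grad_clip = 0.5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(trainable, function(nm) sum(grads[[nm]]^2),
                        numeric(1))))
  scale <- if (is.finite(gn) && gn > grad_clip) grad_clip / gn else 1
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in trainable) {
    g <- as.numeric(grads[[nm]]) * scale
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    upd <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - as.numeric(upd)  # column-major order
  }
  list(params = params, opt = opt)
}

segment_grads <- function(agent, buffer, idx, config) {
  st <- buffer$states[[idx[1]]]
  obs <- buffer$obs[idx, , drop = FALSE]
  act <- buffer$actions[idx]
  rst <- as.integer(buffer$reset_before[idx])
  if (agent$arch == "asnen") {
    init <- asnen_state(agent$params)
    asnen_ppo_grad_cpp(agent$params, obs, act, buffer$logp[idx],
                       buffer$advantages[idx], buffer$returns[idx], rst,
                       st$x, st$w, st$z, init$x, init$w, init$z,
                       config$clip_epsilon, config$entropy_coef,
                       config$value_coef)
  } else if (agent$arch == "vrnn") {
    H <- agent$params$hidden
    rnn_ppo_grad_cpp(agent$params, obs, act, buffer$logp[idx],
                     buffer$advantages[idx], buffer$returns[idx], rst,
                     st$h, rep(0, H), config$clip_epsilon,
                     config$entropy_coef, config$value_coef)
  } else {
    H <- agent$params$hidden
    lstm_ppo_grad_cpp(agent$params, obs, act, buffer$logp[idx],
                      buffer$advantages[idx], buffer$returns[idx], rst,
                      st$h, st$c, rep(0, H), rep(0, H),
                      config$clip_epsilon, config$entropy_coef,
                      config$value_coef)
  }
}

#' One proximal policy update over a collected rollout
#'
#' Runs `ppo_epochs` passes over the rollout split into contiguous
#' segments of `minibatch_size` steps (shuffled each epoch); each segment
#' replays the recurrent dynamics from its stored starting state, gradients
#' flow through the dynamics via backpropagation through time (truncated at
#' episode and segment boundaries), and all learnable matrices are updated
#' with Adam under a global gradient-norm clip.
#'
#' @param agent An [agent_init()] object.
#' @param buffer Rollout buffer with advantages (see
#'   [compute_advantages()]).
#' @param config A [train_config()].
#' @param opt Adam state (created on first use if NULL).
#' @return List with updated `agent`, `opt`, and a `report` of mean loss
#'   components.
#' @export
ppo_update <- function(agent, buffer, config, opt = NULL) {
  if (is.null(buffer$advantages)) stop("compute advantages before updating")
  if (is.null(opt)) opt <- adam_init(agent$params, agent$trainable)
  T <- buffer$horizon
  nseg <- ceiling(T / config$minibatch_size)
  seg_list <- split(seq_len(T), rep(seq_len(nseg),
                                    each = config$minibatch_size)[seq_len(T)])
  losses <- c(loss = 0, policy_loss = 0, value_loss = 0, entropy = 0)
  nstep <- 0L
  for (ep in seq_len(config$ppo_epochs)) {
    ord <- if (nseg > 1L) sample.int(nseg) else 1L
    for (k in ord) {
      g <- segment_grads(agent, buffer, seg_list[[k]], config)
      if (!is.finite(g$loss))
        stop("non-finite loss in policy update; aborting")
      upd <- adam_step(agent$params, g$grads, opt, agent$trainable,
                       config$policy_lr, config$grad_clip)
      agent$params <- upd$params
      opt <- upd$opt
      losses <- losses + c(g$loss, g$policy_loss, g$value_loss, g$entropy)
      nstep <- nstep + 1L
    }
  }
  list(agent = agent, opt = opt, report = as.list(losses / nstep))
}

#' Train an agent on the sequence task
#'
#' Interleaves fixed-horizon rollouts with proximal policy updates until
#' `n_episodes` episodes have completed, tracking per-episode return and
#' success with trailing moving averages over `eval_window` episodes. The
#' single seed controls environment draws, parameter initialization, action
#' sampling, and minibatch shuffling; identical seeds give identical runs.
#'
#' @param env_config A [task_config()].
#' @param config A [train_config()].
#' @param arch Architecture (see [agent_init()]).
#' @param verbose Print progress every 500 episodes.
#' @return List with `agent`, `metrics` (data.frame: episode, return,
#'   success, moving_return, moving_success), and the configs.
#' @export
train_agent <- function(env_config = task_config(), config = train_config(),
                        arch = c("asnen", "vrnn", "lstm"), verbose = FALSE) {
  arch <- match.arg(arch)
  set.seed(config$seed)
  agent <- agent_init(arch, hidden_size = config$hidden_size)
  env <- sequence_task(env_config)
  opt <- NULL
  agent_state <- NULL
  ep_return <- 0
  returns <- numeric(0); successes <- numeric(0)
  if (config$n_episodes > 0L) {
    repeat {
      buffer <- collect_rollout(agent, env, config$rollout_horizon,
                                agent_state)
      agent_state <- buffer$agent_state
      for (t in seq_len(buffer$horizon)) {
        ep_return <- ep_return + buffer$reward[t]
        if (buffer$done[t]) {
          returns <- c(returns, ep_return)
          successes <- c(successes, as.numeric(buffer$success[t]))
          ep_return <- 0
        }
      }
      buffer <- compute_advantages(buffer, config$discount,
                                   config$gae_lambda, config$normalize_adv)
      upd <- ppo_update(agent, buffer, config, opt)
      agent <- upd$agent
      opt <- upd$opt
      if (verbose && length(returns) %% 500L < 4L)
        message(sprintf("episodes %d  success(ma) %.2f", length(returns),
                        mean(utils::tail(successes, config$eval_window))))
      if (length(returns) >= config$n_episodes) break
    }
    returns <- returns[seq_len(config$n_episodes)]
    successes <- successes[seq_len(config$n_episodes)]
  }
  metrics <- data.frame(
    episode = seq_along(returns), return = returns, success = successes,
    moving_return = moving_average(returns, config$eval_window),
    moving_success = moving_average(successes, config$eval_window))
  list(agent = agent, metrics = metrics, env_config = env_config,
       train_config = config, arch = arch)
}

#' Normalized area under a metric curve
#'
#' Mean of the series -- the area under the moving-average curve divided by
#' its length, used to compare learning curves across architectures.
#'
#' @param x Numeric series (e.g. `metrics$moving_success`).
#' @return Scalar mean.
#' @export
metric_auc <- function(x) mean(x)
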