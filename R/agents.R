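#' Construct an actor-critic agent
#'
#' Three recurrent cores share the same episodic interface and the same
#' training code path; only the dynamics differ:
#' \itemize{
#'   \item `"asnen"`: the tripartite neuron-astrocyte network
#'     ([asnen_params()]); the policy reads neuronal activity, the value
#'     reads astrocytic activity.
#'   \item `"vrnn"`: vanilla recurrent network, `h' = tanh(Wh h + Win o + b)`;
#'     policy and value read the same hidden state.
#'   \item `"lstm"`: standard LSTM (gates i, f, g, o; forget bias
#'     initialized to +1); policy and value read the hidden state.
#' }
#' Baselines use `hidden_size` units (reference 128) and uniform
#' `[-1/sqrt(fan), 1/sqrt(fan)]` initialization.
#'
#' @param arch One of `"asnen"`, `"vrnn"`, `"lstm"`.
#' @param hidden_size Hidden dimension for the baselines (default 128).
#' @param network Optional pre-built [asnen_params()] (arch `"asnen"` only);
#'   built with defaults otherwise.
#' @param n_obs Observation dimension (3 for the sequence task).
#' @return An `asnen_agent` list with `arch`, `params` and bookkeeping.
#' @export
agent_init <- function(arch = c("asnen", "vrnn", "lstm"), hidden_size = 128L,
                       network = NULL, n_obs = 3L) {
  arch <- match.arg(arch)
  if (arch == "asnen") {
    params <- if (is.null(network)) asnen_params() else network
    trainable <- asnen_trainable
  } else if (arch == "vrnn") {
    H <- as.integer(hidden_size)
    s <- 1 / sqrt(H)
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
    params <- list(Wh = u(H, H), Win = u(H, n_obs), b = rep(0, H),
                   Wpi = u(2L, H), Wv = u(1L, H), hidden = H)
    trainable <- c("Wh", "Win", "b", "Wpi", "Wv")
  } else {
    H <- as.integer(hidden_size)
    s <- 1 / sqrt(H)
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
    b <- rep(0, 4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
    params <- list(Wi = u(4L * H, n_obs), Whh = u(4L * H, H), b = b,
                   Wpi = u(2L, H), Wv = u(1L, H), hidden = H)
    trainable <- c("Wi", "Whh", "b", "Wpi", "Wv")
  }
  agent <- list(arch = arch, params = params, trainable = trainable)
  class(agent) <- "asnen_agent"
  agent
}

#' Fresh dynamical state for an agent (used at each episode start)
#' @param agent An [agent_init()] object.
#' @return State list (`x`,`w`,`z` for asnen; `h` / `h`,`c` for baselines).
#' @export
agent_reset_state <- function(agent) {
  switch(agent$arch,
    asnen = asnen_state(agent$params),
    vrnn = list(h = rep(0, agent$params$hidden)),
    lstm = list(h = rep(0, agent$params$hidden),
                c = rep(0, agent$params$hidden)))
}

#' Advance an agent's recurrent state with one observation
#' @param agent An [agent_init()] object.
#' @param state Current state list.
#' @param obs Numeric length-3 observation.
#' @return Updated state list.
#' @export
agent_step <- function(agent, state, obs) {
  obs <- as.numeric(obs)
  switch(agent$arch,
    asnen = network_step(agent$params, state, obs),
    vrnn = list(h = as.numeric(rnn_step_cpp(agent$params, state$h, obs))),
    lstm = {
      r <- lstm_step_cpp(agent$params, state$h, state$c, obs)
      list(h = as.numeric(r$h), c = as.numeric(r$c))
    })
}

#' Policy probabilities and value estimate at the current state
#' @param agent An [agent_init()] object.
#' @param state Current state list (post [agent_step()]).
#' @return List with `probs` (move, wait) and `value`.
#' @export
agent_policy_value <- function(agent, state) {
  if (agent$arch == "asnen") {
    list(probs = policy_distribution(agent$params, state$x),
         value = value_estimate(agent$params, state$z))
  } else {
    h <- state$h
    logits <- as.numeric(agent$params$Wpi %*% h)
    e <- exp(logits - max(logits))
    p <- e / sum(e)
    names(p) <- c("move", "wait")
    list(probs = p, value = as.numeric(agent$params$Wv %*% h))
  }
}

#' Number of learnable parameters of an agent
#' @param agent An [agent_init()] object.
#' @return Integer parameter count.
#' @export
parameter_count <- function(agent) {
  sum(vapply(agent$params[agent$trainable], length, integer(1)))
}
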