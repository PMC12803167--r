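#' Configuration of the spatial sequence reward task
#'
#' The task is a discrete-time Markov decision process with four phases --
#' trigger zone, transit, reward zone, and a terminal success/failure state
#' -- mirroring a rodent arena in which the animal moves from a trigger zone
#' to a reward zone and must wait through a delay before reward delivery.
#' Every step carries a small cost so that inefficient trajectories are
#' mildly penalized; success delivers a unit reward.
#'
#' @param transit_duration Steps of forced transit between zones (>= 1).
#' @param reward_delay_min,reward_delay_max Integer bounds of the per-episode
#'   reward delay, drawn uniformly at reset (defaults 2 and 8).
#' @param step_cost Reward added at every step (<= 0, default -0.01).
#' @param success_reward Event reward at delivery (> 0, default +1).
#' @param max_steps Hard maximum trial length in steps (default 20).
#' @param cue_duration Steps the trigger-zone cue stays on (>= 1 shows the
#'   cue in the reset observation; 0 disables it).
#' @param post_reward_duration Steps of the post-reward phase before the
#'   episode terminates in success (>= 0).
#' @return A `task_config` list.
#' @export
task_config <- function(transit_duration = 3L, reward_delay_min = 2L,
                        reward_delay_max = 8L, step_cost = -0.01,
                        success_reward = 1, max_steps = 20L,
                        cue_duration = 1L, post_reward_duration = 1L) {
  cfg <- list(transit_duration = as.integer(transit_duration),
              reward_delay_min = as.integer(reward_delay_min),
              reward_delay_max = as.integer(reward_delay_max),
              step_cost = as.numeric(step_cost),
              success_reward = as.numeric(success_reward),
              max_steps = as.integer(max_steps),
              cue_duration = as.integer(cue_duration),
              post_reward_duration = as.integer(post_reward_duration))
  if (cfg$transit_duration < 1L)
    stop("invalid task config: transit_duration must be >= 1")
  if (cfg$reward_delay_min > cfg$reward_delay_max)
    stop("invalid task config: reward_delay_min > reward_delay_max")
  if (cfg$max_steps <= cfg$transit_duration + cfg$reward_delay_min)
    stop("invalid task config: max_steps must exceed transit_duration + reward_delay_min")
  if (cfg$step_cost > 0) stop("invalid task config: step_cost must be <= 0")
  if (cfg$success_reward <= 0)
    stop("invalid task config: success_reward must be > 0")
  if (cfg$cue_duration < 0L || cfg$post_reward_duration < 0L)
    stop("invalid task config: durations must be >= 0")
  class(cfg) <- "task_config"
  cfg
}

task_phases <- c("TRIGGER", "TRANSIT", "REWARD_ZONE", "POST_REWARD",
                 "SUCCESS", "FAILURE")

make_observation <- function(cue, reward_flag) {
  c(bias = 1, cue = as.numeric(cue), reward_flag = as.numeric(reward_flag))
}

#' Reset the task to the start of a new episode
#'
#' The agent starts in the trigger zone with the cue active; the reward
#' delay for the episode is drawn uniformly from
#' `[reward_delay_min, reward_delay_max]` using the current R random stream.
#'
#' @param config A [task_config()].
#' @param fixed_delay Optional integer overriding the random delay draw
#'   (must lie within the configured bounds); used for deterministic tests.
#' @return List with `state` (environment state) and `observation`
#'   (bias, cue, reward_flag).
#' @export
env_reset <- function(config, fixed_delay = NULL) {
  if (!inherits(config, "task_config")) stop("config must be a task_config")
  if (is.null(fixed_delay)) {
    delay <- config$reward_delay_min +
      sample.int(config$reward_delay_max - config$reward_delay_min + 1L, 1L) - 1L
  } else {
    delay <- as.integer(fixed_delay)
    if (delay < config$reward_delay_min || delay > config$reward_delay_max)
      stop("fixed_delay outside configured bounds")
  }
  state <- list(phase = "TRIGGER", step_index = 0L, transit_progress = 0L,
                hold_counter = 0L, reward_delay = delay,
                cue_timer = config$cue_duration, post_timer = 0L,
                reward_delivered = FALSE)
  class(state) <- "env_state"
  obs <- make_observation(state$cue_timer > 0L, FALSE)
  list(state = state, observation = obs, events = "enter_trigger")
}

#' Advance the task by one step
#'
#' @param state An `env_state` from [env_reset()] or a previous step.
#' @param action `"move"` or `"wait"`.
#' @param config The [task_config()] used at reset.
#' @return List with updated `state` and `result` (observation, reward,
#'   done flag, event labels, and the event-reward component separately).
#' @export
env_step <- function(state, action, config) {
  if (state$phase %in% c("SUCCESS", "FAILURE"))
    stop("cannot step a terminated episode")
  action <- match.arg(action, c("move", "wait"))
  events <- character(0)
  event_reward <- 0
  state$step_index <- state$step_index + 1L
  if (state$cue_timer > 0L) state$cue_timer <- state$cue_timer - 1L

  if (state$phase == "TRIGGER") {
    if (action == "move") {
      state$phase <- "TRANSIT"
      state$transit_progress <- 0L
      events <- c(events, "leave_trigger")
      if (state$transit_progress >= config$transit_duration) {
        state$phase <- "REWARD_ZONE"
        events <- c(events, "enter_reward_zone")
      }
    }
  } else if (state$phase == "TRANSIT") {
    if (action == "move") {
      state$transit_progress <- state$transit_progress + 1L
      if (state$transit_progress >= config$transit_duration) {
        state$phase <- "REWARD_ZONE"
        state$hold_counter <- 0L
        events <- c(events, "enter_reward_zone")
      }
    }
  } else if (state$phase == "REWARD_ZONE") {
    if (action == "wait") {
      state$hold_counter <- state$hold_counter + 1L
      if (state$hold_counter > state$reward_delay) {
        state$reward_delivered <- TRUE
        event_reward <- config$success_reward
        events <- c(events, "reward_delivered")
        if (config$post_reward_duration > 0L) {
          state$phase <- "POST_REWARD"
          state$post_timer <- config$post_reward_duration
        } else {
          state$phase <- "SUCCESS"
          events <- c(events, "success")
        }
      }
    } else {
      # moving breaks the consecutive hold; the zone has no exit transition
      state$hold_counter <- 0L
    }
  } else if (state$phase == "POST_REWARD") {
    state$post_timer <- state$post_timer - 1L
    if (state$post_timer <= 0L) {
      state$phase <- "SUCCESS"
      events <- c(events, "success")
    }
  }

  if (state$step_index >= config$max_steps &&
      !(state$phase %in% c("SUCCESS", "FAILURE"))) {
    if (state$reward_delivered) {
      state$phase <- "SUCCESS"
      events <- c(events, "success")
    } else {
      state$phase <- "FAILURE"
      events <- c(events, "failure")
    }
  }

  done <- state$phase %in% c("SUCCESS", "FAILURE")
  reward <- config$step_cost + event_reward
  obs <- make_observation(state$cue_timer > 0L, state$reward_delivered)
  list(state = state,
       result = list(observation = obs, reward = reward, done = done,
                     events = events, event_reward = event_reward,
                     success = identical(state$phase, "SUCCESS")))
}

#' Mutable episodic environment handle
#'
#' Wraps [env_reset()]/[env_step()] in a closure-based object with the
#' conventional episodic interface (`$reset()`, `$step(action)`,
#' `$observation()`, `$done()`), keeping state internally so training code
#' can drive one persistent instance across rollout boundaries.
#'
#' @param config A [task_config()].
#' @param fixed_delay Optional fixed reward delay (see [env_reset()]).
#' @return An environment object.
#' @export
sequence_task <- function(config, fixed_delay = NULL) {
  self <- new.env(parent = emptyenv())
  self$config <- config
  self$state <- NULL
  self$obs <- NULL
  self$reset <- function() {
    r <- env_reset(config, fixed_delay)
    self$state <- r$state
    self$obs <- r$observation
    r
  }
  self$step <- function(action) {
    r <- env_step(self$state, action, config)
    self$state <- r$state
    self$obs <- r$result$observation
    r$result
  }
  self$observation <- function() self$obs
  self$done <- function() {
    is.null(self$state) || self$state$phase %in% c("SUCCESS", "FAILURE")
  }
  class(self) <- "sequence_task"
  self
}

#' Optimal episode return by exhaustive search
#'
#' Enumerates all deterministic action sequences (depth-first over the
#' deterministic state space for a fixed reward delay, memoized) and returns
#' the maximal achievable episode return. If no action sequence reaches the
#' success state within `max_steps`, returns `NA` (no success reachable).
#'
#' @param config A [task_config()].
#' @param fixed_delay Fixed reward delay used for every branch.
#' @return Scalar optimal return, or `NA_real_` if success is unreachable.
#' @export
optimal_return <- function(config, fixed_delay) {
  fixed_delay <- as.integer(fixed_delay)
  memo <- new.env(parent = emptyenv())
  best <- function(state) {
    if (state$phase == "SUCCESS") return(0)
    if (state$phase == "FAILURE") return(-Inf)
    key <- paste(state$phase, state$step_index, state$transit_progress,
                 state$hold_counter, state$post_timer, sep = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    vals <- vapply(c("move", "wait"), function(a) {
      r <- env_step(state, a, config)
      r$result$reward + best(r$state)
    }, numeric(1))
    v <- max(vals)
    memo[[key]] <- v
    v
  }
  st <- env_reset(config, fixed_delay)$state
  v <- best(st)
  if (!is.finite(v)) NA_real_ else v
}

#' Run one episode under a scripted policy and log it
#'
#' @param config A [task_config()].
#' @param policy Function `(observation, state) -> "move"|"wait"`, or the
#'   string `"optimal"` for the greedy scripted policy (move until the
#'   reward zone, then wait).
#' @param fixed_delay Optional fixed reward delay.
#' @return Data frame log with columns step, phase, action, reward, events,
#'   and attributes `return` (episode return) and `success`.
#' @export
simulate_episode <- function(config, policy = "optimal", fixed_delay = NULL) {
  if (identical(policy, "optimal")) {
    policy <- function(obs, state) {
      if (state$phase %in% c("TRIGGER", "TRANSIT")) "move" else "wait"
    }
  }
  r <- env_reset(config, fixed_delay)
  state <- r$state
  obs <- r$observation
  rows <- list()
  total <- 0
  success <- FALSE
  repeat {
    a <- policy(obs, state)
    s <- env_step(state, a, config)
    total <- total + s$result$reward
    rows[[length(rows) + 1L]] <- data.frame(
      step = s$state$step_index, phase = s$state$phase, action = a,
      reward = s$result$reward,
      events = paste(s$result$events, collapse = ";"),
      stringsAsFactors = FALSE)
    state <- s$state
    obs <- s$result$observation
    if (s$result$done) { success <- s$result$success; break }
  }
  log <- do.call(rbind, rows)
  attr(log, "return") <- total
  attr(log, "success") <- success
  log
}
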