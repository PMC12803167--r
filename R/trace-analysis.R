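#' Record full internal states over rollouts of a trained policy
#'
#' Runs episodes in a fixed environment configuration until
#' `n_success_trials` successful trials have been recorded (or
#' `max_attempts` episodes have been tried), storing at every step the full
#' neuronal/astrocytic/synaptic state (or hidden state for baselines), the
#' environment phase label, the chosen action, and task event labels.
#'
#' @param agent An [agent_init()] object.
#' @param env_config A [task_config()].
#' @param n_success_trials Successful trials to collect.
#' @param max_attempts Cap on total episodes attempted.
#' @param fixed_delay Optional fixed reward delay (fixed environment
#'   configuration for comparable trials).
#' @param greedy Use argmax actions instead of sampling.
#' @param w_summary `"norm"` stores only the synaptic L2 norm per step;
#'   `"full"` stores the whole flattened vector.
#' @return A `state_recording` list: `steps` data.frame (t, trial, phase,
#'   action, events, success), matrices `x`, `z` (and `w` or `w_norm`),
#'   `n_success`, and `truncated` flag when the cap was hit first.
#' @export
record_rollouts <- function(agent, env_config, n_success_trials = 10L,
                            max_attempts = 200L, fixed_delay = NULL,
                            greedy = FALSE, w_summary = c("norm", "full")) {
  w_summary <- match.arg(w_summary)
  env <- sequence_task(env_config, fixed_delay)
  rows <- list(); xs <- list(); zs <- list(); ws <- list()
  n_success <- 0L; attempt <- 0L; t_global <- 0L
  while (n_success < n_success_trials && attempt < max_attempts) {
    attempt <- attempt + 1L
    env$reset()
    st <- agent_reset_state(agent)
    trial_rows <- list(); trial_x <- list(); trial_z <- list(); trial_w <- list()
    repeat {
      o <- env$observation()
      st <- agent_step(agent, st, o)
      pv <- agent_policy_value(agent, st)
      a <- if (greedy) which.max(pv$probs) else
        sample.int(2L, 1L, prob = pv$probs)
      res <- env$step(c("move", "wait")[a])
      t_global <- t_global + 1L
      k <- length(trial_rows) + 1L
      trial_rows[[k]] <- data.frame(
        t = t_global, trial = attempt, phase = env$state$phase,
        action = c("move", "wait")[a],
        events = paste(c(if (k == 1L) "enter_trigger", res$events),
                       collapse = ";"),
        success = NA, stringsAsFactors = FALSE)
      if (agent$arch == "asnen") {
        trial_x[[k]] <- st$x; trial_z[[k]] <- st$z
        trial_w[[k]] <- if (w_summary == "norm") sqrt(sum(st$w^2)) else st$w
      } else {
        trial_x[[k]] <- st$h; trial_z[[k]] <- st$h
        trial_w[[k]] <- 0
      }
      if (res$done) {
        for (i in seq_along(trial_rows)) trial_rows[[i]]$success <- res$success
        if (res$success) n_success <- n_success + 1L
        break
      }
    }
    rows <- c(rows, trial_rows); xs <- c(xs, trial_x); zs <- c(zs, trial_z)
    ws <- c(ws, trial_w)
  }
  rec <- list(steps = do.call(rbind, rows),
              x = do.call(rbind, xs), z = do.call(rbind, zs),
              n_success = n_success,
              truncated = n_success < n_success_trials)
  if (w_summary == "norm") rec$w_norm <- unlist(ws) else
    rec$w <- do.call(rbind, ws)
  if (rec$truncated)
    warning(sprintf("attempt cap reached: %d/%d successful trials recorded",
                    n_success, n_success_trials))
  class(rec) <- "state_recording"
  rec
}

#' Principal-component projection with an optional shared basis
#'
#' Centers the data and computes an orthonormal basis by singular value
#' decomposition; each component is oriented so its largest-magnitude
#' loading is positive (reproducible sign convention). When `basis` is
#' supplied (a previous result), only projection onto that basis is
#' performed -- the shared-basis mode used to project single trials into a
#' basis computed on concatenated successful trials.
#'
#' @param activity Numeric matrix, steps x units.
#' @param n_components Number of components to keep.
#' @param basis Optional `pca_basis` from a previous call.
#' @return List with `projections` (steps x n_components), `basis`
#'   (class `pca_basis`: rotation + center), and `explained_variance`
#'   (proportions).
#' @export
pca_project <- function(activity, n_components = 2L, basis = NULL) {
  activity <- as.matrix(activity)
  if (!is.null(basis)) {
    centered <- sweep(activity, 2L, basis$center)
    return(list(projections = centered %*% basis$rotation, basis = basis,
                explained_variance = basis$explained_variance))
  }
  n_components <- min(as.integer(n_components), ncol(activity))
  ctr <- colMeans(activity)
  centered <- sweep(activity, 2L, ctr)
  tot <- sum(centered^2)
  if (tot < 1e-300) {
    warning("zero-variance activity: degenerate projection")
    rot <- matrix(0, ncol(activity), n_components)
    basis <- structure(list(rotation = rot, center = ctr,
                            explained_variance = rep(0, n_components)),
                       class = "pca_basis")
    return(list(projections = matrix(0, nrow(activity), n_components),
                basis = basis,
                explained_variance = rep(0, n_components)))
  }
  sv <- svd(centered, nu = 0, nv = n_components)
  rot <- sv$v
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  }
  ev <- (sv$d^2 / tot)[seq_len(n_components)]
  basis <- structure(list(rotation = rot, center = ctr,
                          explained_variance = ev), class = "pca_basis")
  list(projections = centered %*% rot, basis = basis,
       explained_variance = ev)
}

recording_event_steps <- function(recording, event) {
  hits <- grepl(event, recording$steps$events, fixed = TRUE)
  which(hits)
}

#' Align a recorded signal to occurrences of a task event
#'
#' Builds a trials x relative-time matrix with time 0 at the event step.
#' Samples that would fall outside the event's own trial (or outside the
#' recording) are marked `NA`, never zero-filled.
#'
#' @param recording A [record_rollouts()] result.
#' @param event Event label (e.g. `"enter_reward_zone"`,
#'   `"reward_delivered"`).
#' @param window Integer pair `c(pre, post)`: steps before/after the event.
#' @param source Either `"x"` or `"z"` with `unit` selecting a column, or a
#'   numeric vector of length `nrow(recording$steps)` (e.g. a PC
#'   projection).
#' @param unit Unit index when `source` is `"x"`/`"z"`.
#' @return An `aligned_tensor`: list with `values` (occurrences x time),
#'   `rel_time`, `event`, `window`.
#' @export
align_to_event <- function(recording, event, window = c(2L, 2L),
                           source = "z", unit = 1L) {
  if (is.character(source)) {
    src <- recording[[source]][, unit]
  } else {
    src <- as.numeric(source)
    if (length(src) != nrow(recording$steps))
      stop("numeric source must have one value per recorded step")
  }
  occ <- recording_event_steps(recording, event)
  rel <- seq(-as.integer(window[1]), as.integer(window[2]))
  vals <- matrix(NA_real_, length(occ), length(rel))
  trial <- recording$steps$trial
  n <- length(src)
  for (i in seq_along(occ)) {
    for (j in seq_along(rel)) {
      k <- occ[i] + rel[j]
      if (k >= 1L && k <= n && trial[k] == trial[occ[i]])
        vals[i, j] <- src[k]
    }
  }
  if (length(occ) == 0L) warning(sprintf("event '%s' absent", event))
  structure(list(values = vals, rel_time = rel, event = event,
                 window = window), class = "aligned_tensor")
}

aligned_mean <- function(at) colMeans(at$values, na.rm = TRUE)

event_locked_amplitude <- function(at) {
  m <- aligned_mean(at)
  pre <- m[at$rel_time < 0]
  base <- if (all(is.na(pre)) || length(pre) == 0L) 0 else
    mean(pre, na.rm = TRUE)
  post <- m[at$rel_time >= 0]
  post <- post[is.finite(post)]
  if (length(post) == 0L) return(NA_real_)
  max(abs(post - base))
}

#' Compare event-locked astrocytic dynamics before and after training
#'
#' Projects each recording's astrocytic activity onto its first principal
#' component, aligns to the event, and reports the event-locked amplitude
#' (maximal deflection of the trial-averaged trace in the post-event window
#' from the pre-event baseline mean) for each condition and their
#' difference.
#'
#' @param untrained,trained Two [record_rollouts()] results.
#' @param event Event label to align on.
#' @param window Integer pair `c(pre, post)` in steps.
#' @return List with `untrained_amplitude`, `trained_amplitude`,
#'   `difference`, and the two aligned tensors.
#' @export
pre_post_compare <- function(untrained, trained, event = "enter_trigger",
                             window = c(2L, 10L)) {
  amp_of <- function(rec) {
    pc1 <- pca_project(rec$z, 1L)$projections[, 1]
    at <- align_to_event(rec, event, window, source = pc1)
    list(at = at, amp = event_locked_amplitude(at))
  }
  a <- amp_of(untrained); b <- amp_of(trained)
  list(untrained_amplitude = a$amp, trained_amplitude = b$amp,
       difference = b$amp - a$amp, untrained_aligned = a$at,
       trained_aligned = b$at)
}

#' Per-unit event-aligned response profiles with slow-signal classes
#'
#' For each astrocytic unit: z-score its trace over the whole recording
#' (the photometry normalization convention), align to the event, average
#' across occurrences, and classify the mean trace as trough / state-change
#' / peak with [classify_slow_signal()] (relative time measured in steps).
#'
#' @param recording A [record_rollouts()] result.
#' @param event Event label.
#' @param window Integer pair `c(pre, post)` in steps.
#' @param prominence_z Prominence threshold passed to the classifier.
#' @return List with `profiles` (units x time matrix of mean aligned
#'   traces), `classes` (factor per unit), `rel_time`.
#' @export
unit_profiles <- function(recording, event = "reward_delivered",
                          window = c(6L, 6L), prominence_z = 1) {
  nz <- ncol(recording$z)
  rel <- seq(-as.integer(window[1]), as.integer(window[2]))
  profiles <- matrix(NA_real_, nz, length(rel))
  classes <- character(nz)
  for (u in seq_len(nz)) {
    tr <- recording$z[, u]
    s <- stats::sd(tr)
    ztr <- if (s > 0) (tr - mean(tr)) / s else tr * 0
    at <- align_to_event(recording, event, window, source = ztr)
    m <- aligned_mean(at)
    profiles[u, ] <- m
    # trial edges can leave all-missing columns (e.g. the post-reward
    # window outlives the episode); classify on the covered samples
    ok <- is.finite(m)
    classes[u] <- if (sum(ok) < 3L) "state_change" else
      classify_slow_signal(m[ok], rel[ok], window = range(rel[ok]),
                           prominence_z = prominence_z)
  }
  list(profiles = profiles,
       classes = factor(classes, levels = c("trough", "state_change", "peak")),
       rel_time = rel)
}

#' Export an aligned tensor as tidy data
#' @param at An `aligned_tensor` from [align_to_event()].
#' @return Data frame with columns trial, rel_time, value.
#' @export
aligned_as_data_frame <- function(at) {
  data.frame(trial = rep(seq_len(nrow(at$values)), times = ncol(at$values)),
             rel_time = rep(at$rel_time, each = nrow(at$values)),
             value = as.numeric(at$values))
}
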