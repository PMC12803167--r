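# Trained runs are expensive; memoize them so several test blocks can share
# the same reference runs (training itself is seeded and deterministic).
.train_cache <- new.env(parent = emptyenv())

cached_train <- function(arch, seed, n_episodes = 2500L) {
  key <- sprintf("%s_%d_%d", arch, seed, n_episodes)
  if (is.null(.train_cache[[key]])) {
    .train_cache[[key]] <- train_agent(
      task_config(),
      train_config(n_episodes = n_episodes, seed = seed), arch)
  }
  .train_cache[[key]]
}
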