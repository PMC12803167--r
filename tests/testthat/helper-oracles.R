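# Scalar-by-scalar re-derivation of the tripartite update, independent of
# the vectorized implementation (explicit loops, no matrix ops).
scalar_network_step <- function(p, st, o) {
  Nx <- p$Nx; Nz <- p$Nz; g <- p$gamma; tau <- p$tau
  sig <- function(u) 1 / (1 + exp(-u))
  xn <- numeric(Nx); zn <- numeric(Nz); wn <- numeric(Nx * Nx)
  for (i in seq_len(Nx)) {
    acc <- 0
    for (j in seq_len(Nx)) acc <- acc + st$w[(i - 1) * Nx + j] * st$x[j]
    for (k in 1:3) acc <- acc + p$Winx[i, k] * o[k]
    xn[i] <- (1 - g) * st$x[i] + g * sig(acc)
  }
  for (i in seq_len(Nx)) for (j in seq_len(Nx)) {
    idx <- (i - 1) * Nx + j
    dz <- 0
    for (m in seq_len(Nz)) dz <- dz + p$D[idx, m] * st$z[m]
    wn[idx] <- (1 - g) * st$w[idx] +
      g * (sig(st$x[i] * st$x[j]) * p$C[i, j] + tanh(dz))
  }
  for (i in seq_len(Nz)) {
    f <- 0
    for (m in seq_len(Nz)) f <- f + p$F[i, m] * st$z[m]
    pool <- 0
    for (j in seq_len(Nx)) pool <- pool + p$H[i, j] * tanh(st$x[i] * st$x[j])
    inz <- 0
    for (k in 1:3) inz <- inz + p$Winz[i, k] * o[k]
    zn[i] <- (1 - g) * st$z[i] + g * tau * (tanh(f) + pool / Nx + tanh(inz))
  }
  list(x = xn, w = wn, z = zn)
}

# short rollout buffer with advantages, for update-rule tests
small_buffer <- function(agent, horizon = 12L, seed = 11L) {
  set.seed(seed)
  env <- sequence_task(task_config())
  buf <- collect_rollout(agent, env, horizon)
  compute_advantages(buf, 0.95, 0.9, TRUE)
}

# central-difference gradient of the segment loss wrt one parameter entry
numeric_grad <- function(agent, buf, cfg, nm, ii, h = 1e-6) {
  lossfn <- function(params) {
    ag <- agent; ag$params <- params
    asnen:::segment_grads(ag, buf, seq_len(buf$horizon), cfg)$loss
  }
  pp <- agent$params; pp[[nm]][ii] <- pp[[nm]][ii] + h
  pm <- agent$params; pm[[nm]][ii] <- pm[[nm]][ii] - h
  (lossfn(pp) - lossfn(pm)) / (2 * h)
}
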