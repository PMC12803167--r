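#' Initialize tripartite neuron-astrocyte network parameters
#'
#' The recurrent core couples three state vectors: neuronal activities `x`
#' (length `Nx`, kept in `[0, 1]` by a leaky sigmoidal update), a flattened
#' synaptic weight vector `w` (length `Nx^2`, reshaped row-major into the
#' recurrent matrix `W`), and astrocytic activities `z` (length `Nz`).
#' Learnable maps: `Winx`/`Winz` inject the 3-component task observation
#' into neurons/astrocytes, `C` applies element-wise gains to the squashed
#' outer product of neuronal activity (Hebbian-like synaptic drive), `D`
#' maps astrocytic activity onto synapses, `H` gates how synaptic
#' coactivation feeds back to astrocytes (each astrocyte pools one row of
#' synapses, normalized by `Nx`, which requires `Nz == Nx`), `F` couples
#' astrocytes to each other, and `Wpi`/`Wv` are the policy and value
#' readouts.
#'
#' All maps are drawn i.i.d. uniform on `[-scale, scale]`; the initial
#' synaptic state `w_init` is sparse with expected nonzero fraction
#' `w_density`.
#'
#' @param Nx,Nz Neuron and astrocyte unit counts (reference 16 and 16;
#'   `Nz` must equal `Nx`).
#' @param gamma Discretization step of the leaky updates (reference 0.01).
#' @param tau Astrocyte timescale factor, `0 < tau < 1` (default 0.5).
#' @param scale Half-width of the uniform initialization (default 0.1).
#' @param w_density Expected nonzero fraction of the initial synaptic
#'   state (default 0.1).
#' @return An `asnen_params` list of matrices plus scalars.
#' @export
asnen_params <- function(Nx = 16L, Nz = 16L, gamma = 0.01, tau = 0.5,
                         scale = 0.1, w_density = 0.1) {
  Nx <- as.integer(Nx); Nz <- as.integer(Nz)
  if (Nx < 1L || Nz < 1L) stop("invalid network config: Nx, Nz must be >= 1")
  if (Nz != Nx)
    stop("invalid network config: Nz must equal Nx (per-row synaptic pooling)")
  if (gamma <= 0 || gamma > 1) stop("invalid network config: gamma in (0, 1]")
  if (tau <= 0 || tau >= 1) stop("invalid network config: tau in (0, 1)")
  if (w_density < 0 || w_density > 1)
    stop("invalid network config: w_density in [0, 1]")
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
  w_init <- stats::runif(Nx * Nx, -scale, scale)
  w_init[stats::runif(Nx * Nx) >= w_density] <- 0
  p <- list(Winx = u(Nx, 3L), Winz = u(Nz, 3L), C = u(Nx, Nx),
            D = u(Nx * Nx, Nz), H = u(Nx, Nx), F = u(Nz, Nz),
            Wpi = u(2L, Nx), Wv = u(1L, Nz),
            gamma = gamma, tau = tau, Nx = Nx, Nz = Nz,
            w_init = w_init, w_density = w_density, scale = scale)
  class(p) <- "asnen_params"
  p
}

#' Initial dynamical state of the network
#'
#' Neuronal activity starts at the sigmoid midpoint 0.5, astrocytic
#' activity at 0, and the synaptic state at the sparse draw stored in the
#' parameters.
#'
#' @param params An [asnen_params()] object.
#' @return List with `x`, `w`, `z`.
#' @export
asnen_state <- function(params) {
  list(x = rep(0.5, params$Nx), w = params$w_init, z = rep(0, params$Nz))
}

#' One update of the tripartite dynamics
#'
#' Applies the coupled leaky updates (elementwise sigmoid/tanh; `o` is the
#' most recent observation):
#' \deqn{x_t = (1-\gamma) x_{t-1} + \gamma\,\sigma(W_{t-1} x_{t-1} + W_{in,x} o)}
#' \deqn{w_t = (1-\gamma) w_{t-1} + \gamma\,[\sigma(\mathrm{vec}(x x^T)) \odot \mathrm{vec}(C) + \tanh(D z_{t-1})]}
#' \deqn{z_t = (1-\gamma) z_{t-1} + \gamma\tau\,[\tanh(F z_{t-1}) + \mathrm{rowsum}(H \odot \tanh(x x^T))/N_x + \tanh(W_{in,z} o)]}
#'
#' @param params An [asnen_params()] object.
#' @param state List with `x`, `w`, `z` (see [asnen_state()]).
#' @param obs Numeric length-3 observation (bias, cue, reward flag).
#' @return Updated state list.
#' @export
network_step <- function(params, state, obs) {
  if (length(state$x) != params$Nx || length(state$z) != params$Nz ||
      length(state$w) != params$Nx^2)
    stop("state dimensions inconsistent with params")
  if (length(obs) != 3L) stop("observation must have 3 components")
  if (!all(is.finite(c(state$x, state$w, state$z, obs))))
    stop("non-finite network state or observation")
  res <- asnen_step_cpp(params, state$x, state$w, state$z, as.numeric(obs))
  list(x = as.numeric(res$x), w = as.numeric(res$w), z = as.numeric(res$z))
}

#' Reshape a flattened synaptic vector into the recurrent matrix
#'
#' Row-major convention: entry `(i, j)` of the matrix is `w[(i-1)*Nx + j]`.
#'
#' @param w Numeric vector of length `Nx^2`.
#' @param Nx Number of neuronal units.
#' @return `Nx x Nx` matrix.
#' @export
reshape_w <- function(w, Nx) {
  if (length(w) != Nx^2) stop("length(w) must equal Nx^2")
  matrix(w, nrow = Nx, ncol = Nx, byrow = TRUE)
}

#' Flatten a recurrent matrix row-major (inverse of [reshape_w()])
#' @param W `Nx x Nx` matrix.
#' @return Numeric vector of length `Nx^2`.
#' @export
flatten_w <- function(W) as.numeric(t(W))

#' Action probabilities from neuronal activity
#'
#' Softmax readout over the two discrete actions (move, wait).
#'
#' @param params An [asnen_params()] object (uses `Wpi`).
#' @param x Neuronal state vector.
#' @return Named numeric probability pair `c(move=, wait=)`.
#' @export
policy_distribution <- function(params, x) {
  logits <- as.numeric(params$Wpi %*% x)
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  names(p) <- c("move", "wait")
  p
}

#' State-value estimate from astrocytic activity
#'
#' Linear readout, no nonlinearity: the astrocytic layer acts as the critic.
#'
#' @param params An [asnen_params()] object (uses `Wv`).
#' @param z Astrocytic state vector.
#' @return Scalar value estimate.
#' @export
value_estimate <- function(params, z) {
  as.numeric(params$Wv %*% z)
}

asnen_trainable <- c("Winx", "Winz", "C", "D", "H", "F", "Wpi", "Wv")

#' Serialize network parameters to a JSON archive
#'
#' Writes all matrices plus metadata (sizes, gamma, tau, version) at full
#' double precision, sufficient for exact restore with [load_network()].
#'
#' @param params An `asnen_params` object (or a baseline agent's `params`).
#' @param path Output file path (`.json`).
#' @export
save_network <- function(params, path) {
  obj <- lapply(params, function(v) if (is.matrix(v)) list(dim = dim(v),
    data = as.numeric(v)) else v)
  obj$.class <- class(params)[1]
  obj$.version <- as.character(utils::packageVersion("asnen"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Restore network parameters from [save_network()] output
#' @param path Path to the JSON archive.
#' @return Parameter object with matrices restored.
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL; obj$.version <- NULL
  p <- lapply(obj, function(v) {
    if (is.list(v) && !is.null(v$dim)) matrix(v$data, v$dim[1], v$dim[2])
    else if (is.numeric(v) && length(v) == 1 &&
             !is.null(names(v))) as.numeric(v)
    else v
  })
  # scalars parsed as length-1 vectors; integers as needed
  for (nm in c("Nx", "Nz")) if (!is.null(p[[nm]])) p[[nm]] <- as.integer(p[[nm]])
  if (!is.null(cls)) class(p) <- cls
  p
}
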