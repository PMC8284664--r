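# Multitask value network: a shared linear first hidden layer (the learned
# subspace), one second-layer subnetwork of 4 hidden units per task, and a
# sigmoid output per task giving the value (reward probability) of each of
# the two possible decisions. Parameters live either as a structured list
# {W, b} or packed into a single vector theta; learning operates on theta.

#' Network architecture specification
#'
#' @param H1 first-hidden-layer size: 1 (minimal capacity) or 2 (increased).
#' @param n_tasks number of output subnetworks currently present (1 or 2).
#' @param H_per_task second-layer units per task subnetwork (4).
#' @param D input dimension (3: two cue counts plus the constant 6).
#' @param act2_by_task activation of each task's second layer: GELU for the
#'   (nonlinear, log-quadratic) first task, linear for the second.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(H1 = 1L, n_tasks = 1L, H_per_task = 4L, D = 3L,
                         act2_by_task = c("gelu", "linear")) {
  stopifnot(H1 >= 1, n_tasks >= 1, H_per_task >= 1, D >= 1,
            length(act2_by_task) >= n_tasks)
  structure(list(H1 = as.integer(H1), n_tasks = as.integer(n_tasks),
                 H = as.integer(H_per_task), D = as.integer(D),
                 act1 = "linear",
                 act2_by_task = act2_by_task[seq_len(max(2L, n_tasks))]),
            class = "network_spec")
}

#' Activation functions
#'
#' `gelu` is the exact Gaussian error linear unit `x * pnorm(x)`; `linear`
#' is the identity. `activation_deriv` gives the derivative used in
#' backpropagation.
#'
#' @param kind `"linear"` or `"gelu"`.
#' @param x numeric.
#' @return numeric of the same shape as `x`.
#' @export
activation <- function(kind, x) {
  switch(kind,
         linear = x,
         gelu = x * stats::pnorm(x),
         stop("unknown activation kind: ", kind))
}

#' @rdname activation
#' @export
activation_deriv <- function(kind, x) {
  switch(kind,
         linear = x * 0 + 1,
         gelu = stats::pnorm(x) + x * stats::dnorm(x),
         stop("unknown activation kind: ", kind))
}

# --- packed-vector layout -------------------------------------------------

# Segment order for one task:  [vec(W1); vec(W2_1); wt_1; b1; b2_1; bt_1]
# and for two tasks:           [vec(W1); vec(W2_1); vec(W2_2); wt_1; wt_2;
#                               b1; b2_1; b2_2; bt_1; bt_2],
# i.e. the two-task vector interleaves task-2 segments after their task-1
# counterparts so each field family stays contiguous. Transfer of prior
# statistics across growth is done by segment name, never raw index.

#' Parameter layout of the packed vector
#'
#' @param spec a [network_spec()].
#' @return a list with `P` (total length) and `segments`, a named list of
#'   index vectors; weight segments also record matrix dims and the task
#'   (`0` for shared) each segment belongs to.
#' @export
param_layout <- function(spec) {
  key <- paste(spec$H1, spec$n_tasks, spec$H, spec$D, sep = "/")
  hit <- .layout_cache[[key]]
  if (!is.null(hit)) return(hit)
  segs <- list()
  add <- function(name, len, task, dim = NULL) {
    segs[[name]] <<- list(len = len, task = task, dim = dim)
  }
  add("W1", spec$H1 * spec$D, 0L, c(spec$H1, spec$D))
  for (n in seq_len(spec$n_tasks)) {
    add(paste0("W2_", n), spec$H * spec$H1, n, c(spec$H, spec$H1))
  }
  for (n in seq_len(spec$n_tasks)) add(paste0("wt_", n), spec$H, n)
  add("b1", spec$H1, 0L)
  for (n in seq_len(spec$n_tasks)) add(paste0("b2_", n), spec$H, n)
  for (n in seq_len(spec$n_tasks)) add(paste0("bt_", n), 1L, n)
  off <- 0L
  for (nm in names(segs)) {
    segs[[nm]]$idx <- off + seq_len(segs[[nm]]$len)
    off <- off + segs[[nm]]$len
  }
  out <- list(P = off, segments = segs)
  .layout_cache[[key]] <- out
  out
}

.layout_cache <- new.env(parent = emptyenv())

#' Pack structured parameters into a vector / unpack a vector
#'
#' `pack_params` flattens a structured parameter list into the canonical
#' theta layout; `unpack_params` inverts it. Matrices are vectorised
#' column-major. The round trip is exact.
#'
#' @param params list with `W1` (H1 x D), `b1`, and per-task lists `W2`
#'   (H x H1), `b2`, `wt`, `bt`.
#' @param theta packed numeric vector.
#' @param spec a [network_spec()].
#' @return `pack_params`: numeric vector; `unpack_params`: parameter list.
#' @export
pack_params <- function(params, spec) {
  lay <- param_layout(spec)
  theta <- numeric(lay$P)
  segs <- lay$segments
  theta[segs$W1$idx] <- as.vector(params$W1)
  theta[segs$b1$idx] <- params$b1
  for (n in seq_len(spec$n_tasks)) {
    theta[segs[[paste0("W2_", n)]]$idx] <- as.vector(params$W2[[n]])
    theta[segs[[paste0("wt_", n)]]$idx] <- params$wt[[n]]
    theta[segs[[paste0("b2_", n)]]$idx] <- params$b2[[n]]
    theta[segs[[paste0("bt_", n)]]$idx] <- params$bt[[n]]
  }
  theta
}

#' @rdname pack_params
#' @export
unpack_params <- function(theta, spec) {
  lay <- param_layout(spec)
  if (length(theta) != lay$P) stop("theta length does not match layout")
  segs <- lay$segments
  p <- list(W1 = matrix(theta[segs$W1$idx], spec$H1, spec$D),
            b1 = theta[segs$b1$idx],
            W2 = list(), b2 = list(), wt = list(), bt = list())
  for (n in seq_len(spec$n_tasks)) {
    p$W2[[n]] <- matrix(theta[segs[[paste0("W2_", n)]]$idx], spec$H, spec$H1)
    p$wt[[n]] <- theta[segs[[paste0("wt_", n)]]$idx]
    p$b2[[n]] <- theta[segs[[paste0("b2_", n)]]$idx]
    p$bt[[n]] <- theta[segs[[paste0("bt_", n)]]$idx]
  }
  p
}

# --- forward pass ---------------------------------------------------------

# Vectorised forward pass for one task over an n x D stimulus matrix.
# Returns the intermediate quantities needed by backprop.
.forward_task <- function(params, spec, U, task) {
  if (task > spec$n_tasks) stop("task subnetwork ", task, " does not exist")
  A1 <- U %*% t(params$W1) + rep(1, nrow(U)) %o% params$b1   # n x H1
  X1 <- A1                                                   # act1 linear
  A2 <- X1 %*% t(params$W2[[task]]) +
    rep(1, nrow(U)) %o% params$b2[[task]]                    # n x H
  act2 <- spec$act2_by_task[task]
  X2 <- activation(act2, A2)
  atilde <- drop(X2 %*% params$wt[[task]]) + params$bt[[task]]
  list(A1 = A1, X1 = X1, A2 = A2, X2 = X2, atilde = atilde, act2 = act2)
}

#' Forward value computation
#'
#' Computes the pair of decision values for a stimulus under a given task:
#' `v1 = sigmoid(atilde)` (value of decision 1) and `v2 = 1 - v1`, where
#' `atilde` is the pre-sigmoid output of the task's subnetwork.
#'
#' @param params structured parameters (see [unpack_params()]).
#' @param spec a [network_spec()].
#' @param u stimulus vector or `n x 3` matrix.
#' @param task task index.
#' @return list with `v1`, `v2` and `atilde` (each length-n).
#' @export
forward_value <- function(params, spec, u, task) {
  U <- if (is.matrix(u)) u else matrix(u, 1)
  fw <- .forward_task(params, spec, U, task)
  v1 <- sigmoid(fw$atilde)
  list(v1 = v1, v2 = 1 - v1, atilde = fw$atilde)
}

# --- sensitivities and gradients ------------------------------------------

# Backward accumulation of eta = d atilde / d theta for every trial at once.
# Returns the per-segment pieces; assembling full per-trial eta vectors is
# only needed for small-net oracles and single trials.
.sensitivity_pieces <- function(params, spec, U, task, fw = NULL) {
  if (is.null(fw)) fw <- .forward_task(params, spec, U, task)
  n <- nrow(U)
  f2p <- activation_deriv(fw$act2, fw$A2)                 # n x H
  S2 <- f2p * (rep(1, n) %o% params$wt[[task]])           # d atilde / d a2
  S1 <- S2 %*% params$W2[[task]]                          # d atilde / d a1 (act1 linear)
  list(fw = fw, S2 = S2, S1 = S1)
}

#' Output sensitivity
#'
#' The gradient `eta(i) = d atilde / d theta_i` of the pre-sigmoid output
#' with respect to every packed parameter, computed by backward
#' accumulation. Entries belonging to another task's private parameters are
#' exactly zero.
#'
#' @inheritParams forward_value
#' @return numeric vector of length `param_layout(spec)$P` (single
#'   stimulus), or an `n x P` matrix for a stimulus matrix.
#' @export
output_sensitivity <- function(params, spec, u, task) {
  U <- if (is.matrix(u)) u else matrix(u, 1)
  lay <- param_layout(spec)
  sp <- .sensitivity_pieces(params, spec, U, task)
  n <- nrow(U)
  eta <- matrix(0, n, lay$P)
  segs <- lay$segments
  # W1[h, j]: S1[, h] * U[, j]; column-major over (h, j)
  for (j in seq_len(spec$D)) {
    eta[, segs$W1$idx[(j - 1L) * spec$H1 + seq_len(spec$H1)]] <-
      sp$S1 * U[, j]
  }
  eta[, segs$b1$idx] <- sp$S1
  w2seg <- segs[[paste0("W2_", task)]]
  for (h in seq_len(spec$H1)) {
    eta[, w2seg$idx[(h - 1L) * spec$H + seq_len(spec$H)]] <-
      sp$S2 * sp$fw$X1[, h]
  }
  eta[, segs[[paste0("b2_", task)]]$idx] <- sp$S2
  eta[, segs[[paste0("wt_", task)]]$idx] <- sp$fw$X2
  eta[, segs[[paste0("bt_", task)]]$idx] <- 1
  if (n == 1L) drop(eta) else eta
}

#' Gradient of one trial's sample log likelihood
#'
#' For a trial with decision `k` and reward `r`, the sample log likelihood
#' is `L = r log v_k + (1 - r) log(1 - v_k)`. Its gradient with respect to
#' theta is `(r - v_k) * eta` for `k = 1` and `-(r - v_k) * eta` for
#' `k = 2`, with `eta` the output sensitivity.
#'
#' @param params structured parameters.
#' @param spec a [network_spec()].
#' @param record one-row list/data.frame with `u` (stimulus vector), `task`,
#'   `decision`, `reward`.
#' @return gradient vector over packed parameters.
#' @export
sample_loglik_gradient <- function(params, spec, record) {
  u <- record$u
  fv <- forward_value(params, spec, u, record$task)
  eta <- output_sensitivity(params, spec, u, record$task)
  v <- if (record$decision == 1L) fv$v1 else fv$v2
  s <- if (record$decision == 1L) 1 else -1
  s * (record$reward - v) * eta
}
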