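# Sequential Bayesian learning over packed network parameters: a factorised
# Gaussian prior/posterior, the block (mini-batch) Bernoulli likelihood, the
# log joint and its gradient, MAP estimation by gradient ascent with bounded
# line search and multistart, and the diagonal Laplace precision update
# (elastic weight consolidation). The posterior after each block becomes the
# prior for the next block or task.

#' Factorised Gaussian over packed parameters
#'
#' @param m mean vector.
#' @param lambda precision vector, strictly positive, same length as `m`.
#' @return object of class `factorised_gaussian`.
#' @export
factorised_gaussian <- function(m, lambda) {
  stopifnot(length(m) == length(lambda))
  if (any(lambda <= 0)) stop("precisions must be strictly positive")
  structure(list(m = as.numeric(m), lambda = as.numeric(lambda)),
            class = "factorised_gaussian")
}

#' Initial prior over network parameters
#'
#' Zero mean everywhere. Precisions follow the fan-in heuristic — units with
#' more inputs get smaller weights: each weight's precision equals the
#' fan-in of its destination unit (first-layer weights D = 3, second-layer
#' weights H1, output weights H = 4); all biases get precision 1, so a
#' standard-normal scale.
#'
#' @param spec a [network_spec()].
#' @return a [factorised_gaussian()] over the packed layout.
#' @export
init_prior <- function(spec) {
  lay <- param_layout(spec)
  lambda <- numeric(lay$P)
  for (nm in names(lay$segments)) {
    seg <- lay$segments[[nm]]
    lambda[seg$idx] <-
      if (startsWith(nm, "W1")) spec$D
      else if (startsWith(nm, "W2")) spec$H1
      else if (startsWith(nm, "wt")) spec$H
      else 1
  }
  factorised_gaussian(numeric(lay$P), lambda)
}

#' Sample a parameter vector from a factorised Gaussian
#'
#' @param prior a [factorised_gaussian()].
#' @return numeric vector.
#' @export
sample_prior_theta <- function(prior) {
  prior$m + stats::rnorm(length(prior$m)) / sqrt(prior$lambda)
}

# --- block evaluation (vectorised core) -----------------------------------

# Every trial's likelihood is Bernoulli in the chosen decision's value; with
# v1 = sigmoid(atilde) this collapses to logistic targets
# y = 1[decision and reward agree on outcome 1], cached on the block.
# One pass computes the log likelihood, its gradient over theta, and the
# diagonal outer-product Hessian increments, per task present in the block.
.block_eval <- function(theta, spec, block, want_grad = FALSE,
                        want_lap = FALSE) {
  params <- unpack_params(theta, spec)
  lay <- param_layout(spec)
  segs <- lay$segments
  ll <- 0
  grad <- if (want_grad) numeric(lay$P) else NULL
  lap <- if (want_lap) numeric(lay$P) else NULL
  for (tk in unique(block$task)) {
    sel <- block$task == tk
    U <- block$U[sel, , drop = FALSE]
    y <- block$y[sel]
    sp <- .sensitivity_pieces(params, spec, U, tk)
    sig <- sigmoid(sp$fw$atilde)
    sigc <- clamp_prob(sig)
    ll <- ll + sum(y * log(sigc) + (1 - y) * log(1 - sigc))
    if (want_grad) {
      delta <- y - sig
      grad[segs$W1$idx] <- grad[segs$W1$idx] +
        as.vector(crossprod(sp$S1 * delta, U))
      grad[segs$b1$idx] <- grad[segs$b1$idx] + colSums(sp$S1 * delta)
      grad[segs[[paste0("W2_", tk)]]$idx] <-
        as.vector(crossprod(sp$S2 * delta, sp$fw$X1))
      grad[segs[[paste0("b2_", tk)]]$idx] <- colSums(sp$S2 * delta)
      grad[segs[[paste0("wt_", tk)]]$idx] <- colSums(sp$fw$X2 * delta)
      grad[segs[[paste0("bt_", tk)]]$idx] <- sum(delta)
    }
    if (want_lap) {
      w <- sig * (1 - sig)
      lap[segs$W1$idx] <- lap[segs$W1$idx] +
        as.vector(crossprod(sp$S1^2 * w, U^2))
      lap[segs$b1$idx] <- lap[segs$b1$idx] + colSums(sp$S1^2 * w)
      lap[segs[[paste0("W2_", tk)]]$idx] <-
        as.vector(crossprod(sp$S2^2 * w, sp$fw$X1^2))
      lap[segs[[paste0("b2_", tk)]]$idx] <- colSums(sp$S2^2 * w)
      lap[segs[[paste0("wt_", tk)]]$idx] <- colSums(sp$fw$X2^2 * w)
      lap[segs[[paste0("bt_", tk)]]$idx] <- sum(w)
    }
  }
  list(ll = ll, grad = grad, lap = lap)
}

#' Block log likelihood
#'
#' Sum over the block's trials of
#' `L_t = r_t log v_tk + (1 - r_t) log(1 - v_tk)` where `v_tk` is the value
#' the network assigned to the decision actually taken. Values are clamped
#' to machine-safe range before the log.
#'
#' @param theta packed parameter vector.
#' @param spec a [network_spec()].
#' @param block a `trial_block`.
#' @return scalar log likelihood (<= 0).
#' @export
block_log_likelihood <- function(theta, spec, block) {
  .block_eval(theta, spec, block)$ll
}

#' Average trial likelihood
#'
#' `exp(log-likelihood / n_trials)`: the geometric-mean per-trial probability
#' of the observed feedback, a.k.a. the average probability of being
#' correct. Equals 0.5 for an all-zero (chance) network.
#'
#' @inheritParams block_log_likelihood
#' @return probability in (0, 1).
#' @export
avg_trial_likelihood <- function(theta, spec, block) {
  exp(block_log_likelihood(theta, spec, block) / n_trials(block))
}

#' Log prior density and gradient
#'
#' Exact factorised-Gaussian log density
#' `-(P/2) log(2 pi) + 1/2 sum(log lambda - lambda (theta - m)^2)` and its
#' gradient `-lambda * (theta - m)`.
#'
#' @param theta packed parameter vector.
#' @param prior a [factorised_gaussian()].
#' @return `log_prior`: scalar; `log_prior_grad`: vector.
#' @export
log_prior <- function(theta, prior) {
  dev <- theta - prior$m
  -0.5 * length(theta) * log(2 * pi) +
    0.5 * sum(log(prior$lambda) - prior$lambda * dev^2)
}

#' @rdname log_prior
#' @export
log_prior_grad <- function(theta, prior) {
  -prior$lambda * (theta - prior$m)
}

#' Log joint density and gradient
#'
#' `J = log p(R_j | theta) + log p(theta | Y_{j-1})`; the gradient is the
#' sum of per-trial likelihood gradients minus `lambda * (theta - m)`.
#'
#' @inheritParams block_log_likelihood
#' @param prior a [factorised_gaussian()].
#' @param want_grad compute the gradient too?
#' @return list with `J` and (if requested) `grad`.
#' @export
log_joint <- function(theta, spec, block, prior, want_grad = TRUE) {
  be <- .block_eval(theta, spec, block, want_grad = want_grad)
  out <- list(J = be$ll + log_prior(theta, prior))
  if (want_grad) out$grad <- be$grad + log_prior_grad(theta, prior)
  out
}

#' Optimiser configuration
#'
#' @param tol convergence tolerance: iteration stops when the log joint
#'   improves by less than this between iterations (0.001).
#' @param max_iter maximum gradient-ascent iterations per start (64).
#' @param pc_T accuracy threshold: a start whose average trial likelihood
#'   reaches this value is accepted without further restarts (0.60).
#' @param maxstarts maximum multistart restarts (3).
#' @param alpha_max upper bound of the line-search step (1).
#' @param max_halvings times `alpha_max` may be halved within one iteration
#'   when the line search fails to improve (3).
#' @return list of class `optimiser_config`.
#' @export
optimiser_config <- function(tol = 0.001, max_iter = 64L, pc_T = 0.60,
                             maxstarts = 3L, alpha_max = 1, max_halvings = 3L) {
  stopifnot(tol > 0, max_iter >= 1, pc_T > 0.5, pc_T < 1, maxstarts >= 1,
            alpha_max > 0, max_halvings >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter), pc_T = pc_T,
                 maxstarts = as.integer(maxstarts), alpha_max = alpha_max,
                 max_halvings = as.integer(max_halvings)),
            class = "optimiser_config")
}

# One gradient-ascent run from theta0. Steps follow the normalised gradient
# direction so the (0, alpha_max] step bound is meaningful in parameter
# units; each iteration picks its step by bounded 1-D minimisation of -J
# over (0, alpha_max], on failure to improve alpha_max is halved (up to
# max_halvings), and if no bound yields an improvement the run terminates.
# Convergence: |dJ| < tol between successive iterations.
.ascend <- function(theta0, spec, block, prior, config, want_trace = FALSE) {
  theta <- theta0
  J <- log_joint(theta, spec, block, prior, want_grad = FALSE)$J
  if (!is.finite(J)) return(list(theta = theta, J = -Inf, ok = FALSE))
  tr <- if (want_trace) list() else NULL
  negJ <- function(a, g) {
    -log_joint(theta + a * g, spec, block, prior, want_grad = FALSE)$J
  }
  for (it in seq_len(config$max_iter)) {
    g <- log_joint(theta, spec, block, prior)$grad
    gnorm <- sqrt(sum(g^2))
    if (!is.finite(gnorm) || gnorm == 0) break
    g <- g / gnorm
    amax <- config$alpha_max
    improved <- FALSE
    for (h in 0:config$max_halvings) {
      opt <- stats::optimize(negJ, c(0, amax), g = g, tol = 1e-4)
      if (is.finite(opt$objective) && -opt$objective > J) {
        theta <- theta + opt$minimum * g
        J_new <- -opt$objective
        improved <- TRUE
        break
      }
      amax <- amax / 2
    }
    if (!improved) break
    if (want_trace) {
      tr[[length(tr) + 1L]] <-
        data.frame(iteration = it, J = J_new, alpha = opt$minimum)
    }
    converged <- abs(J_new - J) < config$tol
    J <- J_new
    if (converged) break
  }
  list(theta = theta, J = J, ok = TRUE,
       trace = if (want_trace) do.call(rbind, tr))
}

#' MAP estimation by multistart gradient ascent with line search
#'
#' Initial parameters are sampled from the prior. Each iteration steps along
#' the normalised gradient of the log joint with a step length chosen by
#' single-variable bounded minimisation of the negative log joint over step
#' sizes in `(0, alpha_max]`; if no improving step is found the maximum step
#' is halved up to `max_halvings` times, after which the run stops. Runs
#' restart from a fresh prior sample until the average trial likelihood
#' reaches `pc_T` or `maxstarts` starts are exhausted; if none reaches
#' `pc_T` the start with the highest log joint is returned.
#'
#' @param block a `trial_block` to fit.
#' @param prior a [factorised_gaussian()].
#' @param spec a [network_spec()].
#' @param config an [optimiser_config()].
#' @param trace_file optional CSV path; per-iteration rows
#'   `(start, iteration, J, alpha, avg_trial_likelihood)` are appended.
#' @return list of class `fit_result`: `theta_map`, `log_joint`,
#'   `avg_trial_likelihood`, `n_starts_used`, `flagged` (TRUE when no start
#'   reached `pc_T`).
#' @export
map_estimate <- function(block, prior, spec, config = optimiser_config(),
                         trace_file = NULL) {
  best <- NULL
  starts <- 0L
  for (s in seq_len(config$maxstarts)) {
    starts <- s
    theta0 <- sample_prior_theta(prior)
    run <- .ascend(theta0, spec, block, prior, config,
                   want_trace = !is.null(trace_file))
    if (!run$ok) next  # non-finite joint: counted as a used start
    atl <- avg_trial_likelihood(run$theta, spec, block)
    if (!is.null(trace_file) && !is.null(run$trace)) {
      tr <- cbind(start = s, run$trace, avg_trial_likelihood = atl)
      utils::write.table(tr, trace_file, sep = ",", row.names = FALSE,
                         col.names = !file.exists(trace_file),
                         append = file.exists(trace_file))
    }
    if (is.null(best) || run$J > best$log_joint) {
      best <- list(theta_map = run$theta, log_joint = run$J,
                   avg_trial_likelihood = atl)
    }
    if (atl >= config$pc_T) {
      best <- list(theta_map = run$theta, log_joint = run$J,
                   avg_trial_likelihood = atl)
      break
    }
  }
  if (is.null(best)) {  # every start diverged; fall back to the prior mean
    best <- list(theta_map = prior$m,
                 log_joint = log_joint(prior$m, spec, block, prior,
                                       want_grad = FALSE)$J,
                 avg_trial_likelihood =
                   avg_trial_likelihood(prior$m, spec, block))
  }
  best$n_starts_used <- starts
  best$flagged <- best$avg_trial_likelihood < config$pc_T
  structure(best, class = "fit_result")
}

#' Diagonal Laplace precision update
#'
#' Posterior precisions from the factorised Laplace approximation with the
#' outer-product Hessian:
#' `lambda_j(i) = lambda_{j-1}(i) + sum_t v_tk (1 - v_tk) eta_t(i)^2`,
#' where values and sensitivities are evaluated at the MAP estimate on the
#' current block's trials only. Precisions never decrease.
#'
#' @param prior a [factorised_gaussian()] (the block's prior).
#' @param theta_map MAP parameter vector for the block.
#' @param spec a [network_spec()].
#' @param block the `trial_block` just learned from.
#' @return a [factorised_gaussian()] posterior with mean `theta_map`.
#' @export
laplace_precision_update <- function(prior, theta_map, spec, block) {
  inc <- .block_eval(theta_map, spec, block, want_lap = TRUE)$lap
  factorised_gaussian(theta_map, prior$lambda + inc)
}

#' Grow a one-task network and carry its posterior forward
#'
#' Extends the packed layout with the second task's subnetwork. Shared and
#' task-1 parameters keep their posterior mean and precision from task 1
#' (segment-matched, so the re-indexing of the grown vector is transparent);
#' the new task-2 parameters receive initial-prior statistics. In the
#' reduced-precision variant the carried means are kept but every carried
#' precision is reset to its initial-prior value, removing the protection of
#' sequential Bayesian learning.
#'
#' @param posterior task-1 posterior, a [factorised_gaussian()] over the
#'   one-task layout.
#' @param spec_old the one-task [network_spec()].
#' @param spec_new the grown [network_spec()] (`n_tasks = 2`).
#' @param reduced_precision reset carried precisions to the initial prior?
#' @return a [factorised_gaussian()] over the grown layout.
#' @export
transfer_prior <- function(posterior, spec_old, spec_new,
                           reduced_precision = FALSE) {
  stopifnot(spec_new$n_tasks == spec_old$n_tasks + 1L,
            spec_new$H1 == spec_old$H1)
  lay_old <- param_layout(spec_old)
  lay_new <- param_layout(spec_new)
  base <- init_prior(spec_new)
  m <- base$m
  lambda <- base$lambda
  for (nm in names(lay_old$segments)) {
    io <- lay_old$segments[[nm]]$idx
    ix <- lay_new$segments[[nm]]$idx
    m[ix] <- posterior$m[io]
    lambda[ix] <- if (reduced_precision) base$lambda[ix] else posterior$lambda[io]
  }
  factorised_gaussian(m, lambda)
}

#' Mean posterior/prior precision ratio of first-layer weights
#'
#' @param posterior,prior [factorised_gaussian()]s over the same layout.
#' @param spec the matching [network_spec()].
#' @return mean of `lambda_post / lambda_prior` over the `W1` weights.
#' @export
precision_ratio_W1 <- function(posterior, prior, spec) {
  idx <- param_layout(spec)$segments$W1$idx
  mean(posterior$lambda[idx] / prior$lambda[idx])
}

#' Serialise a prior/posterior with its packed layout to CSV
#'
#' One row per packed parameter: segment name, within-segment index, mean
#' and precision.
#'
#' @param dist a [factorised_gaussian()].
#' @param spec the matching [network_spec()].
#' @param path output CSV path.
#' @export
write_gaussian <- function(dist, spec, path) {
  lay <- param_layout(spec)
  rows <- do.call(rbind, lapply(names(lay$segments), function(nm) {
    idx <- lay$segments[[nm]]$idx
    data.frame(segment = nm, index = seq_along(idx),
               mean = dist$m[idx], precision = dist$lambda[idx])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
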