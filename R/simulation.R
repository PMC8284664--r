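# Simulation protocols: sequential Bayesian learning over tasks and over
# 25-trial blocks, the three model variants (minimal capacity H1 = 1,
# increased capacity H1 = 2, reduced precision), and batch runs with
# per-run seeds derived from one master seed.

#' Sample a decision from a pair of values
#'
#' Decisions are sampled from the Bernoulli distribution defined by the
#' value pair: `P(k = 1) = v1`.
#'
#' @param v1 value (probability) of decision 1; vectorised.
#' @return integer decisions in `{1, 2}`.
#' @export
sample_decision <- function(v1) {
  ifelse(stats::runif(length(v1)) < v1, 1L, 2L)
}

#' Decision policy backed by a value network
#'
#' Returns a policy function for [generate_trials()] that samples decisions
#' from the network's values for the given task.
#'
#' @param theta packed parameters.
#' @param spec a [network_spec()].
#' @param task task index the policy acts for.
#' @export
network_policy <- function(theta, spec, task) {
  params <- unpack_params(theta, spec)
  function(U, n) sample_decision(forward_value(params, spec, U, task)$v1)
}

#' Simulation run configuration
#'
#' @param mode `"over_tasks"` (one 100-trial batch per task) or
#'   `"over_blocks"` (250 trials per task in 25-trial blocks, test-then-train).
#' @param variant `"minimal"` (H1 = 1), `"increased"` (H1 = 2) or
#'   `"reduced_precision"` (H1 = 1, carried precisions reset at the task
#'   boundary).
#' @param n_trials_per_task trials per task (100 over tasks, 250 over blocks).
#' @param block_size trials per learning block in over-blocks mode (25).
#' @param n_sims simulations per condition in a batch (40).
#' @param optimiser an [optimiser_config()].
#' @param stimuli stimulus sampling for generated trials: `"continuous"`
#'   (uniform over the cue space, the modelling protocol) or `"grid"`
#'   (the 25 discrete configurations shown to human subjects).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("over_tasks", "over_blocks"),
                       variant = c("minimal", "increased", "reduced_precision"),
                       n_trials_per_task = NULL, block_size = 25L,
                       n_sims = 40L, optimiser = optimiser_config(),
                       stimuli = c("continuous", "grid")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  stimuli <- match.arg(stimuli)
  if (is.null(n_trials_per_task)) {
    n_trials_per_task <- if (mode == "over_tasks") 100L else 250L
  }
  if (mode == "over_blocks" && n_trials_per_task %% block_size != 0) {
    stop("block_size must divide n_trials_per_task")
  }
  structure(list(mode = mode, variant = variant,
                 n_trials_per_task = as.integer(n_trials_per_task),
                 block_size = as.integer(block_size),
                 n_sims = as.integer(n_sims), optimiser = optimiser,
                 stimuli = stimuli),
            class = "run_config")
}

.variant_H1 <- function(variant) if (variant == "increased") 2L else 1L

#' One simulation run: sequential Bayesian learning over tasks
#'
#' Builds one dataset per task mapping (uniform stimuli; decisions sampled
#' from a network whose parameters are drawn from the initial prior; rewards
#' from the reward map), fits task 1 by MAP from the initial prior, applies
#' the Laplace precision update, grows the network, carries the task-1
#' posterior over as the task-2 prior (reduced-precision variant: means
#' kept, precisions reset), and fits task 2. Accuracy is the average trial
#' likelihood of each task's training data at its MAP estimate.
#'
#' @param condition a [make_condition()] pairing.
#' @param config a [run_config()] with `mode = "over_tasks"`.
#' @return list: `task1_acc`, `task2_acc`, `precision_ratio` (mean
#'   posterior/prior precision over first-layer weights after task 1),
#'   `flagged` (no start reached `pc_T` on either task).
#' @export
run_over_tasks <- function(condition, config = run_config("over_tasks")) {
  stopifnot(config$mode == "over_tasks")
  H1 <- .variant_H1(config$variant)
  spec1 <- network_spec(H1 = H1, n_tasks = 1L)
  spec2 <- network_spec(H1 = H1, n_tasks = 2L)
  prior1 <- init_prior(spec1)

  block1 <- generate_trials(condition$task1_map, 1L, config$n_trials_per_task,
                            policy = network_policy(sample_prior_theta(prior1),
                                                    spec1, 1L),
                            stimuli = config$stimuli)
  block2 <- generate_trials(condition$task2_map, 2L, config$n_trials_per_task,
                            policy = network_policy(
                              sample_prior_theta(init_prior(spec2)), spec2, 2L),
                            stimuli = config$stimuli)

  fit1 <- map_estimate(block1, prior1, spec1, config$optimiser)
  post1 <- laplace_precision_update(prior1, fit1$theta_map, spec1, block1)
  prior2 <- transfer_prior(post1, spec1, spec2,
                           reduced_precision =
                             config$variant == "reduced_precision")
  fit2 <- map_estimate(block2, prior2, spec2, config$optimiser)

  list(task1_acc = fit1$avg_trial_likelihood,
       task2_acc = fit2$avg_trial_likelihood,
       precision_ratio = precision_ratio_W1(post1, prior1, spec1),
       flagged = fit1$flagged || fit2$flagged)
}

#' One simulation run: sequential Bayesian learning over blocks and tasks
#'
#' Trials arrive in blocks of `block_size` (25). Each block is generated
#' on-policy — uniform stimuli, decisions sampled from the network at the
#' current posterior mean — and scored by average trial likelihood at that
#' mean *before* training on it (test-then-train). A MAP fit and Laplace
#' precision update on the block then yield the prior for the next block.
#' The posterior chains across the task boundary, where the network grows
#' and transfer priors are applied exactly as in the over-tasks protocol.
#' Per-block scores are averaged over neighbouring 25-trial blocks into
#' 50-trial learning-curve points.
#'
#' @inheritParams run_over_tasks
#' @param config a [run_config()] with `mode = "over_blocks"`.
#' @return list: `task1_acc`, `task2_acc` (means of the pre-training block
#'   scores per task), `block_scores` (one per 25-trial block), `curve`
#'   (10 points of 50 trials), `precision_ratio`, `flagged`.
#' @export
run_over_blocks <- function(condition, config = run_config("over_blocks")) {
  stopifnot(config$mode == "over_blocks")
  H1 <- .variant_H1(config$variant)
  spec1 <- network_spec(H1 = H1, n_tasks = 1L)
  spec2 <- network_spec(H1 = H1, n_tasks = 2L)
  n_blocks <- config$n_trials_per_task %/% config$block_size

  prior <- init_prior(spec1)
  init1 <- prior
  spec <- spec1
  scores <- numeric(0)
  flagged <- FALSE
  precision_ratio <- NA_real_
  for (task in 1:2) {
    map <- if (task == 1L) condition$task1_map else condition$task2_map
    if (task == 2L) {
      post1 <- prior  # posterior after the last task-1 block
      precision_ratio <- precision_ratio_W1(post1, init1, spec1)
      prior <- transfer_prior(post1, spec1, spec2,
                              reduced_precision =
                                config$variant == "reduced_precision")
      spec <- spec2
    }
    for (j in seq_len(n_blocks)) {
      blk <- generate_trials(map, task, config$block_size,
                             policy = network_policy(prior$m, spec, task),
                             block_index = (task - 1L) * n_blocks + j,
                             stimuli = config$stimuli)
      scores <- c(scores, avg_trial_likelihood(prior$m, spec, blk))
      fit <- map_estimate(blk, prior, spec, config$optimiser)
      flagged <- flagged || fit$flagged
      prior <- laplace_precision_update(prior, fit$theta_map, spec, blk)
    }
  }
  curve <- colMeans(matrix(scores, nrow = 2))
  list(task1_acc = mean(scores[seq_len(n_blocks)]),
       task2_acc = mean(scores[n_blocks + seq_len(n_blocks)]),
       block_scores = scores, curve = curve,
       precision_ratio = precision_ratio, flagged = flagged)
}

#' Batch of simulation runs over conditions
#'
#' Runs `n_sims` independent simulations per condition, each on its own
#' seed derived deterministically from the master seed, so the whole batch
#' is reproducible end to end.
#'
#' @param conditions vector of condition rows (1..4), see [make_condition()].
#' @param config a [run_config()].
#' @param master_seed integer master seed.
#' @return list with `runs` (data frame: run, condition, relation, variant,
#'   mode, seed, task1_acc, task2_acc, precision_ratio, flagged) and, in
#'   over-blocks mode, `curves` (long data frame: run, condition, relation,
#'   point, accuracy).
#' @export
run_batch <- function(conditions, config, master_seed) {
  n_total <- length(conditions) * config$n_sims
  seeds <- derive_seeds(master_seed, n_total)
  rows <- vector("list", n_total)
  curves <- list()
  i <- 0L
  for (cr in conditions) {
    cond <- make_condition(cr)
    for (s in seq_len(config$n_sims)) {
      i <- i + 1L
      set.seed(seeds[i])
      res <- if (config$mode == "over_tasks") {
        run_over_tasks(cond, config)
      } else {
        run_over_blocks(cond, config)
      }
      rows[[i]] <- data.frame(
        run = s, condition = cr, relation = cond$relation,
        variant = config$variant, mode = config$mode, seed = seeds[i],
        task1_acc = res$task1_acc, task2_acc = res$task2_acc,
        precision_ratio = res$precision_ratio, flagged = res$flagged)
      if (config$mode == "over_blocks") {
        curves[[i]] <- data.frame(
          run = s, condition = cr, relation = cond$relation,
          point = seq_along(res$curve), accuracy = res$curve)
      }
    }
  }
  out <- list(runs = do.call(rbind, rows))
  if (length(curves)) out$curves <- do.call(rbind, curves)
  out
}

#' Write a run-config to a plain key=value text file
#'
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  o <- config$optimiser
  writeLines(c(
    sprintf("mode = %s", config$mode),
    sprintf("variant = %s", config$variant),
    sprintf("n_trials_per_task = %d", config$n_trials_per_task),
    sprintf("block_size = %d", config$block_size),
    sprintf("n_sims = %d", config$n_sims),
    sprintf("stimuli = %s", config$stimuli),
    sprintf("tol = %g", o$tol),
    sprintf("max_iter = %d", o$max_iter),
    sprintf("pc_T = %g", o$pc_T),
    sprintf("maxstarts = %d", o$maxstarts),
    sprintf("alpha_max = %g", o$alpha_max),
    sprintf("max_halvings = %d", o$max_halvings)), path)
  invisible(path)
}
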