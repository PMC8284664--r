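# Task environment: stimulus grid, stimulus-reward maps, condition pairings
# and trial sampling. This is the synthetic environment both human subjects
# and the model agents face: two "pie" cues each showing 1-5 slices, a binary
# prediction (sun/rain in task 1, heads/tails in task 2), and probabilistic
# correct/incorrect feedback drawn from one of four reward maps.

# The full pie holds 6 slices; stimuli are augmented with this constant as a
# third input so additive subspaces are representable with zero bias.
.N_SLICES <- 6L

#' The 25 cue configurations
#'
#' All combinations of left and right pie slice counts, each in 1..5, with
#' the constant augmentation input `u3 = 6` (slices in a full pie) appended.
#'
#' @return a 25 x 3 numeric matrix with columns `u1`, `u2`, `u3`.
#' @export
stimulus_grid <- function() {
  g <- expand.grid(u1 = 1:5, u2 = 1:5)
  cbind(u1 = g$u1, u2 = g$u2, u3 = rep(.N_SLICES, nrow(g)))
}

#' Construct a stimulus vector
#'
#' @param u1,u2 slice counts in 1..5.
#' @return numeric vector `c(u1, u2, 6)`.
#' @export
stimulus <- function(u1, u2) {
  if (!(u1 %in% 1:5) || !(u2 %in% 1:5)) {
    stop("slice counts u1, u2 must be integers in 1..5")
  }
  c(u1 = as.numeric(u1), u2 = as.numeric(u2), u3 = as.numeric(.N_SLICES))
}

# Log-quadratic map parameters: log-odds = (u - mu)' W (u - mu) + w0 with
# mu = (3, 3), w0 = 4 and |entries of W| = 2.4 * 0.71. The sign of the
# off-diagonal entry w_d selects the relevant subspace: +0.71 collapses the
# quadratic form to -1.704 (u1 - u2)^2 (probability peaks at equal slices,
# the Sub rule), -0.71 to -1.704 (u1 + u2 - 6)^2 (peak at a full pie, Add).
.QUAD_SCALE <- 2.4
.QUAD_DIAG <- -0.71
.QUAD_W0 <- 4
.QUAD_MU <- c(3, 3)

.quad_wd <- function(subspace) if (subspace == "Sub") 0.71 else -0.71

# Calibrated slope of the log-linear maps: log-odds = beta * (x - 0.5) where
# x = u1 - u2 (Sub2) or u1 + u2 - 6 (Add2). The 0.5 offset makes the strict
# rules ("more slices on the left", "sum greater than six") the optimal
# policy; beta is solved so the best-possible accuracy is exactly 93%.
.calibrate_linear_beta <- function() {
  g <- stimulus_grid()
  z <- abs(g[, "u1"] - g[, "u2"] - 0.5)  # same |z| multiset for Add2
  stats::uniroot(function(b) mean(sigmoid(b * z)) - 0.93,
                 c(1e-3, 50), tol = 1e-12)$root
}

.env_cache <- new.env(parent = emptyenv())

linear_beta <- function() {
  if (is.null(.env_cache$beta)) .env_cache$beta <- .calibrate_linear_beta()
  .env_cache$beta
}

#' Stimulus-reward maps
#'
#' Builds one of the four reward maps. `Sub1`/`Add1` are log-quadratic: the
#' log-odds of outcome 1 (sun / heads) is a quadratic form in the cue vector.
#' `Sub2`/`Add2` are log-linear in the subspace feature, with the slope
#' calibrated so the best achievable accuracy is 93% (the log-quadratic maps
#' reach 95%). Maps within a subspace depend on the cues only through the
#' shared feature `u1 - u2` (Sub) or `u1 + u2 - 6` (Add).
#'
#' @param map_id one of `"Sub1"`, `"Add1"`, `"Sub2"`, `"Add2"`.
#' @return an object of class `reward_map`.
#' @export
reward_map <- function(map_id) {
  map_id <- match.arg(map_id, c("Sub1", "Add1", "Sub2", "Add2"))
  subspace <- substr(map_id, 1, 3)
  family <- if (substr(map_id, 4, 4) == "1") "log-quadratic" else "log-linear"
  m <- list(map_id = map_id, family = family, subspace = subspace)
  if (family == "log-quadratic") {
    wd <- .quad_wd(subspace)
    m$W <- .QUAD_SCALE * matrix(c(.QUAD_DIAG, wd, wd, .QUAD_DIAG), 2, 2)
    m$mu <- .QUAD_MU
    m$w0 <- .QUAD_W0
  } else {
    m$beta <- linear_beta()
    m$offset <- 0.5
  }
  structure(m, class = "reward_map")
}

#' @export
print.reward_map <- function(x, ...) {
  cat(sprintf("<reward_map %s: %s, subspace %s, ceiling %.1f%%>\n",
              x$map_id, x$family, x$subspace, best_possible_accuracy(x)))
  invisible(x)
}

#' Reward probability of a stimulus under a map
#'
#' Returns `p(y = 1 | u)`, the probability that outcome 1 (sun / heads) is
#' the realised outcome for cue configuration `u`.
#'
#' @param map a [reward_map()].
#' @param u a stimulus vector from [stimulus()], or a matrix with columns
#'   `u1`, `u2` (rows are stimuli). Cue values must lie in `[1, 5]`;
#'   non-integer values are allowed (continuous sampling of input space).
#' @return probability (vector), strictly inside (0, 1).
#' @export
reward_probability <- function(map, u) {
  stopifnot(inherits(map, "reward_map"))
  if (is.matrix(u)) {
    u1 <- u[, 1]; u2 <- u[, 2]
  } else {
    u1 <- u[1]; u2 <- u[2]
  }
  if (any(u1 < 1 | u1 > 5 | u2 < 1 | u2 > 5)) {
    stop("stimulus outside the cue space [1, 5] x [1, 5]")
  }
  lo <- if (map$family == "log-quadratic") {
    d1 <- u1 - map$mu[1]; d2 <- u2 - map$mu[2]
    map$W[1, 1] * d1^2 + map$W[2, 2] * d2^2 + 2 * map$W[1, 2] * d1 * d2 + map$w0
  } else {
    x <- if (map$subspace == "Sub") u1 - u2 else u1 + u2 - .N_SLICES
    map$beta * (x - map$offset)
  }
  unname(sigmoid(lo))
}

#' Best-possible classification accuracy of a reward map
#'
#' The accuracy of the argmax-probability policy, averaged uniformly over
#' the 25 cue configurations: `100 * mean(max(p, 1 - p))`.
#'
#' @param map a [reward_map()].
#' @return percentage in (50, 100).
#' @export
best_possible_accuracy <- function(map) {
  p <- reward_probability(map, stimulus_grid())
  100 * mean(pmax(p, 1 - p))
}

#' Condition pairings of first- and second-task maps
#'
#' The four between-subject conditions pairing a log-quadratic first-task map
#' with a log-linear second-task map; the pair shares a subspace ("same")
#' when both maps use the same cue feature.
#'
#' @param row condition number 1..4.
#' @return a list with elements `condition`, `task1_map`, `task2_map`
#'   (both [reward_map()]s) and `relation` (`"same"` or `"different"`).
#' @export
make_condition <- function(row) {
  if (!(length(row) == 1L && row %in% 1:4)) stop("condition row must be in 1..4")
  tab <- list(
    list("Add1", "Add2", "same"),
    list("Sub1", "Sub2", "same"),
    list("Add1", "Sub2", "different"),
    list("Sub1", "Add2", "different")
  )[[row]]
  list(condition = as.integer(row),
       task1_map = reward_map(tab[[1]]),
       task2_map = reward_map(tab[[2]]),
       relation = tab[[3]])
}

#' Sample a block of trials from a reward map
#'
#' Stimuli are drawn uniformly: either over the 25 discrete cue
#' configurations shown to human subjects (`stimuli = "grid"`) or from the
#' continuous uniform distribution covering the cue space `[1, 5]^2`
#' (`stimuli = "continuous"`, used by the model simulations). On each trial
#' the environment realises an outcome `y ~ Bernoulli(p(y = 1 | u))`; the
#' reward is `1` ("correct") when the agent's decision names the realised
#' outcome (`d = 1` chose outcome 1, `d = 2` chose outcome 2).
#'
#' @param map a [reward_map()].
#' @param task_index task label stored with every trial (1 or 2).
#' @param n_trials number of trials (>= 1).
#' @param policy decision source: a function `(U, n) -> integer vector` of
#'   decisions in `{1, 2}` given the `n x 3` stimulus matrix, or the string
#'   `"random"` (uniform decisions) or `"argmax"` (choose the more probable
#'   outcome under the map, i.e. the ceiling policy).
#' @param block_index block number stored in the log (default 1).
#' @param stimuli `"grid"` or `"continuous"` (see above).
#' @return a `trial_block`: a data frame with columns
#'   `trial, block, task, u1, u2, decision, reward` plus cached matrices used
#'   by the learning code.
#' @export
generate_trials <- function(map, task_index, n_trials, policy = "random",
                            block_index = 1L,
                            stimuli = c("grid", "continuous")) {
  stopifnot(inherits(map, "reward_map"))
  stimuli <- match.arg(stimuli)
  if (!(task_index %in% c(1L, 2L))) stop("task_index must be 1 or 2")
  if (n_trials < 1) stop("n_trials must be >= 1")
  U <- if (stimuli == "grid") {
    stimulus_grid()[sample.int(25L, n_trials, replace = TRUE), , drop = FALSE]
  } else {
    cbind(u1 = stats::runif(n_trials, 1, 5), u2 = stats::runif(n_trials, 1, 5),
          u3 = rep(as.numeric(.N_SLICES), n_trials))
  }
  p <- reward_probability(map, U)
  d <- if (is.function(policy)) {
    policy(U, n_trials)
  } else if (identical(policy, "random")) {
    sample(c(1L, 2L), n_trials, replace = TRUE)
  } else if (identical(policy, "argmax")) {
    ifelse(p >= 0.5, 1L, 2L)
  } else stop("unknown policy")
  if (any(!(d %in% c(1L, 2L)))) stop("policy must return decisions in {1, 2}")
  y <- as.integer(stats::runif(n_trials) < p)  # realised outcome (1 = sun/heads)
  r <- as.integer((d == 1L) == (y == 1L))
  trial_block(U, task = rep(as.integer(task_index), n_trials),
              decision = as.integer(d), reward = r,
              block_index = block_index)
}

#' Assemble a trial block
#'
#' @param U `n x 3` stimulus matrix (columns `u1,u2,u3`).
#' @param task,decision,reward integer vectors of length `n`.
#' @param block_index block number.
#' @return object of class `trial_block`.
#' @export
trial_block <- function(U, task, decision, reward, block_index = 1L) {
  n <- nrow(U)
  stopifnot(length(task) == n, length(decision) == n, length(reward) == n,
            n >= 1, all(reward %in% 0:1), all(decision %in% 1:2))
  records <- data.frame(
    trial = seq_len(n), block = as.integer(block_index), task = as.integer(task),
    u1 = U[, 1], u2 = U[, 2], decision = as.integer(decision),
    reward = as.integer(reward))
  structure(
    list(records = records,
         U = unname(U),
         task = as.integer(task),
         decision = as.integer(decision),
         reward = as.integer(reward),
         # y: indicator that outcome 1 was realised, recovered from (d, r)
         y = as.integer((decision == 1L) == (reward == 1L)),
         block_index = as.integer(block_index)),
    class = "trial_block")
}

#' @export
print.trial_block <- function(x, ...) {
  cat(sprintf("<trial_block %d: %d trials, task(s) %s>\n", x$block_index,
              nrow(x$records), paste(unique(x$task), collapse = ",")))
  invisible(x)
}

n_trials <- function(block) length(block$reward)

#' Write / read trial logs
#'
#' Trial logs are plain CSV with the columns
#' `trial, block, task, u1, u2, decision, reward` (1-based trial numbering).
#'
#' @param blocks a `trial_block` or list of them.
#' @param path CSV file path.
#' @return `read_trials` returns a list of `trial_block`s, one per block
#'   number in the file, in order.
#' @export
write_trials <- function(blocks, path) {
  if (inherits(blocks, "trial_block")) blocks <- list(blocks)
  recs <- do.call(rbind, lapply(blocks, `[[`, "records"))
  recs$trial <- seq_len(nrow(recs))
  utils::write.csv(recs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  recs <- utils::read.csv(path)
  need <- c("trial", "block", "task", "u1", "u2", "decision", "reward")
  if (!all(need %in% names(recs))) stop("trial log missing required columns")
  lapply(split(recs, recs$block), function(b) {
    U <- cbind(u1 = b$u1, u2 = b$u2, u3 = rep(.N_SLICES, nrow(b)))
    trial_block(U, b$task, b$decision, b$reward, block_index = b$block[1])
  })
}

#' Echo map definitions to a key-value config block
#'
#' Writes the four maps' names, families, subspace labels and parameters
#' (including the calibrated log-linear slope) as `key = value` lines.
#'
#' @param path output file.
#' @export
write_maps_config <- function(path) {
  lines <- character(0)
  for (id in c("Sub1", "Add1", "Sub2", "Add2")) {
    m <- reward_map(id)
    lines <- c(lines,
      sprintf("%s.family = %s", id, m$family),
      sprintf("%s.subspace = %s", id, m$subspace),
      if (m$family == "log-quadratic") c(
        sprintf("%s.W = %s", id, paste(format(m$W, digits = 10), collapse = " ")),
        sprintf("%s.mu = %s", id, paste(m$mu, collapse = " ")),
        sprintf("%s.w0 = %g", id, m$w0)
      ) else c(
        sprintf("%s.beta = %.10f", id, m$beta),
        sprintf("%s.offset = %g", id, m$offset)
      ),
      sprintf("%s.ceiling_pct = %.4f", id, best_possible_accuracy(m)))
  }
  writeLines(lines, path)
  invisible(path)
}
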