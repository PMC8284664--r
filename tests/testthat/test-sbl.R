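test_that("block log likelihood matches a naive per-trial loop", {
  spec <- network_spec(1, 2)
  blk <- tiny_block()
  theta <- random_theta(spec, 2)
  params <- unpack_params(theta, spec)
  ll <- 0
  for (i in seq_len(nrow(blk$records))) {
    fv <- forward_value(params, spec, blk$U[i, ], blk$task[i])
    v <- if (blk$decision[i] == 1) fv$v1 else fv$v2
    ll <- ll + blk$reward[i] * log(v) + (1 - blk$reward[i]) * log(1 - v)
  }
  expect_equal(block_log_likelihood(theta, spec, blk), ll, tolerance = 1e-12)

  # chance network: 2 trials at v = 0.5 give 2 log 0.5
  spec1 <- network_spec(1, 1)
  b2 <- trial_block(rbind(c(1, 1, 6), c(2, 2, 6)), c(1L, 1L), c(1L, 2L),
                    c(1L, 0L))
  expect_equal(block_log_likelihood(numeric(17), spec1, b2), 2 * log(0.5))
  expect_equal(avg_trial_likelihood(numeric(17), spec1, b2), 0.5)
})

test_that("log prior density and gradient are exact Gaussians", {
  pr <- factorised_gaussian(0, 1)
  expect_equal(log_prior(0, pr), -0.5 * log(2 * pi))
  expect_equal(log_prior_grad(0, pr), 0)
  expect_error(factorised_gaussian(0, 0))

  set.seed(4)
  m <- rnorm(10); lam <- rexp(10) + 0.1; th <- rnorm(10)
  pr <- factorised_gaussian(m, lam)
  expect_equal(log_prior(th, pr), sum(dnorm(th, m, 1 / sqrt(lam), log = TRUE)),
               tolerance = 1e-12)
  fd <- fd_gradient(function(x) log_prior(x, pr), th)
  expect_lt(max(abs(log_prior_grad(th, pr) - fd) / pmax(abs(fd), 1)), 1e-6)
})

test_that("log joint and its gradient agree with finite differences", {
  spec <- network_spec(1, 2)
  blk <- tiny_block()
  set.seed(9)
  prior <- factorised_gaussian(rnorm(30, sd = 0.3), rexp(30) + 0.5)
  theta <- random_theta(spec, 6)
  lj <- log_joint(theta, spec, blk, prior)
  expect_equal(lj$J, block_log_likelihood(theta, spec, blk) +
                 log_prior(theta, prior), tolerance = 1e-12)
  fd <- fd_gradient(function(th)
    log_joint(th, spec, blk, prior, want_grad = FALSE)$J, theta)
  expect_lt(max(abs(lj$grad - fd) / pmax(abs(fd), 1)), 1e-6)
})

test_that("stronger priors pull the MAP toward the prior mean (1-D toy)", {
  # single free parameter: the task-1 output bias of an otherwise-zero net;
  # grid-search oracle for the argmax of the joint
  spec <- network_spec(1, 1)
  lay <- param_layout(spec)
  bt_idx <- lay$segments$bt_1$idx
  blk <- small_block(40, seed = 12)
  joint_1d <- function(b, lam) {
    th <- numeric(17); th[bt_idx] <- b
    block_log_likelihood(th, spec, blk) - 0.5 * lam * (b - 1)^2
  }
  grid <- seq(-2, 2, by = 1e-3)
  for (lam in c(0.5, 50)) {
    assign(paste0("argmax_", lam), grid[which.max(sapply(grid, joint_1d,
                                                         lam = lam))])
  }
  # prior mean is 1: the tight prior's argmax must sit closer to it
  expect_gt(get("argmax_50"), get("argmax_0.5") - 1e-9)
  expect_lt(abs(get("argmax_50") - 1), abs(get("argmax_0.5") - 1) + 1e-9)
})

test_that("initial prior follows the fan-in rule and samples accordingly", {
  spec <- network_spec(H1 = 2, n_tasks = 2)
  pr <- init_prior(spec)
  lay <- param_layout(spec)
  expect_true(all(pr$m == 0))
  expect_equal(unname(pr$lambda[lay$segments$W1$idx]), rep(3, 6))
  expect_equal(unname(pr$lambda[lay$segments$W2_1$idx]), rep(2, 8))
  expect_equal(unname(pr$lambda[lay$segments$wt_2$idx]), rep(4, 4))
  expect_equal(unname(pr$lambda[lay$segments$b1$idx]), rep(1, 2))
  expect_equal(unname(pr$lambda[lay$segments$bt_1$idx]), 1)

  set.seed(21)
  draws <- replicate(4000, sample_prior_theta(pr))
  sds <- apply(draws, 1, sd)
  expect_equal(sds, 1 / sqrt(pr$lambda), tolerance = 0.08)
})

test_that("MAP estimation improves the joint and is deterministic", {
  spec <- network_spec(1, 1)
  prior <- init_prior(spec)
  blk <- small_block(50, seed = 30, stimuli = "continuous")
  cfg <- optimiser_config(maxstarts = 2)

  set.seed(100)
  theta0 <- sample_prior_theta(prior)
  J0 <- log_joint(theta0, spec, blk, prior, want_grad = FALSE)$J
  set.seed(100)
  fit <- map_estimate(blk, prior, spec, cfg)
  expect_s3_class(fit, "fit_result")
  expect_gte(fit$log_joint, J0)  # ascent never loses to its own start
  expect_true(fit$avg_trial_likelihood > 0 && fit$avg_trial_likelihood < 1)
  expect_lte(fit$n_starts_used, cfg$maxstarts)

  set.seed(100)
  fit2 <- map_estimate(blk, prior, spec, cfg)
  expect_identical(fit$theta_map, fit2$theta_map)
})

test_that("MAP solution is competitive with an independent optimiser", {
  spec <- network_spec(1, 1)
  prior <- init_prior(spec)
  blk <- small_block(60, seed = 31, stimuli = "continuous")
  set.seed(200)
  fit <- map_estimate(blk, prior, spec, optimiser_config())
  # oracle: BFGS with analytic gradients from the same start distribution
  set.seed(200)
  best_bfgs <- -Inf
  for (k in 1:3) {
    o <- optim(sample_prior_theta(prior),
               fn = function(th) -log_joint(th, spec, blk, prior,
                                            want_grad = FALSE)$J,
               gr = function(th) -log_joint(th, spec, blk, prior)$grad,
               method = "BFGS", control = list(maxit = 200))
    best_bfgs <- max(best_bfgs, -o$value)
  }
  # the bounded line-search ascent stops after at most 64 short steps, so it
  # may trail an unconstrained quasi-Newton run, but not catastrophically
  expect_gt(fit$log_joint, best_bfgs - 15)
})

test_that("fit traces are appended as CSV", {
  spec <- network_spec(1, 1)
  prior <- init_prior(spec)
  blk <- small_block(30, seed = 33)
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(5)
  map_estimate(blk, prior, spec, optimiser_config(maxstarts = 1),
               trace_file = path)
  tr <- read.csv(path)
  expect_true(all(c("start", "iteration", "J", "alpha",
                    "avg_trial_likelihood") %in% names(tr)))
  expect_true(all(diff(tr$J) > -1e-9))  # J non-decreasing within a start
})

test_that("Laplace update matches the dense outer-product Hessian diagonal", {
  spec <- network_spec(1, 2)
  blk <- tiny_block()
  theta <- random_theta(spec, 8)
  prior <- init_prior(spec)
  post <- laplace_precision_update(prior, theta, spec, blk)

  # dense oracle: -H = sum_t v(1-v) eta eta'
  params <- unpack_params(theta, spec)
  P <- param_layout(spec)$P
  H <- matrix(0, P, P)
  for (i in seq_len(nrow(blk$records))) {
    eta <- output_sensitivity(params, spec, blk$U[i, ], blk$task[i])
    v1 <- forward_value(params, spec, blk$U[i, ], blk$task[i])$v1
    H <- H + v1 * (1 - v1) * tcrossprod(eta)
  }
  expect_equal(post$lambda, prior$lambda + diag(H), tolerance = 1e-10)
  expect_equal(post$m, theta)
  expect_true(all(post$lambda >= prior$lambda))

  # worked increment: single trial, v = 0.5, eta_i = 2 adds 0.5 * 0.5 * 4 = 1
  spec1 <- network_spec(1, 1)
  th0 <- numeric(17)
  b1 <- trial_block(matrix(c(2, 2, 6), 1), 1L, 1L, 1L)
  post1 <- laplace_precision_update(init_prior(spec1), th0, spec1, b1)
  bt_idx <- param_layout(spec1)$segments$bt_1$idx
  # for the zero network eta(bt) = 1, so the increment there is 0.25
  expect_equal(post1$lambda[bt_idx] - 1, 0.25)
})

test_that("sequential linear-Gaussian learning equals the batch posterior", {
  set.seed(14)
  # globally orthogonal design: disjoint column support
  X <- matrix(0, 30, 3)
  X[1:10, 1] <- rnorm(10); X[11:20, 2] <- rnorm(10); X[21:30, 3] <- rnorm(10)
  theta_true <- c(1, -2, 0.5)
  beta <- 4
  y <- drop(X %*% theta_true) + rnorm(30, sd = 1 / sqrt(beta))
  prior <- factorised_gaussian(rep(0, 3), rep(2, 3))

  seq_post <- sbl_linear_gaussian(X, y, beta, prior,
                                  blocks = split(1:30, rep(1:6, each = 5)))
  bat_post <- sbl_linear_gaussian(X, y, beta, prior, blocks = list(1:30))
  expect_equal(seq_post$m, bat_post$m, tolerance = 1e-10)
  expect_equal(seq_post$lambda, bat_post$lambda, tolerance = 1e-10)

  # dense conjugate closed form
  Lam <- diag(prior$lambda) + beta * crossprod(X)
  m_cf <- drop(solve(Lam, diag(prior$lambda) %*% prior$m +
                       beta * crossprod(X, y)))
  expect_equal(seq_post$m, m_cf, tolerance = 1e-10)
  expect_equal(seq_post$lambda, diag(Lam), tolerance = 1e-10)
})

test_that("transfer priors carry statistics by segment and can be reset", {
  spec1 <- network_spec(1, 1)
  spec2 <- network_spec(1, 2)
  set.seed(17)
  post <- factorised_gaussian(rnorm(17), rexp(17) + 1)
  pr2 <- transfer_prior(post, spec1, spec2)
  lay1 <- param_layout(spec1); lay2 <- param_layout(spec2)
  for (nm in names(lay1$segments)) {
    expect_equal(pr2$m[lay2$segments[[nm]]$idx],
                 post$m[lay1$segments[[nm]]$idx])
    expect_equal(pr2$lambda[lay2$segments[[nm]]$idx],
                 post$lambda[lay1$segments[[nm]]$idx])
  }
  base <- init_prior(spec2)
  expect_equal(pr2$lambda[lay2$segments$W2_2$idx],
               base$lambda[lay2$segments$W2_2$idx])
  expect_equal(pr2$m[lay2$segments$wt_2$idx], rep(0, 4))

  rp <- transfer_prior(post, spec1, spec2, reduced_precision = TRUE)
  expect_equal(rp$m, pr2$m)  # means preserved
  expect_equal(rp$lambda, base$lambda)  # all precisions back to initial
})

test_that("posterior serialises with its layout", {
  spec <- network_spec(1, 1)
  pr <- init_prior(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaussian(pr, spec, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 17)
  expect_setequal(unique(df$segment),
                  c("W1", "W2_1", "wt_1", "b1", "b2_1", "bt_1"))
})
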