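# Exactly solvable reference case of sequential Bayesian learning: Bayesian
# linear regression with known noise precision and an independent (diagonal)
# Gaussian prior. When predictor columns are orthogonal within every block,
# the factorised posterior is exact, and chaining block posteriors as priors
# must reproduce the single-batch conjugate posterior. This is the limit in
# which the package's block-wise recursion can be validated against a
# closed form.

#' Sequential Bayesian linear regression over blocks
#'
#' Runs the sequential recursion posterior(block j) -> prior(block j + 1)
#' for the conjugate Gaussian linear model `y = X theta + e`,
#' `e ~ N(0, 1/beta)`, keeping per-parameter (diagonal) statistics:
#' `lambda_j = lambda_{j-1} + beta * diag(X_j' X_j)` and the matching mean
#' update. Exact when each block's predictor columns are orthogonal.
#'
#' @param X design matrix (rows are observations).
#' @param y response vector.
#' @param beta noise precision.
#' @param prior a [factorised_gaussian()] over the coefficients.
#' @param blocks list of row-index vectors partitioning the data into
#'   blocks, processed in order; a single block gives the batch posterior.
#' @return a [factorised_gaussian()] posterior.
#' @export
sbl_linear_gaussian <- function(X, y, beta, prior, blocks) {
  stopifnot(nrow(X) == length(y), beta > 0)
  m <- prior$m
  lambda <- prior$lambda
  for (ix in blocks) {
    Xj <- X[ix, , drop = FALSE]
    yj <- y[ix]
    lam_new <- lambda + beta * colSums(Xj^2)
    m <- (lambda * m + beta * drop(crossprod(Xj, yj))) / lam_new
    lambda <- lam_new
  }
  factorised_gaussian(m, lambda)
}
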