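# shared numeric helpers

#' Logistic function
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Probabilities are clamped away from 0/1 before taking logs so the log joint
# stays finite even for saturated value units.
.PROB_EPS <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

#' Derive a stream of child seeds from one master seed
#'
#' Simulation batches need one independent, reproducible seed per run. The
#' master seed seeds R's RNG once and the child seeds are drawn from it,
#' all below 2^31 so they remain representable as R integers.
#'
#' @param master_seed single integer.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}
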