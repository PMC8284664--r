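# Transfer statistics: Pearson correlations between task accuracies, the
# Fisher r-to-z contrast between two independent correlations, paired and
# independent t tests, and the summary table of all transfer contrasts for
# a batch of simulation runs. All p values are two-sided.

#' Pearson correlation with significance test
#'
#' Product-moment correlation with the t-based two-sided p value on
#' `n - 2` degrees of freedom (delegated to [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list of class `correlation_result`: `r`, `n`, `df`, `p`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input has zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "correlation_result")
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with the
#' two-sided normal p value.
#'
#' @param r1,r2 sample correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list of class `fisher_z_result`: `z`, `p`, and the inputs.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)),
                 r1 = r1, n1 = n1, r2 = r2, n2 = n2),
            class = "fisher_z_result")
}

#' Paired or independent t test
#'
#' Paired test on differences, or pooled-variance independent-samples test,
#' two-sided (delegated to [stats::t.test()]).
#'
#' @param x,y numeric samples.
#' @param kind `"paired"` or `"independent"`.
#' @return list of class `t_test_result`: `t`, `df`, `p`, `kind`.
#' @export
t_test <- function(x, y, kind = c("paired", "independent")) {
  kind <- match.arg(kind)
  tt <- if (kind == "paired") {
    stopifnot(length(x) == length(y))
    if (stats::sd(x - y) == 0) stop("paired differences have zero variance")
    stats::t.test(x, y, paired = TRUE)
  } else {
    stats::t.test(x, y, var.equal = TRUE)
  }
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, kind = kind),
            class = "t_test_result")
}

#' Transfer-effect summary of a simulation batch
#'
#' For a batch containing both same- and different-subspace conditions,
#' computes the full set of transfer contrasts: mean task-1 and task-2
#' accuracies by subspace relation; the paired t test of task-2 vs task-1
#' accuracy within the same-subspace runs; the independent t test of task-2
#' accuracy, same vs different; the Pearson correlation between task-1 and
#' task-2 accuracy within each relation; and the Fisher r-to-z contrast
#' between the two correlations.
#'
#' @param runs the `runs` data frame from [run_batch()] (columns
#'   `relation`, `task1_acc`, `task2_acc`).
#' @return data frame with one row per contrast: columns `contrast`,
#'   `statistic`, `value`, `df`, `p`.
#' @export
transfer_summary <- function(runs) {
  stopifnot(all(c("relation", "task1_acc", "task2_acc") %in% names(runs)))
  same <- runs[runs$relation == "same", ]
  diff <- runs[runs$relation == "different", ]
  if (nrow(same) == 0 || nrow(diff) == 0) {
    stop("batch must contain both same and different subspace conditions")
  }
  row <- function(contrast, statistic, value, df = NA_real_, p = NA_real_) {
    data.frame(contrast = contrast, statistic = statistic, value = value,
               df = df, p = p)
  }
  const_r <- function(d) stats::sd(d$task1_acc) == 0 || stats::sd(d$task2_acc) == 0
  out <- rbind(
    row("task1_mean_same", "mean", mean(same$task1_acc)),
    row("task1_mean_different", "mean", mean(diff$task1_acc)),
    row("task2_mean_same", "mean", mean(same$task2_acc)),
    row("task2_mean_different", "mean", mean(diff$task2_acc)))
  tt1 <- t_test(same$task2_acc, same$task1_acc, "paired")
  tt2 <- t_test(same$task2_acc, diff$task2_acc, "independent")
  out <- rbind(out,
               row("task2_vs_task1_same", "t_paired", tt1$t, tt1$df, tt1$p),
               row("task2_same_vs_diff", "t_independent", tt2$t, tt2$df, tt2$p))
  if (const_r(same) || const_r(diff)) {
    out <- rbind(out, row("correlation", "undefined", NA_real_))
    return(out)
  }
  cs <- pearson(same$task1_acc, same$task2_acc)
  cd <- pearson(diff$task1_acc, diff$task2_acc)
  fz <- fisher_z_compare(cs$r, cs$n, cd$r, cd$n)
  rbind(out,
        row("corr_same", "pearson_r", cs$r, cs$df, cs$p),
        row("corr_different", "pearson_r", cd$r, cd$df, cd$p),
        row("corr_same_vs_diff", "fisher_z", fz$z, NA_real_, fz$p))
}
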