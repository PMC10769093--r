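#' Bayesian bootstrap confidence interval
#'
#' Per replicate, each row receives an independent standard-exponential
#' weight normalized to mean one (a draw from the flat Dirichlet over
#' observations, scaled by n), the weighted estimator is re-run, and the
#' interval is read off the 2.5th and 97.5th percentiles of the replicate
#' estimates. Unlike the classical bootstrap no observation is ever dropped
#' entirely, which keeps sparse fixed-effect groups populated.
#'
#' @param data Analysis tibble passed to the estimator.
#' @param estimator `function(data, weights)` returning a numeric scalar or
#'   named vector.
#' @param B Number of replicates (>= 100).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param level Coverage level (default 0.95).
#' @return A list of class `ambusy_bootstrap`: `lower`, `upper` (named as
#'   the estimator output), `replicates` (matrix B x k), `B`, `dropped`.
#'   A replicate in which the estimator fails is dropped with a warning;
#'   more than 5% failures is an error.
#' @export
bayesian_bootstrap <- function(data, estimator, B = 1000, seed = 1L,
                               level = 0.95) {
  if (B < 100) {
    abort("B must be at least 100.", class = "ambusy_config_error")
  }
  n <- nrow(data)
  reps <- with_seed(derive_seed(seed, "bayesboot"), {
    lapply(seq_len(B), function(b) {
      w <- rexp(n)
      w <- w / mean(w)
      tryCatch(estimator(data, w), error = function(e) NULL)
    })
  })
  failed <- vapply(reps, is.null, logical(1))
  if (any(failed)) {
    warn(sprintf("%d of %d bootstrap replicates failed and were dropped.",
                 sum(failed), B))
    if (mean(failed) > 0.05) {
      abort("more than 5% of bootstrap replicates failed.",
            class = "ambusy_bootstrap_error")
    }
  }
  est <- do.call(rbind, reps[!failed])
  a <- (1 - level) / 2
  lower <- apply(est, 2, quantile, probs = a, names = FALSE, type = 7)
  upper <- apply(est, 2, quantile, probs = 1 - a, names = FALSE, type = 7)
  names(lower) <- names(upper) <- colnames(est)
  structure(list(lower = lower, upper = upper, replicates = est,
                 B = B, dropped = sum(failed), level = level),
            class = "ambusy_bootstrap")
}

#' @export
print.ambusy_bootstrap <- function(x, ...) {
  cat(sprintf("<ambusy_bootstrap> %d replicates (%d dropped), %.0f%% interval\n",
              x$B, x$dropped, 100 * x$level))
  for (k in seq_along(x$lower)) {
    cat(sprintf("  %s: [%.4f, %.4f]\n",
                names(x$lower)[k] %||% as.character(k),
                x$lower[k], x$upper[k]))
  }
  invisible(x)
}
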