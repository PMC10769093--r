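#' Fit the localized multinomial candidate model
#'
#' Models, for one incident's neighbor set, which unit responds as a
#' function of hour of day and day of week: the log-odds of each candidate
#' unit relative to a reference unit are linear in hour and weekday
#' dummies (a softmax-linear multinomial logistic model). Because the
#' covariates are purely categorical, the (hour, weekday) x unit count
#' table is a sufficient statistic and the model is fitted on the
#' aggregated table by damped Newton iterations with a small ridge penalty
#' (to tame separation when a unit never responds in some hour), starting
#' from zero coefficients — the fit is deterministic given the data.
#'
#' A single-unit selection yields a degenerate-deterministic model that
#' predicts probability 1 for the sole unit.
#'
#' @param neighbors An `ambusy_neighbor_set`.
#' @param selection Result of [select_candidate_units()]; computed with
#'   defaults when omitted.
#' @param ridge Ridge penalty per coefficient (default 1e-4).
#' @param max_iter Newton iteration cap (default 100).
#' @return An object of class `ambusy_candidate_model`: candidate `units`
#'   (reference first), `reference`, `coef` (one column per non-reference
#'   unit, rows intercept + hour/dow dummies), observed `hour_levels` and
#'   `dow_levels` with their reference levels, and diagnostics
#'   (`converged`, `negloglik`, `n_neighbors`, `n_train`).
#' @export
fit_local_multinomial <- function(neighbors, selection = NULL,
                                  ridge = 1e-4, max_iter = 100L) {
  stopifnot(inherits(neighbors, "ambusy_neighbor_set"))
  if (is.null(selection)) selection <- select_candidate_units(neighbors)
  nb <- neighbors$neighbors
  rows <- nb[nb$unit_id %in% selection$units, , drop = FALSE]
  units <- c(selection$reference,
             setdiff(selection$units, selection$reference))
  base <- list(units = units, reference = selection$reference,
               n_neighbors = nrow(nb), n_train = nrow(rows))

  if (length(units) == 1) {
    return(structure(c(base, list(
      coef = matrix(numeric(0), 0, 0), hour_levels = integer(0),
      dow_levels = integer(0), hour_ref = NA_integer_, dow_ref = NA_integer_,
      converged = TRUE, negloglik = 0, degenerate = TRUE
    )), class = "ambusy_candidate_model"))
  }

  tab <- context_count_table(hour_of(rows$call_time),
                             dow_of(rows$call_time),
                             rows$unit_id, units)
  fit_from_table(tab, units, base, ridge = ridge, max_iter = max_iter)
}

# aggregate training rows to the (hour, dow) x unit count table — the
# sufficient statistic of the categorical multinomial
context_count_table <- function(hour, dow, unit, units) {
  hour_levels <- sort(unique(hour))
  dow_levels <- sort(unique(dow))
  ctx_key <- hour * 8L + dow
  ctx <- which(!duplicated(ctx_key))
  g <- match(ctx_key, ctx_key[ctx])
  k <- match(unit, units)
  N <- matrix(0, length(ctx), length(units))
  for (r in seq_along(g)) N[g[r], k[r]] <- N[g[r], k[r]] + 1
  list(N = N, ctx_hour = hour[ctx], ctx_dow = dow[ctx],
       hour_levels = hour_levels, dow_levels = dow_levels)
}

fit_from_table <- function(tab, units, base, ridge = 1e-4,
                           max_iter = 100L) {
  fit <- multinom_newton(match(tab$ctx_hour, tab$hour_levels),
                         match(tab$ctx_dow, tab$dow_levels),
                         length(tab$hour_levels), length(tab$dow_levels),
                         tab$N, ridge = ridge,
                         max_iter = as.integer(max_iter))
  coefm <- fit$coef
  hl <- tab$hour_levels[-1]
  dl <- tab$dow_levels[-1]
  rownames(coefm) <- c("(Intercept)",
                       if (length(hl)) paste0("hour", hl),
                       if (length(dl)) paste0("dow", dl))
  colnames(coefm) <- units[-1]
  structure(c(base, list(
    coef = coefm, hour_levels = tab$hour_levels,
    dow_levels = tab$dow_levels,
    hour_ref = tab$hour_levels[1], dow_ref = tab$dow_levels[1],
    converged = isTRUE(fit$converged), negloglik = -fit$loglik,
    iterations = fit$iterations, degenerate = FALSE
  )), class = "ambusy_candidate_model")
}

#' @export
print.ambusy_candidate_model <- function(x, ...) {
  cat(sprintf("<ambusy_candidate_model> %d units (ref %s), %d training rows, %s\n",
              length(x$units), x$reference, x$n_train,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict candidate-response probabilities at a context
#'
#' Inverts the fitted model through the softmax: linear predictors for each
#' non-reference unit (the reference carries an implicit all-zero block)
#' are exponentiated and normalized, so the probabilities sum to one over
#' the candidate set. A context level unseen in the training rows (an hour
#' or weekday with no neighbors) falls back to intercept-only prediction
#' for that factor; the affected factors are recorded in the `"fallback"`
#' attribute.
#'
#' @param model An `ambusy_candidate_model`.
#' @param context An [incident_context()].
#' @return Named numeric vector of probabilities over the candidate units
#'   (reference first), summing to 1.
#' @export
predict_candidate_probs <- function(model, context) {
  stopifnot(inherits(model, "ambusy_candidate_model"),
            inherits(context, "ambusy_context"))
  if (isTRUE(model$degenerate)) {
    return(setNames(1, model$units))
  }
  fallback <- character(0)
  eta <- model$coef["(Intercept)", ]
  if (context$hour %in% model$hour_levels) {
    nm <- paste0("hour", context$hour)
    if (nm %in% rownames(model$coef)) eta <- eta + model$coef[nm, ]
  } else {
    fallback <- c(fallback, "hour")
  }
  if (context$dow %in% model$dow_levels) {
    nm <- paste0("dow", context$dow)
    if (nm %in% rownames(model$coef)) eta <- eta + model$coef[nm, ]
  } else {
    fallback <- c(fallback, "dow")
  }
  ex <- exp(c(0, eta) - max(0, eta))
  pr <- ex / sum(ex)
  names(pr) <- model$units
  if (length(fallback)) attr(pr, "fallback") <- fallback
  pr
}
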