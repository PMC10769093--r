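#' Assemble the per-incident analysis table
#'
#' Joins eligible incidents with their busy exposure and derives the
#' regression variables: response time, the neighbourhood x calendar-year
#' fixed-effect key, and the month / day-of-week / hour-of-day adjusters.
#' Incidents without a usable exposure (too few neighbors, non-converged
#' model) are dropped here; how many is visible by comparing row counts.
#'
#' @param eligible Eligible incident tibble (from [filter_incidents()]).
#' @param exposure Exposure tibble (from [estimate_busy_exposure()]).
#' @return Analysis tibble with `response_time`, `busy_probability`,
#'   `nb_year`, `year`, `month`, `dow`, `hour`, `urban`, `n_candidates`,
#'   `incident_type`.
#' @export
analysis_rows <- function(eligible, exposure) {
  ex <- exposure[exposure$status == "ok",
                 c("incident_id", "busy_probability", "n_candidates")]
  eligible |>
    dplyr::inner_join(ex, by = "incident_id") |>
    dplyr::mutate(
      response_time = response_time_minutes(eligible)[
        match(.data$incident_id, eligible$incident_id)],
      year = year_of(.data$call_time),
      nb_year = paste(.data$nb_id, .data$year, sep = ":"),
      month = month_of(.data$call_time),
      dow = dow_of(.data$call_time),
      hour = hour_of(.data$call_time)
    ) |>
    dplyr::select("incident_id", "response_time", "busy_probability",
                  "nb_year", "year", "month", "dow", "hour", "urban",
                  "n_candidates", "incident_type")
}

fe_triplet <- function(rows, weights = NULL) {
  fit <- fit_fixed_effects(rows, weights = weights)
  c(mean_busy_probability = mean_w(rows$busy_probability,
                                   weights %||% rep(1, nrow(rows))),
    delay_per_10pp = delay_per_10pp(fit$coefficient),
    mean_additional_min = mean_additional_time(fit))
}

#' Stratified delay estimates
#'
#' Computes, for each stratum, the mean busy probability, the delay per
#' 10-percentage-point increase in busy probability (within
#' neighbourhood-year, adjusted for month, day of week and hour), and the
#' per-incident mean additional response time, each with a Bayesian
#' bootstrap interval. Strata: overall; rural and urban; 1, 2 and >2
#' candidate ambulances; each ISO weekday; each hour of day.
#'
#' @param rows Analysis tibble from [analysis_rows()].
#' @param B Bootstrap replicates per stratum (default 200).
#' @param seed Integer seed.
#' @param min_n Strata with fewer rows are reported with `NA` intervals and
#'   point estimates only where estimable (default 200).
#' @param strata Which stratification families to compute.
#' @return A tibble of class `ambusy_estimates`: one row per stratum with
#'   point estimates, 95% bounds and `n`.
#' @export
stratified_estimates <- function(rows, B = 200, seed = 1L, min_n = 200,
                                 strata = c("overall", "urban",
                                            "candidates", "weekday",
                                            "hour")) {
  subsets <- list()
  if ("overall" %in% strata) subsets[["overall"]] <- rep(TRUE, nrow(rows))
  if ("urban" %in% strata) {
    subsets[["rural"]] <- !rows$urban
    subsets[["urban"]] <- rows$urban
  }
  if ("candidates" %in% strata) {
    subsets[["candidates=1"]] <- rows$n_candidates == 1
    subsets[["candidates=2"]] <- rows$n_candidates == 2
    subsets[["candidates>2"]] <- rows$n_candidates > 2
  }
  if ("weekday" %in% strata) {
    for (d in 1:7) subsets[[paste0("dow=", d)]] <- rows$dow == d
  }
  if ("hour" %in% strata) {
    for (h in 0:23) subsets[[paste0("hour=", h)]] <- rows$hour == h
  }

  out <- purrr::imap(subsets, function(mask, label) {
    sub <- rows[mask, , drop = FALSE]
    est <- tryCatch(fe_triplet(sub), error = function(e) {
      c(mean_busy_probability = if (nrow(sub)) mean(sub$busy_probability)
        else NA_real_,
        delay_per_10pp = NA_real_, mean_additional_min = NA_real_)
    })
    res <- tibble(
      stratum = label, n = nrow(sub),
      mean_busy_probability = est[["mean_busy_probability"]],
      mb_lower = NA_real_, mb_upper = NA_real_,
      delay_per_10pp = est[["delay_per_10pp"]],
      delay_lower = NA_real_, delay_upper = NA_real_,
      mean_additional_min = est[["mean_additional_min"]],
      add_lower = NA_real_, add_upper = NA_real_,
      replicates = 0L
    )
    if (nrow(sub) >= min_n && !is.na(est[["delay_per_10pp"]])) {
      bb <- bayesian_bootstrap(sub, fe_triplet, B = max(B, 100),
                               seed = derive_seed(seed, label))
      res$mb_lower <- bb$lower[["mean_busy_probability"]]
      res$mb_upper <- bb$upper[["mean_busy_probability"]]
      res$delay_lower <- bb$lower[["delay_per_10pp"]]
      res$delay_upper <- bb$upper[["delay_per_10pp"]]
      res$add_lower <- bb$lower[["mean_additional_min"]]
      res$add_upper <- bb$upper[["mean_additional_min"]]
      res$replicates <- nrow(bb$replicates)
    }
    res
  })
  structure(dplyr::bind_rows(out),
            class = c("ambusy_estimates", class(tibble())))
}

#' Balance test: incident type versus busy probability
#'
#' If busy ambulances were associated with the kind of incident, delay
#' comparisons could reflect case mix rather than congestion. For each of
#' the six most common incident types, the type indicator is regressed on
#' the busy probability by ridge-penalized logistic regression (penalty
#' `ridge`, unpenalized intercept) with the neighbourhood-year, month,
#' day-of-week and hour categories absorbed as covariate dummies. Reported
#' is the odds ratio per 0.10 increase in busy probability with a Bayesian
#' bootstrap interval; an unassociated type has OR near 1.
#'
#' @param rows Analysis tibble.
#' @param types Incident types to test (default the six common types, i.e.
#'   all but `"other"`).
#' @param B Bootstrap replicates (default 200; `B = 0` skips intervals).
#' @param seed Integer seed.
#' @param ridge Ridge penalty (default 1e-6).
#' @return Tibble `incident_type`, `odds_ratio_10pp`, `or_lower`,
#'   `or_upper`, `n_type`. Types absent from the data are skipped with a
#'   message.
#' @export
balance_test <- function(rows, types = setdiff(incident_types, "other"),
                         B = 200, seed = 1L, ridge = 1e-6) {
  present <- types[types %in% rows$incident_type]
  absent <- setdiff(types, present)
  if (length(absent)) {
    inform(paste0("type(s) absent from data, skipped: ",
                  paste(absent, collapse = ", ")))
  }
  X <- balance_design(rows)
  out <- purrr::map(present, function(tp) {
    yv <- as.numeric(rows$incident_type == tp)
    beta <- ridge_logistic(X, yv, ridge = ridge)
    or <- exp(beta[["busy_probability"]] * 0.10)
    lo <- hi <- NA_real_
    if (B > 0) {
      bb <- bayesian_bootstrap(
        rows,
        function(d, w) {
          b <- ridge_logistic(X, yv, weights = w, ridge = ridge)
          c(or = exp(b[["busy_probability"]] * 0.10))
        },
        B = max(B, 100), seed = derive_seed(seed, tp))
      lo <- bb$lower[["or"]]
      hi <- bb$upper[["or"]]
    }
    tibble(incident_type = tp, odds_ratio_10pp = or,
           or_lower = lo, or_upper = hi, n_type = sum(yv))
  })
  dplyr::bind_rows(out)
}

# sparse dummy design: the absorbed categories make X mostly zeros
balance_design <- function(rows) {
  f <- function(v) factor(v)
  mm <- Matrix::sparse.model.matrix(
    ~ busy_probability + f(nb_year) + f(month) + f(dow) + f(hour),
    data = data.frame(busy_probability = rows$busy_probability,
                      nb_year = rows$nb_year, month = rows$month,
                      dow = rows$dow, hour = rows$hour))
  colnames(mm)[2] <- "busy_probability"
  mm
}

# IRLS ridge logistic; intercept unpenalized. Returns named coefficients.
ridge_logistic <- function(X, y, weights = NULL, ridge = 1e-6,
                           max_iter = 50L, tol = 1e-9) {
  w0 <- if (is.null(weights)) rep(1, length(y)) else weights
  p <- ncol(X)
  pen <- rep(2 * ridge, p)
  pen[colnames(X) == "(Intercept)"] <- 0
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    wirls <- pmax(w0 * mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
    A <- as.matrix(Matrix::crossprod(X * sqrt(wirls)))
    diag(A) <- diag(A) + pen
    b <- as.numeric(Matrix::crossprod(X, wirls * z))
    newbeta <- drop(solve(A, b))
    if (max(abs(newbeta - beta)) < tol) {
      beta <- newbeta
      break
    }
    beta <- newbeta
  }
  names(beta) <- colnames(X)
  beta
}

#' Pandemic-years sensitivity analysis
#'
#' Re-runs the overall and rural/urban delay estimates on incidents whose
#' call year is outside 2020-2021, to check that pandemic-era changes in
#' demand and operations do not drive the results.
#'
#' @param rows Analysis tibble.
#' @param exclude_years Years to drop (default `c(2020, 2021)`).
#' @inheritParams stratified_estimates
#' @return An `ambusy_estimates` tibble with attribute `"n_excluded"`.
#' @export
covid_sensitivity <- function(rows, exclude_years = c(2020, 2021),
                              B = 200, seed = 1L, min_n = 200) {
  keep <- !(rows$year %in% exclude_years)
  if (!any(keep)) {
    abort("all rows fall in the excluded years; nothing to analyse.",
          class = "ambusy_empty_error")
  }
  out <- stratified_estimates(rows[keep, , drop = FALSE], B = B,
                              seed = seed, min_n = min_n,
                              strata = c("overall", "urban"))
  attr(out, "n_excluded") <- sum(!keep)
  out
}
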