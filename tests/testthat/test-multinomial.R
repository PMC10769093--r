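test_that("intercept-only fits reproduce empirical responder shares as the penalty vanishes", {
  ns <- make_neighbor_set(hours = 14, dows = 3,
                          units = rep(c("A", "B", "C"), c(60, 35, 5)))
  fit <- fit_local_multinomial(ns, ridge = 1e-9)
  expect_true(fit$converged)
  pr <- predict_candidate_probs(fit, incident_context(ns$focal_time))
  expect_equal(unname(pr[c("A", "B", "C")]), c(0.60, 0.35, 0.05),
               tolerance = 1e-5)
})

test_that("perfectly balanced two-unit data predicts one half everywhere", {
  ns <- make_neighbor_set(hours = rep(c(8, 8, 20, 20), 15), dows = 2,
                          units = rep(c("U1", "U2"), 30))
  fit <- fit_local_multinomial(ns, ridge = 1e-6)
  for (h in c(8, 20)) {
    ctx <- structure(list(hour = h, dow = 2L), class = "ambusy_context")
    pr <- predict_candidate_probs(fit, ctx)
    expect_equal(unname(pr), c(0.5, 0.5), tolerance = 1e-6)
  }
})

test_that("the Newton fit matches an independent generic-optimizer oracle", {
  withr::with_seed(7, {
    units <- sample(c("A", "B", "C"), 30, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    hours <- sample(c(9, 21), 30, replace = TRUE)
    dows <- sample(1:3, 30, replace = TRUE)
  })
  ns <- make_neighbor_set(hours = hours, dows = dows, units = units)
  ridge <- 1e-4
  fit <- fit_local_multinomial(ns, ridge = ridge)
  expect_true(fit$converged)

  sel <- select_candidate_units(ns)
  unit_levels <- c(sel$reference, setdiff(sel$units, sel$reference))
  hl <- sort(unique(hours)); dl <- sort(unique(dows))
  p <- 1 + (length(hl) - 1) + (length(dl) - 1)
  orc <- optim(rep(0, p * (length(unit_levels) - 1)),
               fn = function(par) -oracle_pll(par, hours, dows, units,
                                              unit_levels, hl, dl, ridge),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  # penalized objective at the respective optima agrees to 1e-6
  pkg_pll <- oracle_pll(as.vector(fit$coef), hours, dows, units,
                        unit_levels, hl, dl, ridge)
  expect_lt(abs(pkg_pll - (-orc$value)), 1e-6)
  # and the package's unpenalized log-likelihood is coherent with it
  expect_equal(pkg_pll + ridge * sum(fit$coef^2), -fit$negloglik,
               tolerance = 1e-8)
})

test_that("the fit agrees with nnet::multinom on a well-conditioned instance", {
  skip_if_not_installed("nnet")
  withr::with_seed(11, {
    units <- sample(c("A", "B"), 200, replace = TRUE, prob = c(0.6, 0.4))
    hours <- sample(c(8, 14, 20), 200, replace = TRUE)
    dows <- sample(1:7, 200, replace = TRUE)
  })
  ns <- make_neighbor_set(hours = hours, dows = dows, units = units)
  fit <- fit_local_multinomial(ns, ridge = 1e-8)
  nn <- nnet::multinom(factor(u, levels = c("A", "B")) ~ factor(h) + factor(d),
                       data = data.frame(u = units, h = hours, d = dows),
                       trace = FALSE, maxit = 500, reltol = 1e-12)
  ctx <- structure(list(hour = 14L, dow = 4L), class = "ambusy_context")
  pr <- predict_candidate_probs(fit, ctx)
  pr_nn <- predict(nn, newdata = data.frame(h = 14, d = 4), type = "probs")
  expect_equal(unname(pr[["B"]]), unname(pr_nn), tolerance = 1e-4)
})

test_that("predictions are softmax-consistent: normalized, shift-invariant, permutation-equivariant", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      K <- sample(2:5, 1)
      units <- paste0("U", seq_len(K))
      coefm <- matrix(rnorm(3 * (K - 1)), 3,
                      dimnames = list(c("(Intercept)", "hour10", "dow2"),
                                      units[-1]))
      model <- structure(list(units = units, reference = units[1],
                              coef = coefm, hour_levels = c(9L, 10L),
                              dow_levels = c(1L, 2L), hour_ref = 9L,
                              dow_ref = 1L, converged = TRUE,
                              degenerate = FALSE),
                         class = "ambusy_candidate_model")
      ctx <- structure(list(hour = 10L, dow = 2L), class = "ambusy_context")
      pr <- predict_candidate_probs(model, ctx)
      expect_equal(sum(pr), 1, tolerance = 1e-9)
      expect_true(all(pr >= 0 & pr <= 1))
    }
  })

  # all-zero coefficients spread probability uniformly
  zero <- structure(list(units = c("A", "B", "C"), reference = "A",
                         coef = matrix(0, 1, 2,
                                       dimnames = list("(Intercept)",
                                                       c("B", "C"))),
                         hour_levels = 10L, dow_levels = 1L, hour_ref = 10L,
                         dow_ref = 1L, converged = TRUE, degenerate = FALSE),
                    class = "ambusy_candidate_model")
  ctx <- structure(list(hour = 10L, dow = 1L), class = "ambusy_context")
  expect_equal(unname(predict_candidate_probs(zero, ctx)), rep(1 / 3, 3))

  # permuting unit labels permutes fitted predictions identically
  withr::with_seed(29, {
    units <- sample(c("A", "B", "C"), 120, replace = TRUE,
                    prob = c(0.5, 0.35, 0.15))
    hours <- sample(c(9, 15), 120, replace = TRUE)
  })
  ns1 <- make_neighbor_set(hours = hours, dows = 2, units = units)
  perm <- c(A = "X", B = "Q", C = "Z")
  ns2 <- make_neighbor_set(hours = hours, dows = 2,
                           units = unname(perm[units]))
  ctx <- structure(list(hour = 15L, dow = 2L), class = "ambusy_context")
  p1 <- predict_candidate_probs(fit_local_multinomial(ns1), ctx)
  p2 <- predict_candidate_probs(fit_local_multinomial(ns2), ctx)
  expect_equal(unname(p2[perm[names(p1)]]), unname(p1), tolerance = 1e-8)
})

test_that("degenerate and unseen-context cases degrade gracefully", {
  lone <- make_neighbor_set(hours = 10, dows = 1, units = rep("U1", 40))
  fit1 <- fit_local_multinomial(lone)
  pr1 <- predict_candidate_probs(fit1, incident_context(lone$focal_time))
  expect_equal(unname(pr1), 1)

  ns <- make_neighbor_set(hours = rep(c(9, 15), 40), dows = rep(1:4, 20),
                          units = rep(c("U1", "U1", "U2", "U2"), 20))
  fit <- fit_local_multinomial(ns)
  unseen <- structure(list(hour = 3L, dow = 6L), class = "ambusy_context")
  pr <- predict_candidate_probs(fit, unseen)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_setequal(attr(pr, "fallback"), c("hour", "dow"))
})
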