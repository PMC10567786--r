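test_that("the multinomial log-likelihood handles its edge cases", {
  m <- one_condition_model(dP = "by_condition", dA = "by_condition",
                           b = 0, g = 0, lineup_size = 2, n = 5)
  # all-zero counts contribute nothing
  expect_equal(
    suppressWarnings(
      lineup_loglik(make_counts("c1", c(0, 0, 0), c(0, 0, 0)), m, c(1, 1))
    ),
    0
  )
  # probability-one categories: 10 * log(1) = 0
  ll <- lineup_loglik(make_counts("c1", c(10, 0, 0), c(0, 0, 10)), m, c(1, 1))
  expect_equal(ll, 0)
  # two equiprobable cells: 10 * ln(0.5)
  m2 <- one_condition_model(dP = 0, dA = 1, b = 0, g = 1, lineup_size = 2,
                            n = 5)
  ll2 <- suppressWarnings(
    lineup_loglik(make_counts("c1", c(5, 5, 0), c(0, 0, 7)), m2, numeric(0))
  )
  expect_equal(ll2, 10 * log(0.5), tolerance = 1e-12)
  # a positive count in a zero-probability category is impossible data
  ll3 <- suppressWarnings(
    lineup_loglik(make_counts("c1", c(5, 5, 1), c(0, 0, 7)), m2, numeric(0))
  )
  expect_identical(ll3, -Inf)
})

test_that("counts validation catches missing, duplicated and short data", {
  fx <- lineup_study(1)
  expect_error(fit_lineup_model(fx$counts[1:3, ], fx$model), "missing")
  expect_error(fit_lineup_model(fx$counts[c(1, 1, 2, 3, 4), ], fx$model),
               "duplicate")
  skew <- fx$counts
  skew$cp_suspect[1] <- skew$cp_suspect[1] + 1L
  expect_warning(fit_lineup_model(skew, fx$model, n_starts = 2),
                 "n_participants")
})

test_that("fitting model-generated data recovers the generating parameters", {
  fx <- lineup_study(1)
  theta <- setNames(c(0.35, 0.22, 0.4, 0.27, 0.12, 0.08,
                      0.6, 0.68, 0.45, 0.5), fx$model$free_names)
  params <- expand_parameters(fx$model, theta)
  pr <- category_probs(params$dP, params$dA, params$b, params$g,
                       fx$conditions$sampling_constant)
  n <- 20000
  counts <- tibble::tibble(label = params$label)
  for (cl in names(pr)) counts[[cl]] <- round(n * pr[[cl]])
  fit <- suppressWarnings(fit_lineup_model(counts, fx$model, n_starts = 4))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), unname(theta), tolerance = 2e-3)
  expect_lt(fit$g_squared, 0.01)
  # expected counts reproduce the observed tree totals
  ec <- expected_counts(fit)
  expect_equal(ec$cp_suspect + ec$cp_filler + ec$cp_reject,
               counts$cp_suspect + counts$cp_filler + counts$cp_reject,
               tolerance = 1e-6)
})

test_that("the optimizer matches the closed-form estimator of the no-bias sub-model", {
  # with b = dA = 0, the culprit-absent tree yields the moment estimator
  # g = selection rate in culprit-absent lineups and the culprit-present
  # rejections give dP = 1 - cp_reject / (cp_total * (1 - g)). On counts
  # lying on the model surface this closed form is the MLE exactly.
  m <- one_condition_model(dP = "by_condition", dA = 0, b = 0,
                           g = "by_condition", lineup_size = 3, n = 400)
  pr <- category_probs(0.4, 0, 0, 0.55, 1 / 3)
  counts <- make_counts("c1", as.double(pr[1, 1:3]) * 800,
                        as.double(pr[1, 4:6]) * 800)
  fit <- suppressWarnings(fit_lineup_model(counts, m, n_starts = 6))
  g_hat <- (counts$ca_suspect + counts$ca_filler) / 800
  dP_hat <- 1 - counts$cp_reject / (800 * (1 - g_hat))
  expect_equal(unname(fit$estimates[["g"]]), g_hat, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[["dP"]]), dP_hat, tolerance = 1e-6)
  expect_equal(c(g_hat, dP_hat), c(0.55, 0.4), tolerance = 1e-12)

  # off the model surface both trees inform g, so the joint MLE must beat
  # the culprit-absent-only moment estimator in likelihood
  counts2 <- make_counts("c1", c(390, 210, 200), c(170, 330, 300))
  fit2 <- fit_lineup_model(counts2, m, n_starts = 6)
  g_m <- (170 + 330) / 800
  dP_m <- 1 - 200 / (800 * (1 - g_m))
  ll_moment <- lineup_loglik(counts2, m, c(dP_m, g_m))
  expect_gte(fit2$log_likelihood, ll_moment)
})

test_that("G^2 equals twice the log-likelihood gap to the saturated model", {
  fx <- lineup_study(1)
  fit <- fit_lineup_model(fx$counts, fx$model)
  counts <- as.matrix(fx$counts[, -1])
  prop <- counts / cbind(rowSums(counts[, 1:3]), rowSums(counts[, 1:3]),
                         rowSums(counts[, 1:3]), rowSums(counts[, 4:6]),
                         rowSums(counts[, 4:6]), rowSums(counts[, 4:6]))
  ll_sat <- sum(counts[counts > 0] * log(prop[counts > 0]))
  expect_equal(fit$g_squared, 2 * (ll_sat - fit$log_likelihood),
               tolerance = 1e-8)
  expect_gte(fit$g_squared, 0)
})

test_that("estimates are invariant to condition order and column order", {
  fx <- lineup_study(2)
  fit1 <- fit_lineup_model(fx$counts, fx$model)
  shuffled <- fx$counts[c(3, 1, 4, 2),
                        c("ca_reject", "label", "cp_filler", "cp_suspect",
                          "ca_suspect", "cp_reject", "ca_filler")]
  fit2 <- fit_lineup_model(shuffled, fx$model)
  expect_equal(fit1$estimates, fit2$estimates, tolerance = 1e-8)
  expect_equal(fit1$g_squared, fit2$g_squared, tolerance = 1e-8)
})

test_that("twenty random starts agree on the published datasets", {
  for (exp_id in 1:2) {
    fx <- lineup_study(exp_id)
    fit <- fit_lineup_model(fx$counts, fx$model, n_starts = 20, seed = 99)
    expect_true(fit$converged)
    expect_equal(fit$n_starts_agreeing, 20)
  }
})

test_that("standard errors shrink with the square root of the sample size", {
  fx <- lineup_study(1)
  fit1 <- fit_lineup_model(fx$counts, fx$model)
  doubled <- fx$counts
  for (cl in names(doubled)[-1]) doubled[[cl]] <- 2L * doubled[[cl]]
  fit2 <- suppressWarnings(fit_lineup_model(doubled, fx$model))
  expect_equal(unname(fit2$se), unname(fit1$se / sqrt(2)), tolerance = 0.01)
})

test_that("boundary estimates are flagged instead of given standard errors", {
  # culprit-present lineups with only suspect hits force dP to the 1 boundary
  m <- one_condition_model(dP = "by_condition", dA = 0, b = 0,
                           g = "by_condition", lineup_size = 3, n = 400)
  counts <- make_counts("c1", c(800, 0, 0), c(170, 330, 300))
  fit <- fit_lineup_model(counts, m, n_starts = 6)
  expect_true(fit$boundary[["dP"]])
  expect_true(is.na(fit$se[["dP"]]))
  expect_false(is.na(fit$se[["g"]]))
})

test_that("over-parameterized specifications are rejected before fitting", {
  conds <- lineup_conditions("only", "sequential", 3, n_participants = 10)
  m <- lineup_model(conds, dP = "by_condition", dA = "by_condition",
                    b = "by_condition", g = "by_condition")
  # 4 free on 4 df is saturated and allowed; forcing more is impossible by
  # construction, so check the df error path directly on a two-condition
  # model with every parameter condition-specific plus nothing to spare
  expect_equal(degrees_of_freedom(m), 0)
  m_over <- structure(m, class = "lineup_model")
  m_over$free_names <- c(m$free_names, "extra")
  expect_error(degrees_of_freedom(m_over), "over-parameterized")
})

test_that("tidy, glance and autoplot expose the fit", {
  fx <- lineup_study(1)
  fit <- fit_lineup_model(fx$counts, fx$model)
  td <- tidy(fit)
  expect_equal(td$term, fx$model$free_names)
  expect_true(all(td$estimate >= 0 & td$estimate <= 1))
  tdc <- tidy(fit, by_condition = TRUE)
  expect_equal(nrow(tdc), 16)
  expect_equal(dplyr::n_distinct(tdc$estimate[tdc$parameter == "b"]), 1)
  gl <- glance(fit)
  expect_equal(gl$df, 6)
  expect_s3_class(autoplot(fit, parameters = c("dP", "g")), "ggplot")
  expect_equal(unname(logLik(fit)[1]), fit$log_likelihood)
})
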