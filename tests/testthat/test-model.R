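test_that("closed-form category probabilities match the path-enumeration oracle", {
  set.seed(11)
  for (i in 1:200) {
    th <- runif(5)
    got <- category_probs(th[1], th[2], th[3], th[4], th[5])
    want <- enum_tree_probs(th[1], th[2], th[3], th[4], th[5])
    expect_equal(unlist(got), want, tolerance = 1e-12)
  }
})

test_that("degenerate parameter settings give the expected categories", {
  # certain detection of the culprit
  p <- category_probs(dP = 1, dA = 0.3, b = 0.2, g = 0.7,
                      sampling_constant = 1 / 3)
  expect_equal(unlist(p[, 1:3]),
               c(cp_suspect = 1, cp_filler = 0, cp_reject = 0))
  # pure random sampling: guess always, no detection, no bias
  p <- category_probs(dP = 0, dA = 0, b = 0, g = 1, sampling_constant = 1 / 3)
  expect_equal(unlist(p),
               c(cp_suspect = 1 / 3, cp_filler = 2 / 3, cp_reject = 0,
                 ca_suspect = 1 / 3, ca_filler = 2 / 3, ca_reject = 0))
})

test_that("a hand-evaluated suspect-identification probability is reproduced", {
  # dP + (1-dP)*b + (1-dP)*(1-b)*g*c at dP=.4, b=.07, g=.5, c=.16667
  p <- category_probs(dP = 0.4, dA = 0.11, b = 0.07, g = 0.5,
                      sampling_constant = 0.16667)
  expect_equal(round(p$cp_suspect, 5), 0.48850)
})

test_that("out-of-range parameters raise errors naming the offending field", {
  expect_error(category_probs(1.2, 0.5, 0.5, 0.5, 0.5), "'dP'")
  expect_error(category_probs(0.5, -0.1, 0.5, 0.5, 0.5), "'dA'")
  expect_error(category_probs(0.5, 0.5, 0.5, 0.5, 1.3), "'sampling_constant'")
})

test_that("both category triples always sum to one", {
  set.seed(22)
  n <- 20000
  p <- category_probs(runif(n), runif(n), runif(n), runif(n), runif(n))
  expect_lt(max(abs(p$cp_suspect + p$cp_filler + p$cp_reject - 1)), 1e-12)
  expect_lt(max(abs(p$ca_suspect + p$ca_filler + p$ca_reject - 1)), 1e-12)
  expect_true(all(as.matrix(p) >= 0 & as.matrix(p) <= 1))
})

test_that("suspect identification is monotone in detection, dispersed by size", {
  dP <- seq(0, 1, by = 0.05)
  p <- category_probs(dP, 0.2, 0.1, 0.5, 1 / 4)
  expect_true(all(diff(p$cp_suspect) >= 0))
  dA <- seq(0, 1, by = 0.05)
  p <- category_probs(0.3, dA, 0.1, 0.5, 1 / 4)
  expect_true(all(diff(p$ca_reject) >= 0))
  # larger lineups (smaller constant) push guesses from suspect to fillers
  sizes <- 2:10
  p <- category_probs(0.3, 0.2, 0.1, 0.5, 1 / sizes)
  expect_true(all(diff(p$cp_suspect) <= 0))
  expect_true(all(diff(p$ca_suspect) <= 0))
  expect_true(all(diff(p$cp_filler) >= 0))
  expect_true(all(diff(p$ca_filler) >= 0))
})

test_that("condition tables enforce their invariants", {
  expect_error(lineup_conditions("a", "sequential", 1, n_participants = 10),
               "at least 2")
  expect_error(lineup_conditions("a", "elsewise", 3, n_participants = 10),
               "sequential")
  # rounded constants within 5e-5 are accepted, coarser ones rejected
  expect_silent(lineup_conditions("a", "sequential", 3,
                                  sampling_constant = 0.33333,
                                  n_participants = 10))
  expect_error(lineup_conditions("a", "sequential", 3,
                                 sampling_constant = 0.334,
                                 n_participants = 10),
               "5e-5")
  expect_error(lineup_conditions(c("a", "a"), "sequential", 3,
                                 n_participants = 10), "unique")
})

test_that("restriction maps expand to per-condition parameters correctly", {
  fx <- lineup_study(1)
  expect_length(fx$model$free_names, 10)
  theta <- setNames(seq(0.05, 0.95, length.out = 10), fx$model$free_names)
  params <- expand_parameters(fx$model, theta)
  # shared parameters identical across conditions, specific ones distinct
  expect_length(unique(params$b), 1)
  expect_length(unique(params$dA), 1)
  expect_length(unique(params$dP), 4)
  expect_equal(params$dP, unname(theta[paste0("dP[", params$label, "]")]))

  # everything fixed: zero free values accepted
  m0 <- lineup_model(fx$conditions, dP = 0.3, dA = 0.1, b = 0, g = 0.5)
  expect_equal(n_free(m0), 0)
  p0 <- expand_parameters(m0, numeric(0))
  expect_equal(p0$dP, rep(0.3, 4))
  expect_equal(p0$g, rep(0.5, 4))

  # dP equated across sizes within format: 8 free values
  m8 <- equate_across(fx$model, "dP", "size")
  expect_length(m8$free_names, 8)
  p8 <- expand_parameters(m8, setNames(seq(0.1, 0.8, length.out = 8),
                                       m8$free_names))
  expect_equal(p8$dP[p8$label == "seq3"], p8$dP[p8$label == "seq6"])
  expect_equal(p8$dP[p8$label == "sim3"], p8$dP[p8$label == "sim6"])
  expect_false(p8$dP[1] == p8$dP[3])

  expect_error(expand_parameters(fx$model, rep(0.5, 9)), "10 free values")
  expect_error(expand_parameters(fx$model, rep(1.5, 10)), "\\[0, 1\\]")
})

test_that("expanding then collapsing is the identity on any restriction map", {
  fx <- lineup_study(1)
  set.seed(33)
  maps <- list(
    fx$model,
    equate_across(fx$model, "dP", "size"),
    equate_across(fx$model, "g", "format"),
    lineup_model(fx$conditions, dP = "shared", dA = 0.1,
                 b = c("x", "x", "y", "y"), g = "by_condition")
  )
  for (m in maps) {
    theta <- setNames(runif(n_free(m)), m$free_names)
    expect_equal(collapse_parameters(m, expand_parameters(m, theta)), theta)
  }
  # unequal values inside one class must be rejected
  bad <- expand_parameters(fx$model, setNames(runif(10), fx$model$free_names))
  bad$b[2] <- bad$b[2] + 0.01
  expect_error(collapse_parameters(fx$model, bad), "unequal")
})

test_that("goodness-of-fit degrees of freedom follow the category count", {
  fx <- lineup_study(1)
  expect_equal(degrees_of_freedom(fx$model), 6)
  expect_equal(degrees_of_freedom(equate_across(fx$model, "dP", "size")), 8)
  # saturated: one free parameter per condition and process
  msat <- lineup_model(fx$conditions, dP = "by_condition", dA = "by_condition",
                       b = "by_condition", g = "by_condition")
  expect_equal(degrees_of_freedom(msat), 0)
})

test_that("identifiability is diagnosed from the information rank", {
  fx <- lineup_study(1)
  chk <- check_identifiability(fx$model)
  expect_true(chk$identifiable)
  expect_equal(chk$rank, 10)
  # with guessing switched off, dP and b trade off within two data df
  m_bad <- one_condition_model(g = 0)
  chk_bad <- check_identifiability(m_bad)
  expect_false(chk_bad$identifiable)
  expect_lt(chk_bad$rank, chk_bad$n_free)
})
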