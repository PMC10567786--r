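#' Multinomial log-likelihood of a lineup model
#'
#' Sums `count * log(probability)` over the six response categories of every
#' condition, with `0 * log(0)` defined as 0. Returns `-Inf` when a category
#' with probability zero has a positive observed count.
#'
#' @param data Counts tibble with columns `label` and the six category
#'   counts `cp_suspect`, `cp_filler`, `cp_reject`, `ca_suspect`,
#'   `ca_filler`, `ca_reject`; one row per model condition.
#' @param model A [lineup_model()].
#' @param free_values Numeric vector of free parameter values.
#' @return The log-likelihood (up to the multinomial coefficient, which does
#'   not depend on the parameters).
#' @export
lineup_loglik <- function(data, model, free_values) {
  counts <- align_counts(data, model)
  P <- expand_matrix(model, free_values)
  pr <- prob_matrix(P[, "dP"], P[, "dA"], P[, "b"], P[, "g"],
                    model$conditions$sampling_constant)
  pos <- counts > 0
  if (any(pos & pr == 0)) return(-Inf)
  sum(counts[pos] * log(pr[pos]))
}

# order and validate a counts data frame against the model's conditions;
# returns an n x 6 matrix in category_cols order
align_counts <- function(data, model, require_positive = FALSE) {
  if (!is.data.frame(data) || !all(c("label", category_cols) %in% names(data))) {
    abort(paste0("counts data must have columns 'label', ",
                 paste(category_cols, collapse = ", ")))
  }
  labs <- model$conditions$label
  if (anyDuplicated(data$label)) {
    abort("duplicate condition labels in counts data")
  }
  i <- match(labs, data$label)
  if (anyNA(i)) {
    abort(paste0("counts data is missing condition(s): ",
                 paste(labs[is.na(i)], collapse = ", ")))
  }
  m <- as.matrix(data[i, category_cols])
  rownames(m) <- labs
  if (anyNA(m) || any(m < 0)) abort("category counts must be non-negative")
  cp_tot <- rowSums(m[, 1:3, drop = FALSE])
  ca_tot <- rowSums(m[, 4:6, drop = FALSE])
  if (require_positive && (any(cp_tot == 0) || any(ca_tot == 0))) {
    abort("every condition needs a positive culprit-present and culprit-absent total to be fittable")
  }
  expected_tot <- 2L * model$conditions$n_participants
  if (any(expected_tot > 0L & (cp_tot != expected_tot | ca_tot != expected_tot))) {
    warn(paste0("tree totals do not equal 2 x n_participants for condition(s): ",
                paste(labs[cp_tot != expected_tot | ca_tot != expected_tot],
                      collapse = ", ")))
  }
  m
}

#' Fit a 2-HT lineup model by maximum likelihood
#'
#' Maximizes the joint multinomial likelihood of the per-condition response
#' counts over the model's free parameters, using box-constrained
#' quasi-Newton optimization (`optim` method `"L-BFGS-B"`) on the
#' probability scale with multiple starting points: one start at 0.5 for
#' every parameter and `n_starts - 1` uniform-random starts governed by
#' `seed`. The best solution is retained and the number of starts agreeing
#' with it (within `1e-6` in log-likelihood) is recorded.
#'
#' Goodness of fit is the likelihood-ratio statistic
#' \deqn{G^2 = 2 \sum_{\text{cells}} O \log(O / E),}
#' summed over categories with positive observed count `O`, where the
#' expected count `E` is the fitted category probability times the observed
#' tree total; `G^2` is referred to the chi-square distribution on
#' [degrees_of_freedom()] degrees of freedom. Standard errors come from the
#' observed information matrix (numerical Hessian of the negative
#' log-likelihood at the maximum); they are reported as `NA` for estimates
#' on the `[0, 1]` boundary or when the information matrix is singular.
#'
#' @param data Counts tibble (see [lineup_loglik()]); one row per condition.
#' @param model A [lineup_model()].
#' @param n_starts Number of optimization starts (default 10).
#' @param seed Integer seed for the random starts.
#' @param compute_se Compute standard errors (default `TRUE`).
#' @param control Passed to [stats::optim()]; defaults set `maxit = 1000`
#'   and `factr = 100`. The optimizer is supplied the analytic gradient of
#'   the multinomial log-likelihood.
#'
#' @return An object of class `lineup_fit` with components `estimates`
#'   (named vector), `se`, `vcov`, `expected` (per-condition expected counts
#'   tibble), `log_likelihood`, `g_squared`, `df`, `p_value`, `converged`,
#'   `n_starts_agreeing`, `boundary` (logical per parameter), plus the model
#'   and aligned data. Supports [tidy()], [glance()], [autoplot()],
#'   `logLik()`, `coef()` and `vcov()`.
#' @examples
#' fx <- lineup_study(1)
#' fit <- fit_lineup_model(fx$counts, fx$model, seed = 1)
#' glance(fit)
#' tidy(fit)
#' @export
fit_lineup_model <- function(data, model, n_starts = 10, seed = 1,
                             compute_se = TRUE, control = list()) {
  df <- degrees_of_freedom(model)  # errors if over-parameterized
  counts <- align_counts(data, model, require_positive = TRUE)
  k <- n_free(model)
  cc <- model$conditions$sampling_constant
  eps <- 1e-8

  nll <- function(th) {
    P <- expand_matrix(model, th)
    pr <- prob_matrix(P[, "dP"], P[, "dA"], P[, "b"], P[, "g"], cc)
    -sum(counts * log(pmax(pr, 1e-300)))
  }
  # analytic gradient: d(-logL)/dtheta_j = -sum counts/p * dp/dtheta_j,
  # accumulated over the condition slots mapped to each free parameter
  nll_grad <- function(th) {
    P <- expand_matrix(model, th)
    dP <- P[, "dP"]; dA <- P[, "dA"]; b <- P[, "b"]; g <- P[, "g"]
    pr <- prob_matrix(dP, dA, b, g, cc)
    w <- counts / pmax(pr, 1e-300)
    sel <- b + (1 - b) * g * cc
    D <- list(
      dP = cbind(1 - sel, -(1 - b) * g * (1 - cc), -(1 - b) * (1 - g),
                 0, 0, 0),
      dA = cbind(0, 0, 0,
                 -sel, -(1 - b) * g * (1 - cc), 1 - (1 - b) * (1 - g)),
      b = cbind((1 - dP) * (1 - g * cc), -(1 - dP) * g * (1 - cc),
                -(1 - dP) * (1 - g),
                (1 - dA) * (1 - g * cc), -(1 - dA) * g * (1 - cc),
                -(1 - dA) * (1 - g)),
      g = cbind((1 - dP) * (1 - b) * cc, (1 - dP) * (1 - b) * (1 - cc),
                -(1 - dP) * (1 - b),
                (1 - dA) * (1 - b) * cc, (1 - dA) * (1 - b) * (1 - cc),
                -(1 - dA) * (1 - b))
    )
    grad <- numeric(length(th))
    for (p in param_names) {
      contrib <- rowSums(w * D[[p]])
      idx <- model$index[, p]
      for (i in which(idx > 0L)) grad[idx[i]] <- grad[idx[i]] - contrib[i]
    }
    grad
  }

  control <- utils::modifyList(list(maxit = 1000, factr = 100), control)
  starts <- matrix(rep(0.5, k), nrow = 1)
  if (n_starts > 1) {
    extra <- withr::with_seed(seed,
      matrix(runif((n_starts - 1) * max(k, 1)), ncol = max(k, 1)))
    starts <- rbind(starts, extra[, seq_len(k), drop = FALSE])
  }

  if (k == 0L) {
    best <- list(par = numeric(0), value = nll(numeric(0)), convergence = 0L)
    values <- best$value
  } else {
    fits <- apply(starts, 1, function(st) {
      optim(st, nll, gr = nll_grad, method = "L-BFGS-B",
            lower = eps, upper = 1 - eps, control = control)
    })
    values <- purrr::map_dbl(fits, "value")
    # among starts agreeing with the best value, prefer one whose line
    # search also terminated cleanly
    near <- which(values <= min(values) + 1e-6)
    codes <- purrr::map_dbl(fits, "convergence")
    pick <- if (any(codes[near] == 0)) near[codes[near] == 0][[1]] else near[[1]]
    best <- fits[[pick]]
  }
  estimates <- setNames(as.double(best$par), model$free_names)
  n_agree <- sum(values <= min(values) + 1e-6)

  # fitted probabilities, expected counts, G^2
  P <- expand_matrix(model, estimates)
  pr <- prob_matrix(P[, "dP"], P[, "dA"], P[, "b"], P[, "g"], cc)
  cp_tot <- rowSums(counts[, 1:3, drop = FALSE])
  ca_tot <- rowSums(counts[, 4:6, drop = FALSE])
  expected <- pr * cbind(cp_tot, cp_tot, cp_tot, ca_tot, ca_tot, ca_tot)
  obs <- counts
  if (any(obs > 0 & expected == 0)) {
    warn("observed count in a category with fitted expected count 0; G^2 is infinite")
    g2 <- Inf
  } else {
    pos <- obs > 0
    g2 <- 2 * sum(obs[pos] * log(obs[pos] / expected[pos]))
    g2 <- max(g2, 0)
  }

  boundary <- estimates <= 10 * eps | estimates >= 1 - 10 * eps
  se <- setNames(rep(NA_real_, k), model$free_names)
  vcov <- matrix(NA_real_, k, k, dimnames = list(model$free_names, model$free_names))
  info_rank <- NA_integer_
  if (compute_se && k > 0L) {
    H <- tryCatch(optimHess(estimates, nll), error = function(e) NULL)
    if (!is.null(H)) {
      info_rank <- qr(H)$rank
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        d <- diag(V)
        ok <- !boundary & d > 0
        se[ok] <- sqrt(d[ok])
        vcov[] <- V
      } else {
        warn(paste0("observed information matrix is singular (rank ", info_rank,
                    " of ", k, "); standard errors undefined"))
      }
    }
  }

  expected_tbl <- tibble::tibble(label = model$conditions$label)
  for (j in seq_along(category_cols)) {
    expected_tbl[[category_cols[j]]] <- unname(expected[, j])
  }

  structure(
    list(
      model = model,
      data = tibble::as_tibble(cbind(tibble::tibble(label = rownames(counts)),
                                     as.data.frame(counts))),
      estimates = estimates,
      se = se,
      vcov = vcov,
      boundary = boundary,
      expected = expected_tbl,
      log_likelihood = -best$value,
      g_squared = g2,
      df = df,
      p_value = chisq_tail_p(g2, max(df, 1L)) * (df > 0) + (df == 0) * 1,
      converged = identical(best$convergence, 0L) || best$convergence == 0,
      n_starts_agreeing = n_agree,
      information_rank = info_rank,
      n_starts = n_starts,
      seed = seed
    ),
    class = "lineup_fit"
  )
}

#' @export
print.lineup_fit <- function(x, ...) {
  cat("<lineup_fit> ", nrow(x$model$conditions), " conditions, ",
      length(x$estimates), " free parameters\n", sep = "")
  cat(sprintf("G^2(%d) = %.2f, p = %.3f\n", x$df, x$g_squared, x$p_value))
  est <- sprintf("%.2f", x$estimates)
  ses <- ifelse(is.na(x$se), "NA", sprintf("%.2f", x$se))
  cat(paste0("  ", format(names(x$estimates)), " = ", est, " (SE = ", ses, ")"),
      sep = "\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  cat("starts agreeing with the best solution:", x$n_starts_agreeing, "of",
      x$n_starts, "\n")
  invisible(x)
}

#' @export
coef.lineup_fit <- function(object, ...) object$estimates

#' @export
vcov.lineup_fit <- function(object, ...) object$vcov

#' @export
logLik.lineup_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$estimates),
            class = "logLik")
}

#' Per-condition expected counts of a fitted lineup model
#' @param fit A `lineup_fit`.
#' @return Tibble of expected category counts, one row per condition.
#' @export
expected_counts <- function(fit) {
  stopifnot(inherits(fit, "lineup_fit"))
  fit$expected
}
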