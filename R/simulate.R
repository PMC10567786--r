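# deterministic substream seeds: adding conditions or replicates never
# perturbs earlier streams
substream_seed <- function(root, i) {
  as.integer((as.double(root) %% 2147483647 + i * 48271) %% 2147483647)
}

#' Simulate lineup response counts from the 2-HT model
#'
#' Draws per-condition category counts from the model's category
#' probabilities under the standard design in which every participant
#' contributes `lineups_cp` culprit-present and `lineups_ca` culprit-absent
#' lineup decisions, all treated as independent multinomial observations
#' (no participant-level dependence is simulated). Each condition uses its
#' own random substream derived from `seed`, so adding a condition leaves
#' the counts of earlier conditions unchanged.
#'
#' @param model A [lineup_model()]; its conditions supply sampling constants
#'   and participant numbers.
#' @param params Generating parameters: either a named vector of free values
#'   (expanded through the model's restrictions) or a per-condition tibble
#'   with columns `label`, `dP`, `dA`, `b`, `g`.
#' @param seed Integer root seed; fixed seed implies fully reproducible
#'   counts.
#' @param lineups_cp,lineups_ca Culprit-present / culprit-absent decisions
#'   per participant (default 2 and 2).
#'
#' @return A counts tibble with columns `label` and the six category counts;
#'   each tree total equals `lineups_* * n_participants` exactly.
#' @examples
#' fx <- lineup_study(1)
#' fit <- fit_lineup_model(fx$counts, fx$model, seed = 1)
#' simulate_lineup_counts(fx$model, coef(fit), seed = 42)
#' @export
simulate_lineup_counts <- function(model, params, seed,
                                   lineups_cp = 2L, lineups_ca = 2L) {
  if (is.numeric(params) && !is.data.frame(params)) {
    params <- expand_parameters(model, params)
  }
  params <- params[match(model$conditions$label, params$label), ]
  if (anyNA(params$label)) abort("'params' must cover every condition label")
  if (any(model$conditions$n_participants <= 0L)) {
    abort("every condition needs n_participants > 0 to simulate")
  }
  pr <- category_probs(params$dP, params$dA, params$b, params$g,
                       model$conditions$sampling_constant)
  n_cp <- lineups_cp * model$conditions$n_participants
  n_ca <- lineups_ca * model$conditions$n_participants
  draw <- function(i) {
    withr::with_seed(substream_seed(seed, i), {
      cp <- rmultinom(1, n_cp[i], as.double(pr[i, 1:3]))
      ca <- rmultinom(1, n_ca[i], as.double(pr[i, 4:6]))
      c(cp, ca)
    })
  }
  m <- t(vapply(seq_len(nrow(params)), draw, numeric(6)))
  out <- tibble::tibble(label = model$conditions$label)
  for (j in seq_along(category_cols)) out[[category_cols[j]]] <- as.integer(m[, j])
  out
}

#' Parameter-recovery study for a lineup model
#'
#' Repeatedly simulates counts from the model at known generating
#' parameters, refits the model, and summarizes the sampling behaviour of
#' the estimator: bias, empirical standard deviation, average model-based
#' standard error and coverage of nominal 95% Wald intervals, per free
#' parameter. Replicates whose fit fails or does not converge are excluded
#' and counted, never silently dropped.
#'
#' @param model A [lineup_model()] that nests the generating structure.
#' @param params Generating parameters (free-value vector or per-condition
#'   tibble, as in [simulate_lineup_counts()]); parameters restricted to be
#'   equal must truly be equal.
#' @param replications Number of simulate-fit replicates.
#' @param seed Integer root seed; replicate `r` uses its own substream.
#' @param n_starts Optimization starts per replicate fit (default 2; the
#'   likelihood is well-behaved at the generating values used here).
#' @param lineups_cp,lineups_ca Decisions per participant, as in
#'   [simulate_lineup_counts()].
#'
#' @return A tibble with one row per free parameter: `term`, `generating`,
#'   `mean_estimate`, `bias`, `sd_estimate`, `mean_se`, `coverage`,
#'   `replications`; attribute `n_failed` counts excluded replicates.
#' @export
parameter_recovery <- function(model, params, replications, seed,
                               n_starts = 2, lineups_cp = 2L, lineups_ca = 2L) {
  if (replications <= 0) abort("'replications' must be positive")
  if (is.numeric(params) && !is.data.frame(params)) {
    free_true <- setNames(as.double(params), model$free_names)
    if (!is.null(names(params))) free_true <- collapse_parameters(
      model, expand_parameters(model, params))
  } else {
    free_true <- collapse_parameters(model, params)
  }
  k <- n_free(model)
  est <- matrix(NA_real_, replications, k)
  ses <- matrix(NA_real_, replications, k)
  failed <- 0L
  for (r in seq_len(replications)) {
    counts <- simulate_lineup_counts(model, free_true,
                                     seed = substream_seed(seed, 100000 + r),
                                     lineups_cp = lineups_cp,
                                     lineups_ca = lineups_ca)
    fit <- tryCatch(
      fit_lineup_model(counts, model, n_starts = n_starts,
                       seed = substream_seed(seed, 200000 + r)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      failed <- failed + 1L
      next
    }
    est[r, ] <- fit$estimates
    ses[r, ] <- fit$se
  }
  ok <- !is.na(est[, 1])
  if (!any(ok)) abort("every replicate failed to fit")
  lo <- est - 1.96 * ses
  hi <- est + 1.96 * ses
  covered <- lo <= rep(free_true, each = replications) &
             rep(free_true, each = replications) <= hi
  out <- tibble::tibble(
    term = model$free_names,
    generating = as.double(free_true),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - as.double(free_true),
    sd_estimate = apply(est[ok, , drop = FALSE], 2, sd),
    mean_se = colMeans(ses[ok, , drop = FALSE], na.rm = TRUE),
    coverage = colMeans(covered[ok, , drop = FALSE], na.rm = TRUE),
    replications = sum(ok)
  )
  attr(out, "n_failed") <- failed
  out
}
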