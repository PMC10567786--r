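#' Upper-tail chi-square probability
#'
#' Survival function of the central chi-square distribution, used to refer
#' goodness-of-fit and nested-model statistics to their asymptotic null
#' distribution.
#'
#' @param statistic Non-negative test statistic.
#' @param df Positive integer degrees of freedom.
#' @return `P(X > statistic)` for `X ~ chi-square(df)`.
#' @examples
#' chisq_tail_p(8.39, 6)
#' @export
chisq_tail_p <- function(statistic, df) {
  if (any(statistic < 0)) abort("'statistic' must be non-negative")
  if (any(df < 1)) abort("'df' must be a positive integer")
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test of nested lineup models
#'
#' Fits a base model and a restricted model to the same counts and tests the
#' restriction with the difference in likelihood-ratio goodness-of-fit
#' statistics, `deltaG^2 = G^2_restricted - G^2_base`, referred to the
#' chi-square distribution on `delta_df` (the number of free parameters
#' removed by the restriction). Both fits use the same multi-start policy
#' and seed so reports are deterministic.
#'
#' @param data Counts tibble, one row per condition.
#' @param base Base `lineup_model`.
#' @param restricted Restricted `lineup_model`; must be nested in `base`
#'   (see [is_nested()]).
#' @param label Optional description of the restriction tested.
#' @param n_starts,seed Multi-start policy passed to [fit_lineup_model()].
#'
#' @return An object of class `lineup_lrt` with `delta_g_squared`,
#'   `delta_df`, `p_value`, `base_fit`, `restricted_fit` and `label`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' fx <- lineup_study(1)
#' compare_lineup_models(fx$counts, fx$model, equate_across(fx$model, "dP", "size"))
#' @export
compare_lineup_models <- function(data, base, restricted, label = NULL,
                                  n_starts = 10, seed = 1) {
  nested <- is_nested(base, restricted)
  if (!nested) {
    abort(c("'restricted' is not nested in 'base'", attr(nested, "violations")))
  }
  delta_df <- n_free(base) - n_free(restricted)
  if (delta_df <= 0L) {
    abort(paste0("the restricted model must have fewer free parameters than ",
                 "the base model (both have ", n_free(base), "); an identical ",
                 "specification tests nothing"))
  }
  base_fit <- fit_lineup_model(data, base, n_starts = n_starts, seed = seed)
  restricted_fit <- fit_lineup_model(data, restricted, n_starts = n_starts,
                                     seed = seed)
  dg2 <- restricted_fit$g_squared - base_fit$g_squared
  if (dg2 < -1e-6) {
    warn(paste0("restricted fit improved on the base fit (deltaG^2 = ",
                signif(dg2, 4), "); check convergence"))
  }
  dg2 <- max(dg2, 0)
  structure(
    list(
      delta_g_squared = dg2,
      delta_df = delta_df,
      p_value = chisq_tail_p(dg2, delta_df),
      base_fit = base_fit,
      restricted_fit = restricted_fit,
      label = label %||% "nested-model comparison"
    ),
    class = "lineup_lrt"
  )
}

#' @export
print.lineup_lrt <- function(x, ...) {
  cat("<lineup_lrt> ", x$label, "\n", sep = "")
  cat(sprintf("deltaG^2(%d) = %.2f, p = %.3f\n",
              x$delta_df, x$delta_g_squared, x$p_value))
  cat(sprintf("base: G^2(%d) = %.2f; restricted: G^2(%d) = %.2f\n",
              x$base_fit$df, x$base_fit$g_squared,
              x$restricted_fit$df, x$restricted_fit$g_squared))
  invisible(x)
}
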