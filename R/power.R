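#' Cohen's w effect size for chi-square tests
#'
#' \deqn{w = \sqrt{\sum_i (p_{1i} - p_{0i})^2 / p_{0i}}}
#' the standardized discrepancy between an alternative and a null cell
#' probability vector.
#'
#' @param p_null Null probability vector, strictly positive, summing to 1.
#' @param p_alt Alternative probability vector of the same length, summing
#'   to 1.
#' @return Non-negative effect size `w`.
#' @examples
#' cohens_w(c(0.5, 0.5), c(0.6, 0.4))
#' @export
cohens_w <- function(p_null, p_alt) {
  if (length(p_null) != length(p_alt)) {
    abort("'p_null' and 'p_alt' must have the same length")
  }
  if (any(p_null <= 0)) abort("'p_null' must be strictly positive in every cell")
  for (nm in c("p_null", "p_alt")) {
    s <- sum(get(nm))
    if (abs(s - 1) > 1e-9) {
      abort(paste0("'", nm, "' must sum to 1 (got ", signif(s, 10), ")"))
    }
  }
  sqrt(sum((p_alt - p_null)^2 / p_null))
}

#' Power of a chi-square test via the noncentral distribution
#'
#' Power of the level-`alpha` chi-square test on `df` degrees of freedom
#' against an alternative of effect size `w` with `n_observations` total
#' observations: the noncentral chi-square survival function with
#' noncentrality `lambda = n_observations * w^2`, evaluated at the central
#' `1 - alpha` quantile. In a lineup design each participant typically
#' contributes several decisions; `n_observations` counts decisions, not
#' participants.
#'
#' @param w Cohen's effect size `w` (non-negative).
#' @param n_observations Positive total observation count.
#' @param df Positive integer degrees of freedom.
#' @param alpha Significance level in (0, 1).
#' @return Power in `[alpha, 1)`; equals `alpha` when `w = 0`.
#' @examples
#' chisq_power(w = 0.05, n_observations = 1537 * 4, df = 2)
#' @export
chisq_power <- function(w, n_observations, df, alpha = 0.05) {
  if (any(w < 0)) abort("'w' must be non-negative")
  if (n_observations <= 0) abort("'n_observations' must be positive")
  if (df < 1) abort("'df' must be a positive integer")
  if (alpha <= 0 || alpha >= 1) abort("'alpha' must lie in (0, 1)")
  crit <- qchisq(1 - alpha, df = df)
  pchisq(crit, df = df, ncp = n_observations * w^2, lower.tail = FALSE)
}

#' Minimal detectable effect size of a chi-square test
#'
#' Solves for the Cohen's `w` at which [chisq_power()] attains the requested
#' power — the sensitivity of a design. Equivalently `sqrt(lambda* / N)`
#' where `lambda*` is the noncentrality at which the noncentral chi-square
#' test first reaches the target power; the solution is found by monotone
#' root-finding on `w` in `[0, 3]` to a tolerance of 1e-8.
#'
#' @inheritParams chisq_power
#' @param power Target power in `(alpha, 1)`.
#' @return The minimal detectable `w`.
#' @examples
#' # sensitivity of a 1537-participant design with 4 decisions per participant
#' minimal_detectable_w(1537 * 4, df = 2, alpha = 0.05, power = 0.95)
#' @export
minimal_detectable_w <- function(n_observations, df, alpha = 0.05,
                                 power = 0.95) {
  if (power <= alpha || power >= 1) {
    abort("'power' must lie in (alpha, 1)")
  }
  f <- function(w) chisq_power(w, n_observations, df, alpha) - power
  if (f(3) < 0) {
    abort(paste0("requested power ", power, " is unattainable with w <= 3 at ",
                 "N = ", n_observations, ", df = ", df))
  }
  uniroot(f, interval = c(0, 3), tol = 1e-8)$root
}
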