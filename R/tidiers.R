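#' Tidy a fitted lineup model
#'
#' @param x A `lineup_fit`.
#' @param by_condition If `TRUE`, return one row per condition and process
#'   parameter (restricted parameters repeat their shared estimate; fixed
#'   parameters appear with `NA` standard error). Default `FALSE`: one row
#'   per free parameter.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` (plus
#'   `label` and `parameter` when `by_condition = TRUE`).
#' @export
tidy.lineup_fit <- function(x, by_condition = FALSE, ...) {
  if (!by_condition) {
    return(tibble::tibble(
      term = names(x$estimates),
      estimate = as.double(x$estimates),
      std.error = as.double(x$se)
    ))
  }
  model <- x$model
  params <- expand_parameters(model, x$estimates)
  long <- tidyr::pivot_longer(params, dplyr::all_of(param_names),
                              names_to = "parameter", values_to = "estimate")
  long$std.error <- purrr::map2_dbl(long$parameter, long$label, function(p, l) {
    j <- model$index[l, p]
    if (j == 0L) NA_real_ else as.double(x$se[[j]])
  })
  long$term <- purrr::map2_chr(long$parameter, long$label, function(p, l) {
    j <- model$index[l, p]
    if (j == 0L) paste0(p, "=", model$fixed[l, p]) else model$free_names[[j]]
  })
  long[, c("label", "parameter", "term", "estimate", "std.error")]
}

#' Glance at a fitted lineup model
#'
#' @param x A `lineup_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `g_squared`, `df`, `p_value`,
#'   `log_likelihood`, `n_free`, `converged`, `n_starts_agreeing`.
#' @export
glance.lineup_fit <- function(x, ...) {
  tibble::tibble(
    g_squared = x$g_squared,
    df = x$df,
    p_value = x$p_value,
    log_likelihood = x$log_likelihood,
    n_free = length(x$estimates),
    converged = x$converged,
    n_starts_agreeing = x$n_starts_agreeing
  )
}

#' Tidy a nested-model lineup test
#'
#' @param x A `lineup_lrt`.
#' @param ... Unused.
#' @return A one-row tibble with the restriction label, `delta_g_squared`,
#'   `delta_df`, `p_value` and both models' `G^2`.
#' @export
tidy.lineup_lrt <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    delta_g_squared = x$delta_g_squared,
    delta_df = x$delta_df,
    p_value = x$p_value,
    base_g_squared = x$base_fit$g_squared,
    restricted_g_squared = x$restricted_fit$g_squared
  )
}

#' @rdname tidy.lineup_lrt
#' @export
glance.lineup_lrt <- function(x, ...) tidy(x)

#' Plot per-condition parameter estimates of a fitted lineup model
#'
#' Bar chart of the estimated process probabilities per condition with
#' standard-error bars, faceted by parameter (fixed parameters are omitted).
#'
#' @param object A `lineup_fit`.
#' @param parameters Which process parameters to display; defaults to all
#'   free ones.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lineup_fit <- function(object,
                                parameters = c("dP", "dA", "b", "g"), ...) {
  free_ps <- names(which(purrr::map_chr(object$model$spec, "kind") == "free"))
  parameters <- intersect(parameters, free_ps)
  d <- tidy(object, by_condition = TRUE)
  d <- dplyr::filter(d, .data$parameter %in% parameters)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = "condition", y = "estimated probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
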