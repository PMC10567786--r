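#' Run a full base-model-plus-contrasts lineup analysis
#'
#' Fits the base model to a counts table and runs any requested nested-model
#' contrasts, collecting everything into a single report object whose print
#' method mirrors the conventional reporting precision (probabilities and
#' `G^2` to two decimals, p values to three). The standard contrast presets
#' are:
#'
#' * `"size_dP"`, `"size_g"` — equate `dP` (or `g`) across lineup sizes
#'   within each format;
#' * `"format_dP"`, `"format_g"` — equate `dP` (or `g`) across formats
#'   within each lineup size.
#'
#' @param data Counts tibble, one row per condition.
#' @param model Base [lineup_model()].
#' @param contrasts Character vector of preset names (possibly empty).
#' @param n_starts,seed Multi-start policy applied to every fit.
#' @return An object of class `lineup_report`: list with `base_fit` and a
#'   named list `contrasts` of `lineup_lrt` objects. `tidy()` returns the
#'   contrast table.
#' @examples
#' fx <- lineup_study(1)
#' run_lineup_analysis(fx$counts, fx$model, contrasts = c("size_dP", "size_g"))
#' @export
run_lineup_analysis <- function(data, model, contrasts = character(),
                                n_starts = 10, seed = 1) {
  presets <- c("size_dP", "size_g", "format_dP", "format_g")
  unknown <- setdiff(contrasts, presets)
  if (length(unknown)) {
    abort(paste0("unknown contrast preset(s): ", paste(unknown, collapse = ", "),
                 "; available: ", paste(presets, collapse = ", ")))
  }
  base_fit <- fit_lineup_model(data, model, n_starts = n_starts, seed = seed)
  tests <- purrr::map(setNames(contrasts, contrasts), function(ct) {
    parts <- strsplit(ct, "_", fixed = TRUE)[[1]]
    restricted <- equate_across(model, parameter = parts[[2]],
                                across = parts[[1]])
    compare_lineup_models(data, model, restricted,
                          label = paste0(parts[[2]], " equated across ",
                                         parts[[1]], "s"),
                          n_starts = n_starts, seed = seed)
  })
  structure(list(base_fit = base_fit, contrasts = tests),
            class = "lineup_report")
}

#' @export
print.lineup_report <- function(x, ...) {
  cat("== Base model ==\n")
  print(x$base_fit)
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat("\n== Contrast ", nm, " (", ct$label, ") ==\n", sep = "")
    cat(sprintf("deltaG^2(%d) = %.2f, p = %.3f\n",
                ct$delta_df, ct$delta_g_squared, ct$p_value))
  }
  invisible(x)
}

#' @export
tidy.lineup_report <- function(x, ...) {
  purrr::map_dfr(x$contrasts, tidy, .id = "contrast")
}

#' Replicate the packaged study's published analysis
#'
#' Runs the full analysis of one experiment of the packaged lineup-size
#' study: the base-model fit plus the four standard contrasts (`size_dP`,
#' `size_g`, `format_dP`, `format_g`) on the packaged counts.
#'
#' @param experiment 1 or 2.
#' @param seed Seed for the multi-start optimizer.
#' @return A `lineup_report`.
#' @examples
#' \donttest{
#' replicate_study(1)
#' }
#' @export
replicate_study <- function(experiment = 1, seed = 1) {
  fx <- lineup_study(experiment)
  run_lineup_analysis(fx$counts, fx$model,
                      contrasts = c("size_dP", "size_g",
                                    "format_dP", "format_g"),
                      seed = seed)
}
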