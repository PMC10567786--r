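#' Read and write lineup count tables
#'
#' Counts files are comma-delimited text with the fixed header
#' `label,cp_suspect,cp_filler,cp_reject,ca_suspect,ca_filler,ca_reject`
#' and one row per condition. The packaged study tables ship in this format
#' under `system.file("extdata", package = "lineupmpt")`.
#'
#' @param path File path.
#' @return `read_lineup_counts()` returns a counts tibble;
#'   `write_lineup_counts()` returns `data` invisibly.
#' @examples
#' path <- system.file("extdata", "exp1_counts.csv", package = "lineupmpt")
#' read_lineup_counts(path)
#' @export
read_lineup_counts <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), .default = readr::col_integer()
  ))
  missing <- setdiff(c("label", category_cols), names(out))
  if (length(missing)) {
    abort(paste0("counts file '", path, "' lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out[, c("label", category_cols)]
}

#' @rdname read_lineup_counts
#' @param data Counts tibble with columns `label` and the six categories.
#' @export
write_lineup_counts <- function(data, path) {
  missing <- setdiff(c("label", category_cols), names(data))
  if (length(missing)) {
    abort(paste0("counts data lacks column(s): ", paste(missing, collapse = ", ")))
  }
  readr::write_csv(data[, c("label", category_cols)], path)
  invisible(data)
}

#' Read and write lineup model specification files
#'
#' Model files are YAML documents with two blocks: `conditions`, a list of
#' condition records (`label`, `lineup_format`, `lineup_size`,
#' `sampling_constant`, `n_participants`), and `parameters`, mapping each of
#' `dP`, `dA`, `b`, `g` either to `groups:` (a list of per-condition group
#' labels; equal labels share one free parameter) or to `fixed:` (a list of
#' per-condition constants). The representation round-trips losslessly.
#'
#' @param path File path.
#' @return `read_lineup_model()` returns a [lineup_model()];
#'   `write_lineup_model()` returns `model` invisibly.
#' @examples
#' path <- system.file("extdata", "exp1_base_model.yaml", package = "lineupmpt")
#' read_lineup_model(path)
#' @export
read_lineup_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!all(c("conditions", "parameters") %in% names(doc))) {
    abort(paste0("model file '", path,
                 "' must contain 'conditions' and 'parameters' blocks"))
  }
  cond <- purrr::map_dfr(doc$conditions, tibble::as_tibble)
  conditions <- lineup_conditions(
    label = cond$label, lineup_format = cond$lineup_format,
    lineup_size = cond$lineup_size,
    sampling_constant = cond$sampling_constant,
    n_participants = cond$n_participants
  )
  restr <- purrr::imap(doc$parameters[param_names], function(x, nm) {
    if (is.null(x)) abort(paste0("model file lacks parameter block '", nm, "'"))
    if (!is.null(x$groups)) as.character(unlist(x$groups))
    else if (!is.null(x$fixed)) as.double(unlist(x$fixed))
    else abort(paste0("parameter '", nm, "' needs 'groups' or 'fixed'"))
  })
  lineup_model(conditions, dP = restr$dP, dA = restr$dA,
               b = restr$b, g = restr$g)
}

#' @rdname read_lineup_model
#' @param model A [lineup_model()].
#' @export
write_lineup_model <- function(model, path) {
  cond <- purrr::transpose(as.list(model$conditions))
  pars <- purrr::map(model$spec, function(s) {
    if (s$kind == "free") list(groups = as.list(s$groups))
    else list(fixed = as.list(s$values))
  })
  yaml::write_yaml(list(conditions = cond, parameters = pars), path,
                   precision = 12)
  invisible(model)
}
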