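#' Specify a multi-condition 2-HT lineup model with parameter restrictions
#'
#' Builds a model specification from a table of lineup conditions and a
#' restriction for each of the four process parameters (`dP`, `dA`, `b`,
#' `g`). A restriction says which conditions share a free parameter, or
#' fixes the parameter to a constant:
#'
#' * `"by_condition"` — one free parameter per condition.
#' * `"shared"` — a single free parameter common to all conditions.
#' * a character vector of group labels (one per condition) — conditions
#'   with the same label share one free parameter.
#' * a numeric scalar or vector in `[0, 1]` — the parameter is fixed to the
#'   given value(s) and not estimated.
#'
#' Free parameters are named `"<parameter>"` when shared by all conditions
#' and `"<parameter>[<group>]"` otherwise, in the order `dP`, `dA`, `b`, `g`
#' with groups in order of first appearance.
#'
#' @param conditions A tibble from [lineup_conditions()].
#' @param dP,dA,b,g Restriction for each process parameter (see Details).
#'
#' @return An object of class `lineup_model`.
#' @examples
#' conds <- lineup_conditions(
#'   label = c("seq3", "seq6", "sim3", "sim6"),
#'   lineup_format = c("sequential", "sequential", "simultaneous", "simultaneous"),
#'   lineup_size = c(3, 6, 3, 6),
#'   sampling_constant = c(0.33333, 0.16667, 0.33333, 0.16667),
#'   n_participants = c(382, 393, 380, 382)
#' )
#' # condition-specific detection and guessing, shared bias and absence detection
#' lineup_model(conds)
#' @export
lineup_model <- function(conditions, dP = "by_condition", dA = "shared",
                         b = "shared", g = "by_condition") {
  if (!is.data.frame(conditions) ||
      !all(c("label", "lineup_format", "lineup_size", "sampling_constant",
             "n_participants") %in% names(conditions))) {
    abort("'conditions' must be a tibble from lineup_conditions()")
  }
  conditions <- tibble::as_tibble(conditions)
  n <- nrow(conditions)
  spec <- list(dP = dP, dA = dA, b = b, g = g)
  spec <- purrr::imap(spec, function(x, nm) normalize_restriction(x, nm, conditions))
  new_lineup_model(conditions, spec)
}

# spec: named list (dP, dA, b, g), each either
#   list(kind = "free", groups = <chr n>) or list(kind = "fixed", values = <dbl n>)
new_lineup_model <- function(conditions, spec) {
  free_names <- character(0)
  n <- nrow(conditions)
  index <- matrix(0L, n, 4, dimnames = list(conditions$label, param_names))
  fixed <- matrix(NA_real_, n, 4, dimnames = list(conditions$label, param_names))
  for (p in param_names) {
    s <- spec[[p]]
    if (s$kind == "fixed") {
      fixed[, p] <- s$values
    } else {
      groups <- unique(s$groups)
      nm_unique <- if (length(groups) == 1L) p else paste0(p, "[", groups, "]")
      index[, p] <- length(free_names) + match(s$groups, groups)
      free_names <- c(free_names, nm_unique)
    }
  }
  structure(
    list(conditions = conditions, spec = spec, free_names = free_names,
         index = index, fixed = fixed),
    class = "lineup_model"
  )
}

normalize_restriction <- function(x, nm, conditions) {
  n <- nrow(conditions)
  if (is.character(x) && length(x) == 1L && x == "by_condition") {
    list(kind = "free", groups = conditions$label)
  } else if (is.character(x) && length(x) == 1L && x == "shared") {
    list(kind = "free", groups = rep("all", n))
  } else if (is.character(x)) {
    if (length(x) != n) {
      abort(paste0("restriction for '", nm, "' must have one group label per ",
                   "condition (", n, "), got ", length(x)))
    }
    if (anyNA(x)) abort(paste0("restriction for '", nm, "' contains NA"))
    list(kind = "free", groups = x)
  } else if (is.numeric(x)) {
    v <- rep_len(as.double(x), n)
    if (anyNA(v) || any(v < 0) || any(v > 1)) {
      abort(paste0("fixed values for '", nm, "' must lie in [0, 1]"))
    }
    list(kind = "fixed", values = v)
  } else {
    abort(paste0("invalid restriction for '", nm, "'"))
  }
}

#' @export
print.lineup_model <- function(x, ...) {
  cat("<lineup_model> ", nrow(x$conditions), " conditions, ",
      n_free(x), " free parameters, ", degrees_of_freedom(x), " df\n", sep = "")
  print(x$conditions)
  cat("free parameters:", paste(x$free_names, collapse = ", "), "\n")
  fixed_ps <- names(which(purrr::map_chr(x$spec, "kind") == "fixed"))
  if (length(fixed_ps)) {
    cat("fixed:", paste0(fixed_ps, " = ",
        purrr::map_chr(x$spec[fixed_ps], ~ paste(unique(.x$values), collapse = "/")),
        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of free parameters of a lineup model
#' @param model A `lineup_model`.
#' @return Integer count of free parameters.
#' @export
n_free <- function(model) length(model$free_names)

#' Goodness-of-fit degrees of freedom of a lineup model
#'
#' Each condition contributes two multinomial trees with two free category
#' degrees of freedom apiece, so the model's goodness-of-fit df is
#' `4 * n_conditions - n_free(model)`.
#'
#' @param model A `lineup_model`.
#' @return Non-negative integer df.
#' @export
degrees_of_freedom <- function(model) {
  df <- 4L * nrow(model$conditions) - n_free(model)
  if (df < 0L) {
    abort(paste0("model has ", n_free(model), " free parameters but the data ",
                 "supply only ", 4L * nrow(model$conditions), " degrees of ",
                 "freedom; the model is over-parameterized and not testable"))
  }
  df
}

#' Expand free parameter values to per-condition process parameters
#'
#' Applies the model's restriction map: restricted parameters receive the
#' shared free value, fixed parameters their declared constants.
#'
#' @param model A `lineup_model`.
#' @param free_values Numeric vector of free parameter values in `[0, 1]`,
#'   in the order of `model$free_names` (names, if present, are checked).
#'
#' @return A tibble with columns `label`, `dP`, `dA`, `b`, `g`, one row per
#'   condition.
#' @export
expand_parameters <- function(model, free_values) {
  k <- n_free(model)
  if (length(free_values) != k) {
    abort(paste0("expected ", k, " free values, got ", length(free_values)))
  }
  if (!is.null(names(free_values)) &&
      !identical(names(free_values), model$free_names)) {
    free_values <- free_values[model$free_names]
    if (anyNA(free_values)) abort("free value names do not match model$free_names")
  }
  if (any(free_values < 0 | free_values > 1)) {
    abort("free values must lie in [0, 1]")
  }
  P <- expand_matrix(model, as.double(free_values))
  tibble::tibble(label = model$conditions$label,
                 dP = unname(P[, "dP"]), dA = unname(P[, "dA"]),
                 b = unname(P[, "b"]), g = unname(P[, "g"]))
}

# fast path used by the likelihood: n_conditions x 4 matrix
expand_matrix <- function(model, free_values) {
  P <- model$fixed
  idx <- model$index
  P[idx > 0L] <- free_values[idx[idx > 0L]]
  P
}

#' Collapse per-condition parameters back to free values
#'
#' Inverse of [expand_parameters()]: reads one value per free parameter off
#' a per-condition parameter table, checking that conditions sharing a free
#' parameter carry identical values and that fixed slots match their
#' declared constants.
#'
#' @param model A `lineup_model`.
#' @param params A data frame with columns `label`, `dP`, `dA`, `b`, `g`.
#' @param tol Tolerance for equality within a restriction class.
#' @return Named numeric vector of free values in `model$free_names` order.
#' @export
collapse_parameters <- function(model, params, tol = 1e-10) {
  params <- params[match(model$conditions$label, params$label), ]
  if (anyNA(params$label)) abort("'params' must cover every condition label")
  out <- setNames(numeric(n_free(model)), model$free_names)
  for (p in param_names) {
    idx <- model$index[, p]
    vals <- params[[p]]
    if (all(idx == 0L)) {
      if (any(abs(vals - model$fixed[, p]) > tol)) {
        abort(paste0("'", p, "' differs from its fixed values"))
      }
      next
    }
    for (j in unique(idx)) {
      v <- vals[idx == j]
      if (diff(range(v)) > tol) {
        abort(paste0("conditions sharing free parameter '",
                     model$free_names[[j]], "' carry unequal values"))
      }
      out[[j]] <- v[[1]]
    }
  }
  out
}

#' Equate a process parameter across lineup sizes or formats
#'
#' Builds the restricted model for the standard nested-model contrasts: the
#' lineup-size contrast equates the parameter across sizes *within each
#' format* (groups defined by `lineup_format`); the format contrast equates
#' it across formats *within each size* (groups defined by `lineup_size`).
#' With four conditions in a 2x2 design either contrast removes two free
#' parameters.
#'
#' @param model A base `lineup_model` in which the parameter is free per
#'   condition.
#' @param parameter One of `"dP"`, `"dA"`, `"b"`, `"g"`.
#' @param across `"size"` or `"format"`: the factor across which the
#'   parameter is equated.
#' @return The restricted `lineup_model`.
#' @examples
#' fx <- lineup_study(1)
#' restricted <- equate_across(fx$model, "dP", "size")
#' n_free(fx$model) - n_free(restricted)
#' @export
equate_across <- function(model, parameter = c("dP", "dA", "b", "g"),
                          across = c("size", "format")) {
  parameter <- match.arg(parameter)
  across <- match.arg(across)
  if (model$spec[[parameter]]$kind != "free") {
    abort(paste0("'", parameter, "' is fixed in the base model"))
  }
  groups <- switch(across,
    size = model$conditions$lineup_format,
    format = paste0("size", model$conditions$lineup_size)
  )
  spec <- model$spec
  spec[[parameter]] <- list(kind = "free", groups = groups)
  new_lineup_model(model$conditions, spec)
}

#' Test whether one lineup model is nested in another
#'
#' The restricted model must be a coarsening of the base model: any two
#' condition slots sharing a free parameter in the base model must share one
#' in the restricted model, and a slot fixed in the base model must be fixed
#' to the same value in the restricted model. Conditions (labels, sampling
#' constants) must agree.
#'
#' @param base,restricted `lineup_model` objects.
#' @return `TRUE` or `FALSE`; on `FALSE`, attribute `"violations"` lists the
#'   offending parameter blocks.
#' @export
is_nested <- function(base, restricted) {
  if (!identical(base$conditions$label, restricted$conditions$label) ||
      !isTRUE(all.equal(base$conditions$sampling_constant,
                        restricted$conditions$sampling_constant))) {
    out <- FALSE
    attr(out, "violations") <- "conditions differ between the two models"
    return(out)
  }
  viol <- character(0)
  for (p in param_names) {
    sb <- base$spec[[p]]; sr <- restricted$spec[[p]]
    if (sb$kind == "fixed") {
      if (sr$kind != "fixed" || any(abs(sr$values - sb$values) > 1e-12)) {
        viol <- c(viol, paste0("'", p, "' is fixed in the base model but not ",
                               "identically fixed in the restricted model"))
      }
      next
    }
    if (sr$kind == "fixed") next  # fixing a free parameter is a restriction
    # every base equivalence class must fall inside one restricted class
    split_r <- split(sr$groups, sb$groups)
    bad <- names(split_r)[purrr::map_int(split_r, dplyr::n_distinct) > 1L]
    if (length(bad)) {
      viol <- c(viol, paste0("'", p, "' group '", bad, "' of the base model ",
                             "is split across restricted-model groups"))
    }
  }
  out <- length(viol) == 0L
  attr(out, "violations") <- viol
  out
}

#' Local identifiability check via the Fisher-information rank
#'
#' Computes the rank of the Jacobian of the stacked category probabilities
#' with respect to the free parameters at a given point (by central finite
#' differences). A rank below the number of free parameters signals a
#' locally non-identifiable parameterization, for example a saturated
#' single-condition model.
#'
#' @param model A `lineup_model`.
#' @param free_values Point at which to evaluate; defaults to all 0.5.
#' @return A list with `rank`, `n_free` and logical `identifiable`.
#' @export
check_identifiability <- function(model, free_values = NULL) {
  k <- n_free(model)
  theta <- free_values %||% rep(0.5, k)
  probs_at <- function(th) {
    P <- expand_matrix(model, th)
    prob_matrix(P[, "dP"], P[, "dA"], P[, "b"], P[, "g"],
                model$conditions$sampling_constant)
  }
  h <- 1e-6
  J <- matrix(0, nrow = 6L * nrow(model$conditions), ncol = k)
  for (j in seq_len(k)) {
    up <- theta; up[j] <- min(theta[j] + h, 1)
    dn <- theta; dn[j] <- max(theta[j] - h, 0)
    J[, j] <- (as.vector(probs_at(up)) - as.vector(probs_at(dn))) / (up[j] - dn[j])
  }
  r <- if (k == 0L) 0L else qr(J)$rank
  list(rank = r, n_free = k, identifiable = r == k)
}
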