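#' Packaged lineup-size study: conditions, counts and base models
#'
#' Response frequencies from a published two-experiment study of lineup-size
#' effects on eyewitness decisions, in which each participant saw four
#' lineups (two culprit-present, two culprit-absent). Experiment 1 crossed
#' lineup format (sequential, simultaneous) with lineup size (three vs six
#' persons); Experiment 2 used two- vs five-person lineups. The study's
#' analysis used rounded sampling constants in Experiment 1 (0.33333 and
#' 0.16667) and exact ones in Experiment 2 (0.5 and 0.2); those constants
#' are reproduced verbatim here so fits replicate the published numbers
#' exactly.
#'
#' The base model for both experiments estimates condition-specific
#' culprit-presence detection `dP` and guessing `g`, with biased suspect
#' selection `b` and culprit-absence detection `dA` each equated across the
#' four conditions (10 free parameters, 6 df).
#'
#' The same counts ship as delimited text under
#' `system.file("extdata", package = "lineupmpt")`.
#'
#' @param experiment 1 or 2.
#' @return A list with elements `conditions` (tibble), `counts` (tibble) and
#'   `model` (the base [lineup_model()]).
#' @examples
#' fx <- lineup_study(1)
#' fx$counts
#' @export
lineup_study <- function(experiment = 1) {
  if (!experiment %in% c(1, 2)) {
    abort("'experiment' must be 1 or 2")
  }
  if (experiment == 1) {
    conditions <- lineup_conditions(
      label = c("seq3", "seq6", "sim3", "sim6"),
      lineup_format = c("sequential", "sequential",
                        "simultaneous", "simultaneous"),
      lineup_size = c(3L, 6L, 3L, 6L),
      sampling_constant = c(0.33333, 0.16667, 0.33333, 0.16667),
      n_participants = c(382L, 393L, 380L, 382L)
    )
    counts <- tibble::tribble(
      ~label, ~cp_suspect, ~cp_filler, ~cp_reject,
              ~ca_suspect, ~ca_filler, ~ca_reject,
      "seq3", 386L, 205L, 173L, 206L, 241L, 317L,
      "seq6", 273L, 339L, 174L, 127L, 374L, 285L,
      "sim3", 371L, 120L, 269L, 139L, 184L, 437L,
      "sim6", 283L, 191L, 290L,  87L, 249L, 428L
    )
  } else {
    conditions <- lineup_conditions(
      label = c("seq2", "seq5", "sim2", "sim5"),
      lineup_format = c("sequential", "sequential",
                        "simultaneous", "simultaneous"),
      lineup_size = c(2L, 5L, 2L, 5L),
      sampling_constant = c(0.5, 0.2, 0.5, 0.2),
      n_participants = c(408L, 401L, 393L, 394L)
    )
    counts <- tibble::tribble(
      ~label, ~cp_suspect, ~cp_filler, ~cp_reject,
              ~ca_suspect, ~ca_filler, ~ca_reject,
      "seq2", 499L, 124L, 193L, 259L, 161L, 396L,
      "seq5", 320L, 316L, 166L, 143L, 378L, 281L,
      "sim2", 433L,  72L, 281L, 204L,  98L, 484L,
      "sim5", 320L, 172L, 296L, 115L, 232L, 441L
    )
  }
  list(
    conditions = conditions,
    counts = counts,
    model = lineup_model(conditions)
  )
}
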