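#' Define the lineup conditions of an experimental design
#'
#' A lineup condition is one cell of a lineup experiment: a presentation
#' format (sequential or simultaneous), a lineup size, the random-sampling
#' constant (the probability that a guessing-based selection lands on the
#' suspect, `1 / lineup_size`), and the number of participants assigned to
#' the cell.
#'
#' The sampling constant is stored explicitly rather than derived from the
#' size, so that rounded constants used in a published analysis (for example
#' 0.33333 for a three-person lineup) can be reproduced verbatim. When
#' `sampling_constant` is omitted it defaults to the exact `1 / lineup_size`.
#' A stored constant must agree with `1 / lineup_size` to within 5e-5.
#'
#' @param label Character vector of unique condition identifiers.
#' @param lineup_format `"sequential"` or `"simultaneous"`, recycled to the
#'   number of conditions.
#' @param lineup_size Integer number of persons shown (suspect plus fillers),
#'   at least 2.
#' @param sampling_constant Probability in (0, 1] used as the random-sampling
#'   constant; defaults to `1 / lineup_size`.
#' @param n_participants Non-negative integer count of participants per
#'   condition.
#'
#' @return A tibble with one row per condition and columns `label`,
#'   `lineup_format`, `lineup_size`, `sampling_constant`, `n_participants`.
#' @examples
#' lineup_conditions(
#'   label = c("seq3", "seq6"),
#'   lineup_format = "sequential",
#'   lineup_size = c(3, 6),
#'   sampling_constant = c(0.33333, 0.16667),
#'   n_participants = c(382, 393)
#' )
#' @export
lineup_conditions <- function(label, lineup_format, lineup_size,
                              sampling_constant = 1 / lineup_size,
                              n_participants) {
  n <- length(label)
  if (anyDuplicated(label)) {
    abort("condition labels must be unique")
  }
  out <- tibble::tibble(
    label = as.character(label),
    lineup_format = rep_len(as.character(lineup_format), n),
    lineup_size = rep_len(as.integer(lineup_size), n),
    sampling_constant = rep_len(as.double(sampling_constant), n),
    n_participants = rep_len(as.integer(n_participants), n)
  )
  bad_fmt <- setdiff(out$lineup_format, c("sequential", "simultaneous"))
  if (length(bad_fmt)) {
    abort(paste0("lineup_format must be 'sequential' or 'simultaneous', got '",
                 bad_fmt[[1]], "'"))
  }
  if (any(out$lineup_size < 2L)) {
    abort("lineup_size must be at least 2")
  }
  if (any(out$sampling_constant <= 0 | out$sampling_constant > 1)) {
    abort("sampling_constant must lie in (0, 1]")
  }
  off <- abs(out$sampling_constant - 1 / out$lineup_size)
  if (any(off > 5e-5)) {
    abort(paste0("sampling_constant must equal 1 / lineup_size within 5e-5; ",
                 "condition '", out$label[which.max(off)], "' is off by ",
                 signif(max(off), 3)))
  }
  if (any(out$n_participants < 0L)) {
    abort("n_participants must be non-negative")
  }
  out
}

#' Category probabilities of the 2-HT eyewitness identification model
#'
#' Computes the six observable response-category probabilities of the
#' two-high-threshold eyewitness identification tree for given process
#' parameters. In a culprit-present lineup the culprit is detected with
#' probability `dP`; failing that, biased suspect selection occurs with
#' probability `b`, and otherwise a guessing-based selection is made with
#' probability `g`, landing on the suspect with the random-sampling constant
#' `c` and on a filler with `1 - c`. In a culprit-absent lineup, culprit
#' absence is detected with probability `dA` (a correct rejection) and the
#' same non-detection processes operate otherwise:
#'
#' \deqn{P(\text{suspect} \mid \text{CP}) = dP + (1-dP)\,b + (1-dP)(1-b)\,g\,c}
#' \deqn{P(\text{filler} \mid \text{CP}) = (1-dP)(1-b)\,g\,(1-c)}
#' \deqn{P(\text{reject} \mid \text{CP}) = (1-dP)(1-b)(1-g)}
#' \deqn{P(\text{suspect} \mid \text{CA}) = (1-dA)\,b + (1-dA)(1-b)\,g\,c}
#' \deqn{P(\text{filler} \mid \text{CA}) = (1-dA)(1-b)\,g\,(1-c)}
#' \deqn{P(\text{reject} \mid \text{CA}) = dA + (1-dA)(1-b)(1-g)}
#'
#' All arguments are vectorized and recycled to a common length. Each triple
#' sums to one.
#'
#' @param dP Probability of detecting the presence of the culprit.
#' @param dA Probability of detecting the absence of the culprit.
#' @param b Probability of biased suspect selection.
#' @param g Probability of guessing-based selection among the lineup members.
#' @param sampling_constant Random-sampling constant, `1 / lineup_size`.
#'
#' @return A tibble with columns `cp_suspect`, `cp_filler`, `cp_reject`,
#'   `ca_suspect`, `ca_filler`, `ca_reject`.
#' @examples
#' category_probs(dP = 0.4, dA = 0.11, b = 0.07, g = 0.5,
#'                sampling_constant = 1 / 6)
#' @export
category_probs <- function(dP, dA, b, g, sampling_constant) {
  args <- list(dP = dP, dA = dA, b = b, g = g,
               sampling_constant = sampling_constant)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      abort(paste0("'", nm, "' must be a probability in [0, 1]"))
    }
  }
  n <- max(lengths(args))
  m <- prob_matrix(rep_len(dP, n), rep_len(dA, n), rep_len(b, n),
                   rep_len(g, n), rep_len(sampling_constant, n))
  tibble::as_tibble(as.data.frame(m))
}

# bare-matrix hot path shared by the likelihood; no validation, no tibble
prob_matrix <- function(dP, dA, b, g, cc) {
  sel <- b + (1 - b) * g * cc           # suspect selection absent detection
  m <- cbind(
    dP + (1 - dP) * sel,
    (1 - dP) * (1 - b) * g * (1 - cc),
    (1 - dP) * (1 - b) * (1 - g),
    (1 - dA) * sel,
    (1 - dA) * (1 - b) * g * (1 - cc),
    dA + (1 - dA) * (1 - b) * (1 - g)
  )
  colnames(m) <- category_cols
  m
}

category_cols <- c("cp_suspect", "cp_filler", "cp_reject",
                   "ca_suspect", "ca_filler", "ca_reject")
param_names <- c("dP", "dA", "b", "g")
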