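# Independent oracles used across the suite. Kept deliberately naive:
# they enumerate or simulate rather than reusing package code paths.

# Path-enumeration oracle for the 2-HT identification tree: walk every
# branch of each tree, multiply link probabilities along the branch and sum
# branch products per terminal category.
enum_tree_probs <- function(dP, dA, b, g, cc) {
  cp_branches <- list(
    list(p = dP, cat = "suspect"),
    list(p = (1 - dP) * b, cat = "suspect"),
    list(p = (1 - dP) * (1 - b) * g * cc, cat = "suspect"),
    list(p = (1 - dP) * (1 - b) * g * (1 - cc), cat = "filler"),
    list(p = (1 - dP) * (1 - b) * (1 - g), cat = "reject")
  )
  ca_branches <- list(
    list(p = dA, cat = "reject"),
    list(p = (1 - dA) * b, cat = "suspect"),
    list(p = (1 - dA) * (1 - b) * g * cc, cat = "suspect"),
    list(p = (1 - dA) * (1 - b) * g * (1 - cc), cat = "filler"),
    list(p = (1 - dA) * (1 - b) * (1 - g), cat = "reject")
  )
  sum_cat <- function(branches, cat) {
    sum(vapply(branches, function(br) if (br$cat == cat) br$p else 0, 1.0))
  }
  c(
    cp_suspect = sum_cat(cp_branches, "suspect"),
    cp_filler = sum_cat(cp_branches, "filler"),
    cp_reject = sum_cat(cp_branches, "reject"),
    ca_suspect = sum_cat(ca_branches, "suspect"),
    ca_filler = sum_cat(ca_branches, "filler"),
    ca_reject = sum_cat(ca_branches, "reject")
  )
}

# one-condition design used by several estimation tests
one_condition_model <- function(dP = "by_condition", dA = "by_condition",
                                b = "by_condition", g = "by_condition",
                                lineup_size = 3, n = 400) {
  conds <- lineup_conditions(
    label = "c1", lineup_format = "sequential", lineup_size = lineup_size,
    n_participants = n
  )
  lineup_model(conds, dP = dP, dA = dA, b = b, g = g)
}

make_counts <- function(label, cp, ca) {
  tibble::tibble(
    label = label,
    cp_suspect = cp[1], cp_filler = cp[2], cp_reject = cp[3],
    ca_suspect = ca[1], ca_filler = ca[2], ca_reject = ca[3]
  )
}
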