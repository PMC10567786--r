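---
title: "Measuring the processes behind eyewitness lineup decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the processes behind eyewitness lineup decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineupmpt)
library(dplyr)
```

## The measurement problem

A police lineup presents an eyewitness with one suspect among known-innocent
fillers. Three responses are observable: identify the suspect, identify a
filler, or reject the lineup — in both culprit-present (CP) and
culprit-absent (CA) lineups, so an experimental condition yields six response
counts. Raw identification rates confound qualitatively different cognitive
processes: a suspect identification can reflect genuine recognition, a biased
pick of someone who stands out, or a lucky guess. `lineupmpt` implements a
multinomial processing tree (MPT) measurement model — the two-high-threshold
(2-HT) eyewitness identification model — that separates these processes and
supports hypothesis tests directly on them.

## The model

Four latent probabilities drive the trees:

* `dP` — detection of the culprit's presence (CP lineups only),
* `dA` — detection of the culprit's absence (CA lineups only),
* `b`  — biased selection of the suspect (the suspect "stands out"),
* `g`  — guessing-based selection among the lineup members.

A guessing-based selection lands on the suspect with the *random-sampling
constant* `c = 1 / lineup size` and on some filler with `1 - c`. The constant
is not estimated; it is a design quantity. The category probabilities are

$$
\begin{aligned}
P(\text{suspect} \mid \text{CP}) &= d_P + (1-d_P)\,b + (1-d_P)(1-b)\,g\,c \\
P(\text{filler} \mid \text{CP})  &= (1-d_P)(1-b)\,g\,(1-c) \\
P(\text{reject} \mid \text{CP})  &= (1-d_P)(1-b)(1-g) \\
P(\text{suspect} \mid \text{CA}) &= (1-d_A)\,b + (1-d_A)(1-b)\,g\,c \\
P(\text{filler} \mid \text{CA})  &= (1-d_A)(1-b)\,g\,(1-c) \\
P(\text{reject} \mid \text{CA})  &= d_A + (1-d_A)(1-b)(1-g).
\end{aligned}
$$

`category_probs()` evaluates these; the test suite checks them against an
independent path-enumeration oracle that walks every branch of the tree.

The sampling constant is *stored*, not derived. Published analyses sometimes
use rounded constants (0.33333 for a three-person lineup rather than exactly
1/3), and replicating such an analysis bit-faithfully requires carrying the
rounded value. `lineup_conditions()` therefore accepts an explicit
`sampling_constant` (defaulting to the exact `1/lineup_size`) and tolerates a
deviation of at most 5e-5 from it.

## Restrictions, estimation, inference

A `lineup_model()` couples a condition table with one restriction per
parameter: condition-specific (`"by_condition"`), shared across all
conditions (`"shared"`), shared within named groups (a character vector), or
fixed to constants (a numeric vector — e.g. `b = 0` encodes a perfectly fair
lineup). Identical group labels share one free parameter; this is how the
standard contrasts are built. The packaged study's base model frees `dP` and
`g` per condition and shares `b` and `dA` across the four conditions of each
experiment: 10 free parameters against 16 data degrees of freedom (4 per
condition), leaving 6 for the goodness-of-fit test.

`fit_lineup_model()` maximizes the joint multinomial likelihood with
box-constrained quasi-Newton search (`optim`, `L-BFGS-B`) directly on the
probability scale, bounds `[1e-8, 1 - 1e-8]`. Probability-scale optimization
with box bounds was chosen over a logit reparameterization because the
likelihood here is smooth on the closed cube and boundary solutions are
meaningful (they are flagged rather than pushed to infinity on the logit
scale). Ten starts are used by default — one at 0.5 everywhere plus nine
uniform-random draws governed by `seed` — and the number of starts agreeing
with the best solution (within 1e-6 in log-likelihood) is reported; on the
packaged data all twenty starts of a doubled run agree. The search uses the
analytic gradient of the multinomial log-likelihood and a tight convergence
tolerance (`factr = 100`), so parameter estimates are reproducible to well
below 1e-6.

Goodness of fit is the likelihood-ratio statistic
$G^2 = 2\sum O \log(O/E)$ over all cells with observed count $O > 0$,
referred to chi-square on the model's df. Cells with $O = 0$ contribute
nothing; a fitted expected count of zero against a positive observation makes
$G^2$ infinite with a diagnostic. Standard errors come from the observed
information matrix (numerical Hessian of the negative log-likelihood at the
MLE) — observed rather than expected information, the common default for MPT
software; estimates at the boundary get `NA` standard errors and a flag, and
a singular information matrix is reported with its rank.
`check_identifiability()` exposes a local Fisher-information rank check,
because a saturated or degenerate restriction map (say, `g` fixed to 0 with
`dP` and `b` both free) can be rank-deficient even when its df are
non-negative.

Nested hypotheses are tested by `compare_lineup_models()` via
$\Delta G^2$, the difference in $G^2$ between the restricted and the base
model, on df equal to the number of free parameters removed. `is_nested()`
verifies that the restriction map of the smaller model coarsens that of the
larger one. The shipped presets mirror the standard 2x2 contrasts:
`size_dP`/`size_g` equate a parameter across lineup sizes *within each
format*, `format_dP`/`format_g` across formats *within each size*; each
removes two free parameters in a four-condition design.

## The packaged study

`lineup_study()` returns the complete response-frequency tables of a
published two-experiment study of lineup-size effects (Experiment 1: three-
vs six-person lineups, constants 0.33333/0.16667, n = 382/393/380/382;
Experiment 2: two- vs five-person lineups, constants 0.5/0.2,
n = 408/401/393/394; both crossed with sequential vs simultaneous
presentation, four decisions per participant — two CP, two CA). Fitting the
base model reproduces the published results:

```{r exp1}
fx <- lineup_study(1)
fit <- fit_lineup_model(fx$counts, fx$model, seed = 1)
glance(fit)
tidy(fit)
```

```{r contrasts}
run_lineup_analysis(fx$counts, fx$model,
                    contrasts = c("size_dP", "size_g"), seed = 1) |>
  tidy()
```

Culprit-presence detection is higher and guessing lower in the smaller
lineups; the suspect-protection advantage of large lineups comes from the
shrinking sampling constant, not from less guessing.

```{r plot, fig.width = 6, fig.height = 4}
autoplot(fit, parameters = c("dP", "g"))
```

## Sensitivity and power

The `cohens_w()` / `chisq_power()` / `minimal_detectable_w()` trio performs
generic noncentral chi-square sensitivity calculations with noncentrality
$\lambda = N w^2$. `N` counts *decisions*, not participants: each participant
here contributes four lineup decisions, so the first experiment's design has
$N = 1537 \times 4$ observations and can detect effects as small as

```{r power}
minimal_detectable_w(1537 * 4, df = 2, alpha = 0.05, power = 0.95)
```

at 95% power and alpha = 0.05 on 2 df. This is deliberately the generic
omnibus calculation (as produced by standard power software for chi-square
tests), not a model-specific power analysis for particular $\Delta G^2$
contrasts; the root is found by bisection on $w \in [0, 3]$ to 1e-8.

## What the simulator emulates — and what it does not

`simulate_lineup_counts()` draws each condition's CP and CA counts
multinomially from the model's category probabilities with tree totals of
(by default) two CP and two CA decisions per participant, matching the
packaged study's design. Every condition uses its own deterministic
substream of the root seed, so adding conditions or replicates never
perturbs earlier draws. All of a participant's decisions are treated as
independent observations. This matches the independence assumption of the
analysis model itself, but it is an idealization: real participants share
ability and criterion across their four lineups, which would overdisperse
real counts relative to the simulator. Passing recovery and calibration
tests therefore validates the estimator *under the model's own assumptions*,
not the assumptions themselves; a participant-level dependence knob is
deliberately out of scope.

`parameter_recovery()` runs the simulate-fit loop and reports bias,
empirical SD, mean model-based SE and 95% Wald coverage per free parameter,
counting (never silently dropping) failed replicates.

## Numerical and design choices

* Study-scale problem sizes are used for the heavier validation runs: the
  null-calibration check simulates 2000 replicates of a reduced
  two-condition design (base 6 free parameters vs 5), and the recovery check
  500 replicates of the full four-condition design at 380 participants per
  condition with generating values taken from the fitted base model.
* Grid-search cross-checks of the optimizer use a full 0.001-step grid for
  two-parameter models and a coarse-plus-refined grid for three parameters.
* Reported tables round probabilities and $G^2$ to two decimals and p values
  to three — presentation only; all computation is at full precision.
* Ties between multi-start solutions are resolved by the first best value;
  agreement across starts is part of the fit object so silent multimodality
  cannot pass unnoticed.

## Limitations

The package covers the 2-HT lineup tree family only — it is not a general
MPT compiler. Confidence ratings, position-by-position sequential responses,
Bayesian or bootstrap uncertainty, and latent heterogeneity across
participants are out of scope. Asymptotic chi-square calibration is
excellent at the packaged study's sample sizes but should not be assumed for
very small designs or boundary estimates.
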