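---
title: "Modelling holistic episodic retrieval: dependency, reinstatement, and hippocampal coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling holistic episodic retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmem)
library(dplyr)
```

## The experimental assay

`loopmem` implements the statistical machinery of closed-/open-loop
cued-recognition experiments on episodic memory. Participants learn
three-element "events" (a location, a famous person, a common object)
as overlapping pairwise associations. Two associative structures are
contrasted:

* **closed loops** — all three pairs are encoded, so any element can reach
  any other;
* **open loops** — only two pairs are encoded, sharing one **common
  element**; the third pair is never shown and never tested.

Each event belongs to one of four within-subject cells: loop (closed/open)
crossed with delay (encoded ~24 h before retrieval, or immediately before).
Retrieval is a six-alternative forced choice (chance 1/6), testing every
encoded pair in both cue directions: six directed tests per closed loop and
four per open loop.

If retrieval is **holistic** — a cue reinstates the entire event via
hippocampal pattern completion — then the success of two retrievals from
the same event should be correlated. The package's core statistic,
**retrieval dependency**, quantifies exactly that excess correlation.

## The design generator

`generate_events()` + `build_encoding_schedule()` +
`build_retrieval_schedule()` reproduce the factorial design exactly:

* 72 events, 18 per loop × delay cell; open-loop common elements balanced
  6 per role per encoding session.
* 90 encoding trials per session in blocks of 18/36/36; block 1 holds only
  closed-loop pairs so that the lag between final encoding and retrieval is
  matched across loop types. Pair presentation follows one of three rotated
  orders per loop type, chosen so that the first two encoding trials of a
  closed loop are structurally identical to an open loop; the three orders
  are used equally often (6 events each per session and loop type).
* 360 retrieval trials (180 per run, 9 events of each cell per run), with
  18 six-second null trials interleaved per run and the constraint that no
  two successive trials test the same event.

Two scheduling choices are deliberately simple. The constrained ordering is
a uniform shuffle with rejection (bounded at 10,000 retries; in practice a
few dozen suffice for a 180-trial run). Stimulus-presentation software
sometimes optimises trial orderings for BOLD design efficiency instead; that
optimisation affects only measurement efficiency at the scanner, not any
statistic implemented here, so we draw uniformly from the constrained order
space. Null-trial positions are likewise drawn uniformly among the 198 slots
of a run *after* the non-null order satisfies the adjacency constraint, so
the constraint also holds across a null gap. Left/right screen placement at
encoding is randomised per trial, stored, and never used downstream.

All generators are deterministic given their seed, and timing columns
(`onset`, `duration`) follow the stated trial structure (0.5 s fixation,
6 s pair, 0.5 s blank, 10 s breaks every 18 encoding trials; 1 s fixation,
up to 6 s response, 1 s blank at retrieval).

## Retrieval dependency and the independent model

For one participant and condition, consider an event's elements A, B, C and
the directed tests $A_B$ (cue A, retrieve B) and $A_C$. Over the
condition's $N$ events a 2×2 contingency table counts events by the joint
outcome of the two tests. The **independent model** predicts those counts
from the participant's marginal accuracies $P_{AB}$, $P_{AC}$ (means over
the condition's events): $N P_{AB} P_{AC}$ both correct,
$N P_{AB}(1-P_{AC})$ first-only, and so on. The **proportion of joint
retrieval** of a table is its leading diagonal over $N$, and

$$\text{dependency} \;=\; \overline{p^{\text{joint}}_{\text{data}}} \;-\;
\overline{p^{\text{joint}}_{\text{independent}}},$$

averaged (unweighted) over the condition's tables. Closed loops contribute
six tables (for each choice of common element A: retrieval of B and C when
cued by A, and retrieval of A when cued by B and C). Open loops are only
tested in the four directions involving their common element; they
contribute four tables: common-cue ($A_B A_C$), common-target
($B_A C_A$), and the two mixed pairings ($A_B C_A$, $B_A A_C$). The mixed
pairings are the natural completion of the "four tables" count for open
loops; `enumerate_tables()` exposes the list so users who prefer only the
two canonical analyses can restrict to them.

Two implementation choices deserve note:

* **Role-relative pooling for open loops.** Within a condition the 18 open
  loops split 6/6/6 across the three possible common elements. The four
  open-loop tables are therefore defined *relative to each event's own
  common element* (A = common, B/C = the remaining roles in canonical
  location < person < object order) and pooled over all 18 events — this is
  what makes "four tables over N events" well defined. The common element
  never needs to be supplied: it is inferred from which directions were
  tested.
* **Subject-level marginals.** $P_{AB}$ is a subject's mean accuracy for a
  directed test across events, constant across events; with binary
  single-trial outcomes, per-event probabilities are inestimable, and the
  per-event sums of the independent model reduce to $N \times$ products of
  the marginals.

Useful closed forms, used as test oracles: if every test of an event shares
the event's all-or-none outcome with success probability $p$, the observed
joint proportion is exactly 1 and dependency is exactly $2p(1-p)$; under
independent retrieval the expected dependency is 0.

Missing responses (response window exceeded) are scored incorrect
throughout, for both accuracy and dependency; the readers and
`dependency_summary()` enforce `missing == 1 ⇒ correct == 0`.

## The behavioural outcome simulator

`simulate_subject()` / `simulate_cohort()` generate outcomes from the
minimal generative model that produces dependency: a latent **all-or-none
mixture**. Per event, a Bernoulli(ρ) draw decides whether the event is
holistically accessible; each of its tests then succeeds independently with
probability `p_hi` (accessible) or `p_lo` (not accessible), and a response
goes missing with probability `p_missing` (forcing incorrect). Marginal
accuracy per cell is `(1 − p_missing)(ρ·p_hi + (1 − ρ)·p_lo)`.

Default parameters per cell were chosen once to land the marginal
accuracies near the canonical profile for this design — closed/no-delay
≈ 0.68, open/no-delay ≈ 0.62, closed/delay ≈ 0.61, open/delay ≈ 0.50 —
with `p_lo` at or above the 1/6 guessing floor, `p_missing = 0.035`
(≈ 3.5% missing responses), and ρ decreasing with delay and smaller for
open loops:

```{r}
generative_params()$cells
expected_accuracy(generative_params())
```

Response times are drawn lognormal with a 2.86 s median purely for format
fidelity; they feed no statistic. An optional logit-scale subject jitter on
ρ (`rho_subject_sd`) mimics across-subject heterogeneity; it is off by
default.

What the simulator does *not* emulate: encoding-session learning dynamics,
sleep/consolidation mechanisms, strategic inference of the untested
open-loop pair, item- or category-level difficulty, and serial-position or
fatigue effects. Passing tests therefore certify the *statistical
machinery* (estimators, type-I behaviour, power trends) under a known
generative truth — not the cognitive claims one would test on real data.
The open-loop/no-delay cell's ρ is a free parameter precisely so users can
explore scenarios where that condition shows dependency.

## Behavioural inference layer

* `one_sample_t()` — two-tailed t with Cohen's
  *d* = mean difference / SD of the difference scores.
* `anova_2x2_within()` — the 2×2 within-subject ANOVA computed from
  orthogonal paired contrasts: each 1-df effect is the squared one-sample
  t of its contrast score, with $\eta_p^2 = F/(F + df_{den})$. For a 2×2
  repeated-measures design this *is* the classical decomposition (verified
  against `aov()` with an `Error()` term in the test suite), while being
  exactly testable. A zero-variance contrast is reported as F = 0, p = 1
  when its mean is zero and F = ∞, p = 0 otherwise (a perfectly determined
  effect), so noise-free constructed inputs behave sensibly.
* `bonferroni_alpha()` — α/m, with a half-up 3-decimal presentation value
  (0.05/4 → 0.013, 0.05/3 → 0.017); R's default banker's rounding would
  print 0.012.
* `power_one_sample_t()` / `sample_size_one_sample_t()` — exact noncentral-t
  power (ncp $d\sqrt{n}$, df $n-1$, both rejection tails included) and the
  minimal n reaching a target power by upward scan. At d = 0.62, α = 0.05,
  power 0.90 the minimal n is 30:

```{r}
sample_size_one_sample_t(d = 0.62, alpha = 0.05, power = 0.90)
```

The effect-size adjustment by which a pilot accuracy decrement discounts a
previously published *d* (0.67 → 0.62) has no closed form we could adopt,
so the package takes *d* itself as the input.

## ROI contrasts and the hippocampal-coupling model

`simulate_contrasts()` generates per-subject, per-condition
closed-minus-open contrasts with known linear coupling:
$\text{nontarget}_{ic} = \alpha_c + \beta_c \cdot \text{hipp}_{ic} + u_i +
\varepsilon_{ic}$, with a subject random intercept $u_i$ shared across the
two conditions. Defaults ($\alpha_{nd}=0$, $\alpha_d=0.15$,
$\beta_{nd}=0.8$, $\beta_d=0.45$, hipp ~ N(0.15, 0.2²), $s_u = s_e =
0.12$) give across-subject correlations of ≈ 0.7 (no delay) and ≈ 0.45
(delay), a null intercept at no delay and a positive intercept at delay —
a realistic regime in which reinstatement partly decouples from the
hippocampal signature after consolidation. Cue and target channels default
to null effects but accept their own coefficients.

`fit_glmm()` fits the corresponding linear mixed model by REML
(`lme4::lmer`): fixed effects of delay, the hippocampal contrast, and their
interaction; a random intercept per participant. Design choices:

* **Random-effects structure.** A "random effect of delay per participant"
  on top of a participant intercept is unidentifiable with one observation
  per participant and condition; the random intercept (equivalently,
  compound symmetry of the two conditions) is the richest identifiable
  structure, and is what the package fits.
* **Uncentered predictor.** The hippocampal contrast is *not* centered by
  default: the intercepts must be interpretable at zero hippocampal
  contrast, because "reinstatement without a hippocampal signature" is the
  scientific question. `center_hipp = TRUE` is available for sensitivity
  analysis (slopes are invariant; intercepts shift).
* **Inference df.** All six derived contrasts — slope and intercept at each
  delay level, and their differences — use t statistics with residual
  df $= N_{obs} - 4$ (96 for 50 subjects). Satterthwaite/Kenward–Roger
  corrections are out of scope. The contrasts are linear in the fixed
  effects, so they are invariant to the factor coding; the identities
  `slope_diff = slope_delay − slope_nodelay` (and the intercept analogue)
  hold exactly.
* **Degenerate inputs.** If the fixed-effect design fits exactly (zero
  residual variance) REML is undefined; the fit falls back to the exact
  least-squares solution with zero standard errors, p = 0 for nonzero
  estimates and p = 1 otherwise. Boundary (singular) REML fits are
  reported with a warning and `glance()$singular = TRUE`; the variance is
  floored at zero.

`robustness_analysis()` implements the leave-k-out procedure: for each k
(default 1..20) it removes k randomly chosen participants, refits, and
records whether each contrast's reject/not-reject decision (default
α = 0.008, the Bonferroni level for six comparisons) agrees with the
full-sample decision, over 50 iterations per k. "Consistency" is reported
per contrast; agreement of the joint six-decision pattern can be derived
from the returned table if preferred.

```{r, warning = FALSE}
con <- simulate_contrasts(coupling_params(seed = 1), n_subjects = 50)
fit <- fit_glmm(con)
tidy(fit)
```

## Problem sizes and numerical tolerances

The test suite exercises the full 72-event design throughout but scales
cohort sizes to the question at hand: 50 subjects where a study-sized
cohort matters (accuracy calibration, df structure), 120–1,000 subjects for
null-calibration checks (type-I rates are held to 99% binomial bands), 500
replicate cohorts for parameter recovery (bias within 2 Monte-Carlo SEs),
and 10,000 subjects for moment-convergence checks of the contrast
simulator. Exact identities (brute-force table enumeration, `2p(1−p)`,
contrast linearity) are asserted to 1e-10–1e-12; agreements between two
estimation routes (REML vs OLS at boundary fits) to 1e-6.

## Limitations

* The package deliberately contains no voxel-level machinery: no
  preprocessing, first/second-level GLMs, multiple-comparison correction on
  images, or ROI extraction. Its ROI layer starts where a per-subject
  contrast table ends.
* The independent model uses subject-level marginal accuracies; dependency
  estimates on very few events per cell are noisy, and conditions with
  ceiling accuracy carry no information about dependency (`2p(1−p) → 0`).
* The coupling model treats the hippocampal contrast as a fixed regressor;
  measurement error in that contrast attenuates slopes, as in any
  errors-in-variables regression.
* Leave-k-out consistency is a stability diagnostic, not an inferential
  guarantee; for borderline effects it decreases with k on average but not
  monotonically in any single run.
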