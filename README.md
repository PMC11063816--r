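# loopmem

Statistical tooling for **holistic episodic retrieval** experiments with
closed- and open-loop event structures: counterbalanced design generation,
behavioural and ROI-level simulation with known ground truth, the
retrieval-dependency statistic, the within-subject inference battery, and
the hippocampal-coupling mixed model with a leave-k-out robustness
procedure.

## The scientific problem

In this paradigm participants learn three-element events
(location–person–object) as overlapping word pairs. For *closed loops* all
three pairwise associations are encoded; for *open loops* only two pairs
sharing a *common element* are encoded. Retrieval is a six-alternative
forced-choice cued-recognition test (chance ≈ 16.7%) of every encoded pair
in both directions, for events encoded either immediately or ~24 h before
retrieval. If retrieval is holistic — hippocampal pattern completion
reinstates the whole event from any cue — successes and failures on two
tests of the same event should covary.

**Retrieval dependency** captures that covariation. For a participant and
condition with directed-test accuracies $P_{AB}$, $P_{AC}$ over $N$
events, a 2×2 contingency table counts events by the joint outcome of two
tests; the *independent model* predicts cells
$N P_{AB} P_{AC},\ N P_{AB}(1-P_{AC}),\ N P_{AC}(1-P_{AB}),\
N(1-P_{AB})(1-P_{AC})$. With $p^{joint}$ the leading-diagonal proportion
(joint retrieval + joint non-retrieval), averaged over the condition's six
(closed) or four (open) tables,

$$\mathrm{dependency} = \bar p^{\,joint}_{data} - \bar p^{\,joint}_{indep}.$$

At the ROI level, the package fits the coupling between a subject's
hippocampal closed-vs-open contrast $h$ and their nontarget reinstatement
contrast $y$ across delay conditions $c$:

$$y_{ic} = \alpha_c + \beta_c h_{ic} + u_i + \varepsilon_{ic},
\qquad u_i \sim N(0, \sigma_u^2),$$

a linear mixed model (REML, random intercept per participant) whose six
derived contrasts — slope and intercept per condition and their
differences, tested on $t_{(N_{obs}-4)}$ — separate hippocampus-dependent
(slope) from hippocampus-independent (intercept) reinstatement.

## Worked example

```r
library(loopmem)

cfg      <- design_config(seed = 2024)              # 72 events, 18 per cell
events   <- generate_events(cfg)
schedule <- build_retrieval_schedule(events, cfg, seed = 2024)
outcomes <- simulate_cohort(generative_params(seed = 2024), schedule,
                            n_subjects = 50)

condition_summary(outcomes)[, c(1:2, 4, 6, 8, 10)]
#>   loop   delay    accuracy_mean joint_data_mean joint_independent_mean dependency_mean
#> 1 closed delay            0.610           0.643                  0.530          0.113
#> 2 closed no_delay         0.671           0.658                  0.564          0.094
#> 3 open   delay            0.514           0.523                  0.501          0.022
#> 4 open   no_delay         0.600           0.576                  0.524          0.052
```

Accuracy falls with delay and is higher for closed loops; dependency — the
excess of observed joint retrieval over the independent model — is large
for closed loops and near zero for open loops, exactly the holistic
signature the all-or-none simulator builds in. `behav_stats_report()` runs
the 2×2 within-subject ANOVA and the per-condition one-sample t tests
(with the Bonferroni-adjusted α = 0.0125, presented as 0.013).

```r
contrasts <- simulate_contrasts(coupling_params(seed = 2024), n_subjects = 50)
fit <- fit_glmm(contrasts)
print(fit)
#> Hippocampal-coupling mixed model (reml, 50 subjects, residual df = 96)
#> Variance components: subject 0.01881, residual 0.01199
#>
#>   contrast          estimate     se      t    df        p
#> 1 intercept_nodelay   0.0259 0.0286  0.903    96 3.69e- 1
#> 2 intercept_delay     0.152  0.0288  5.27     96 8.35e- 7
#> 3 intercept_diff      0.126  0.0301  4.17     96 6.56e- 5
#> 4 slope_nodelay       0.720  0.0959  7.50     96 3.16e-11
#> 5 slope_delay         0.507  0.106   4.77     96 6.59e- 6
#> 6 slope_diff         -0.213  0.145  -1.47     96 1.45e- 1
```

Here the slopes are positive in both conditions (hippocampal coupling), the
no-delay intercept is null, and the delay intercept is reliably positive:
reinstatement without a corresponding hippocampal signature — the regime
the default simulation parameters encode. `robustness_analysis(contrasts)`
reruns the model with k = 1..20 randomly removed participants (50
iterations each) and reports per-contrast decision consistency;
`autoplot()` methods visualise the fit and the consistency curves, and
`run_pipeline()` executes the whole chain (design → simulation →
dependency → stats → GLMM → robustness) into a directory of TSV/CSV/JSON
artifacts with a seed-stamped manifest.

A thin command-line wrapper with the same stages lives at
`inst/cli/loopmem.R`.

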