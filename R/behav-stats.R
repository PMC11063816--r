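#' One-sample t test with Cohen's d
#'
#' Two-tailed one-sample t test against `mu0`, reporting Cohen's d as the
#' mean difference divided by the standard deviation of the (difference)
#' scores. For paired contrasts, pass the per-subject difference scores.
#'
#' @param values Numeric vector (n >= 2, nonzero variance).
#' @param mu0 Null value (default 0).
#' @return One-row tibble: `estimate` (mean of `values`), `t`, `df`, `p`,
#'   `d`, `n`.
#' @export
#' @examples
#' one_sample_t(c(0.1, 0.3, 0.2, 0.4))
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort("`values` must hold at least 2 non-missing observations.")
  s <- sd(values)
  if (s < .Machine$double.eps^0.5 * max(1, abs(mean(values)))) {
    abort("`values` has (numerically) zero variance; the t statistic is undefined.")
  }
  ht <- t.test(values, mu = mu0)
  tibble(estimate = mean(values), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value,
         d = (mean(values) - mu0) / s, n = n)
}

#' 2x2 within-subject ANOVA via paired contrasts
#'
#' Each 1-df within-subject effect (two main effects and the interaction) is
#' the one-sample t test of its orthogonal contrast score across subjects,
#' reported as F = t^2 with df 1 and n - 1, plus partial eta squared
#' F / (F + df_den). This is exactly the repeated-measures decomposition for
#' a 2x2 design.
#'
#' @param data Long tibble with one value per subject x cell.
#' @param value Name of the response column (default `"value"`).
#' @param factors Character vector of the two within-subject factor columns
#'   (default `c("loop", "delay")`); each must have exactly two levels.
#' @param subject Name of the subject id column (default `"subject_id"`).
#' @return Tibble with one row per effect (`factors[1]`, `factors[2]`,
#'   `"interaction"`): `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`.
#' @export
anova_2x2_within <- function(data, value = "value",
                             factors = c("loop", "delay"),
                             subject = "subject_id") {
  check_columns(data, c(value, factors, subject), "`data`")
  f1 <- factor(data[[factors[1]]])
  f2 <- factor(data[[factors[2]]])
  if (nlevels(f1) != 2 || nlevels(f2) != 2) {
    abort("Both factors must have exactly two levels.")
  }
  cells <- data %>%
    select(subject_id = dplyr::all_of(subject)) %>%
    mutate(f1 = f1, f2 = f2, y = data[[value]]) %>%
    tidyr::pivot_wider(names_from = c("f1", "f2"), values_from = "y",
                       names_sep = ".")
  lv1 <- levels(f1)
  lv2 <- levels(f2)
  cn <- function(i, j) paste(lv1[i], lv2[j], sep = ".")
  need <- c(cn(1, 1), cn(1, 2), cn(2, 1), cn(2, 2))
  check_columns(cells, need, "cell matrix")
  if (anyNA(cells[need])) {
    abort("Every subject needs a value in all four cells.")
  }
  m <- as.matrix(cells[need])  # columns: (1,1) (1,2) (2,1) (2,2)
  scores <- list(
    (m[, 1] + m[, 2] - m[, 3] - m[, 4]) / 2,        # main effect factor 1
    (m[, 1] - m[, 2] + m[, 3] - m[, 4]) / 2,        # main effect factor 2
    (m[, 1] - m[, 2] - m[, 3] + m[, 4]) / 2         # interaction
  )
  purrr::map2_dfr(scores, c(factors, "interaction"), function(sc, eff) {
    n <- length(sc)
    se <- sd(sc) / sqrt(n)
    if (se == 0) {
      # degenerate contrast: either exactly null (no evidence) or a
      # perfectly determined nonzero effect
      null_eff <- mean(sc) == 0
      Fstat <- if (null_eff) 0 else Inf
      pval <- if (null_eff) 1 else 0
    } else {
      Fstat <- (mean(sc) / se)^2
      pval <- pt(sqrt(Fstat), n - 1, lower.tail = FALSE) * 2
    }
    tibble(effect = eff, F = Fstat, df_num = 1L, df_den = n - 1L, p = pval,
           partial_eta_sq = if (Fstat == 0) 0 else Fstat / (Fstat + (n - 1)))
  })
}

# half-up rounding (round() rounds half to even, which would print
# 0.0125 as 0.012)
round_half_up <- function(x, digits) floor(x * 10^digits + 0.5) / 10^digits

#' Bonferroni-adjusted alpha
#'
#' @param alpha Familywise level (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return One-row tibble: `alpha`, `m`, `alpha_adjusted` (= alpha / m) and
#'   `alpha_presented` (half-up rounded to 3 decimals, the conventional
#'   reporting precision: 0.05 / 4 presents as 0.013).
#' @export
#' @examples
#' bonferroni_alpha(0.05, 4)
bonferroni_alpha <- function(alpha = 0.05, m) {
  check_prob(alpha, "alpha")
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    abort("`m` must be a single integer >= 1.")
  }
  adj <- alpha / m
  tibble(alpha = alpha, m = as.integer(m), alpha_adjusted = adj,
         alpha_presented = round_half_up(adj, 3))
}

#' Power of a two-tailed one-sample t test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' d * sqrt(n) and df n - 1, including the (negligible) opposite-tail term.
#'
#' @param d Cohen's d effect size (> 0).
#' @param n Sample size (>= 2).
#' @param alpha Two-tailed significance level.
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_one_sample_t(d = 0.62, n = 30)
power_one_sample_t <- function(d, n, alpha = 0.05) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d <= 0) {
    abort("`d` must be a single positive effect size.")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 2) abort("`n` must be >= 2.")
  check_prob(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  df <- n - 1
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}

#' Minimal sample size for a one-sample t test
#'
#' Smallest integer n >= 2 whose two-tailed one-sample t-test power
#' (noncentral t) reaches the target.
#'
#' @inheritParams power_one_sample_t
#' @param power Target power in (0, 1).
#' @param n_max Upper scan bound.
#' @return Integer sample size.
#' @export
#' @examples
#' sample_size_one_sample_t(d = 0.62, alpha = 0.05, power = 0.90)
sample_size_one_sample_t <- function(d, alpha = 0.05, power = 0.90,
                                     n_max = 1e6) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d <= 0) {
    abort("`d` must be a single positive effect size; the target power is unreachable otherwise.")
  }
  check_prob(power, "power")
  for (n in 2:n_max) {
    if (power_one_sample_t(d, n, alpha) >= power) return(as.integer(n))
  }
  abort(sprintf("No n <= %g reaches power %g at d = %g.", n_max, power, d))
}

#' Behavioural statistics report for a cohort
#'
#' Runs the standard inference battery on per-subject accuracy and
#' dependency: the 2x2 loop x delay within-subject ANOVA on each measure,
#' and one-sample t tests of dependency against zero per condition with the
#' Bonferroni-adjusted alpha for the four comparisons.
#'
#' @param outcomes Outcome tibble covering >= 2 subjects.
#' @param alpha Familywise level (default 0.05).
#' @return List of class `behav_stats_report`: `accuracy_anova`,
#'   `dependency_anova`, `dependency_t` (with `alpha_adjusted` /
#'   `alpha_presented` columns), `condition_summary`.
#' @export
behav_stats_report <- function(outcomes, alpha = 0.05) {
  acc <- outcomes %>%
    group_by(.data$subject_id, .data$loop, .data$delay) %>%
    summarise(value = mean(.data$correct), .groups = "drop")
  dep <- dependency_summary(outcomes) %>% rename(value = "dependency")
  adj <- bonferroni_alpha(alpha, 4L)
  dep_t <- dep %>%
    group_by(.data$loop, .data$delay) %>%
    dplyr::group_modify(~ one_sample_t(.x$value)) %>%
    ungroup() %>%
    mutate(alpha_adjusted = adj$alpha_adjusted,
           alpha_presented = adj$alpha_presented)
  structure(list(accuracy_anova = anova_2x2_within(acc),
                 dependency_anova = anova_2x2_within(dep),
                 dependency_t = dep_t,
                 condition_summary = condition_summary(outcomes)),
            class = "behav_stats_report")
}

#' @export
print.behav_stats_report <- function(x, ...) {
  cat("Behavioural statistics report\n\n2x2 ANOVA on accuracy:\n")
  print(x$accuracy_anova)
  cat("\n2x2 ANOVA on dependency:\n")
  print(x$dependency_anova)
  cat("\nDependency vs zero (one-sample t):\n")
  print(x$dependency_t)
  invisible(x)
}
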