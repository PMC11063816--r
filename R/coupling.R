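#' Pearson correlation with two-tailed p value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, nonzero variance).
#' @return One-row tibble: `r`, `t`, `df`, `p`, `n`.
#' @export
#' @examples
#' pearson_r(1:10, (1:10) + rnorm(10))
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: one input has zero variance.")
  }
  ht <- cor.test(x, y)
  tibble(r = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value, n = length(x))
}

glmm_contrast_matrix <- function() {
  L <- rbind(
    intercept_nodelay = c(1, 0, 0, 0),
    intercept_delay   = c(1, 1, 0, 0),
    intercept_diff    = c(0, 1, 0, 0),
    slope_nodelay     = c(0, 0, 1, 0),
    slope_delay       = c(0, 0, 1, 1),
    slope_diff        = c(0, 0, 0, 1)
  )
  colnames(L) <- c("(Intercept)", "delay", "hipp", "delay:hipp")
  L
}

check_contrast_data <- function(data) {
  check_columns(data, c("subject_id", "delay", "hipp_contrast",
                        "nontarget_contrast"), "`data`")
  counts <- data %>% count(.data$subject_id, .data$delay)
  per_subj <- data %>% count(.data$subject_id)
  if (any(counts$n != 1) || any(per_subj$n != 2) ||
      !setequal(unique(data$delay), .delays)) {
    abort("Each subject needs exactly one row per delay condition (delay, no_delay).")
  }
  invisible(data)
}

#' Fit the hippocampal-coupling mixed model
#'
#' Linear mixed model of nontarget reinstatement (closed-minus-open
#' contrast) on delay condition, the hippocampal closed-vs-open contrast,
#' and their interaction, with a random intercept per participant, fitted by
#' REML. The hippocampal predictor is left uncentered by default so the
#' intercepts are interpretable as reinstatement at *zero* hippocampal
#' contrast — the quantity that separates hippocampus-dependent from
#' hippocampus-independent reinstatement. Six derived contrasts (slope and
#' intercept at each delay level and their differences) are tested against
#' t with residual df = N_obs - 4.
#'
#' If the fixed-effect design fits the data exactly (zero residual
#' variance), REML is undefined; the fit then reduces to the exact
#' least-squares solution with zero standard errors, and contrast p values
#' are 0 for nonzero estimates and 1 otherwise.
#'
#' @param data Tibble with one row per subject x delay condition:
#'   `subject_id`, `delay`, `hipp_contrast`, `nontarget_contrast` (e.g. from
#'   [simulate_contrasts()]).
#' @param center_hipp Center the hippocampal predictor (sensitivity
#'   analysis; changes the meaning of the intercepts). Default `FALSE`.
#' @return Object of class `coupling_glmm`: fixed-effect estimates, the six
#'   contrasts with t and p, variance components, residual df. Use
#'   [tidy()] / [glance()] or `print()`.
#' @export
#' @examples
#' fit <- fit_glmm(simulate_contrasts(coupling_params(seed = 4), 50))
#' tidy(fit)
fit_glmm <- function(data, center_hipp = FALSE) {
  check_contrast_data(data)
  d <- data %>%
    mutate(delay_f = factor(.data$delay, levels = c("no_delay", "delay")),
           hipp = .data$hipp_contrast -
             if (center_hipp) mean(.data$hipp_contrast) else 0)
  n_obs <- nrow(d)
  resid_df <- n_obs - 4L
  ols <- lm(nontarget_contrast ~ delay_f * hipp, data = d)
  exact <- stats::sigma(ols) < 1e-10
  singular <- FALSE
  if (exact) {
    beta <- coef(ols)
    V <- matrix(0, 4, 4)
    varcomp <- c(subject = 0, residual = 0)
    method <- "exact"
    model <- NULL
  } else {
    model <- withCallingHandlers(
      lme4::lmer(nontarget_contrast ~ delay_f * hipp + (1 | subject_id),
                 data = d, REML = TRUE),
      message = function(m) invokeRestart("muffleMessage")
    )
    singular <- lme4::isSingular(model)
    if (singular) {
      warn("Random-intercept variance estimated at the boundary (0); fixed effects equal ordinary least squares.")
    }
    beta <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- c(subject = vc$vcov[vc$grp == "subject_id"],
                 residual = vc$vcov[vc$grp == "Residual"])
    method <- "reml"
  }
  L <- glmm_contrast_matrix()
  est <- drop(L %*% beta)
  se <- sqrt(pmax(diag(L %*% V %*% t(L)), 0))
  if (exact) {
    nonzero <- abs(est) > 1e-8
    tstat <- ifelse(nonzero, sign(est) * Inf, 0)
    pval <- ifelse(nonzero, 0, 1)
  } else {
    tstat <- est / se
    pval <- 2 * pt(abs(tstat), resid_df, lower.tail = FALSE)
  }
  structure(list(
    fixed = tibble(term = names(beta), estimate = unname(beta),
                   se = sqrt(diag(V))),
    contrasts = tibble(contrast = rownames(L), estimate = unname(est),
                       se = unname(se), t = unname(tstat), df = resid_df,
                       p = unname(pval)),
    varcomp = varcomp, df = resid_df, n_obs = n_obs,
    n_subjects = n_obs / 2L, method = method, singular = singular,
    center_hipp = center_hipp, model = model, data = d
  ), class = "coupling_glmm")
}

#' @export
print.coupling_glmm <- function(x, ...) {
  cat(sprintf("Hippocampal-coupling mixed model (%s, %d subjects, residual df = %d)\n",
              x$method, x$n_subjects, x$df))
  cat(sprintf("Variance components: subject %.4g, residual %.4g\n\n",
              x$varcomp["subject"], x$varcomp["residual"]))
  print(x$contrasts)
  invisible(x)
}

#' Tidy and glance methods for coupling fits
#'
#' `tidy()` returns the six contrast rows (estimate, se, t, df, p);
#' `glance()` a one-row model summary (sizes, variance components,
#' estimation method).
#'
#' @param x A `coupling_glmm` fit.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy coupling_glmm
#' @export
tidy.coupling_glmm <- function(x, ...) x$contrasts

#' @rdname tidy.coupling_glmm
#' @method glance coupling_glmm
#' @export
glance.coupling_glmm <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_obs = x$n_obs, residual_df = x$df,
         var_subject = unname(x$varcomp["subject"]),
         var_residual = unname(x$varcomp["residual"]),
         method = x$method, singular = x$singular)
}

glmm_decisions <- function(fit, alpha) {
  setNames(fit$contrasts$p < alpha & !is.na(fit$contrasts$p),
           fit$contrasts$contrast)
}

#' Leave-k-out robustness of the coupling contrasts
#'
#' Refits the coupling model while removing k randomly chosen participants
#' (k = 1..`k_max`, `iters` random subsets per k) and reports, per contrast
#' and k, the fraction of iterations whose reject/not-reject decision at
#' `alpha` agrees with the full-sample decision.
#'
#' @inheritParams fit_glmm
#' @param ks Integer vector of removal counts (default `1:k_max`); `0` is
#'   allowed and trivially yields consistency 1.
#' @param k_max Largest removal count (used when `ks` is NULL).
#' @param iters Random subsets per k (default 50).
#' @param alpha Decision threshold; defaults to 0.008, the Bonferroni level
#'   for the six contrasts at familywise 0.05.
#' @param seed Optional integer seed.
#' @return Tibble of class `robustness_report`: `k`, `contrast`,
#'   `consistency`, `full_decision`, plus attributes `alpha` and `iters`.
#' @export
robustness_analysis <- function(data, k_max = 20L, iters = 50L,
                                alpha = 0.008, ks = NULL, seed = NULL,
                                center_hipp = FALSE) {
  check_contrast_data(data)
  subjects <- unique(data$subject_id)
  n <- length(subjects)
  if (is.null(ks)) ks <- seq_len(k_max)
  ks <- as.integer(ks)
  if (any(ks < 0) || n - max(ks) < 3) {
    abort(sprintf("Removal counts must leave at least 3 subjects (n = %d, max k = %d).",
                  n, max(ks)))
  }
  full <- glmm_decisions(fit_glmm(data, center_hipp), alpha)
  res <- with_seed(seed, {
    purrr::map_dfr(ks, function(k) {
      agree <- matrix(NA, nrow = iters, ncol = length(full))
      for (it in seq_len(iters)) {
        drop_s <- if (k == 0) character(0) else sample(subjects, k)
        sub <- data %>% filter(!.data$subject_id %in% drop_s)
        dec <- glmm_decisions(fit_glmm(sub, center_hipp), alpha)
        agree[it, ] <- dec == full
      }
      tibble(k = k, contrast = names(full),
             consistency = colMeans(agree),
             full_decision = unname(full))
    })
  })
  structure(res, class = c("robustness_report", class(res)),
            alpha = alpha, iters = as.integer(iters))
}

#' Closed-vs-open contrast t tests per role and condition
#'
#' One-sample t tests against zero of the closed-minus-open contrast for
#' each role (cue, target, nontarget) in each delay condition, with the
#' Bonferroni-adjusted alpha for the six comparisons; optionally also
#' collapsed across delay (three comparisons).
#'
#' @param data Contrast tibble (`subject_id`, `delay`, `cue_contrast`,
#'   `target_contrast`, `nontarget_contrast`).
#' @param alpha Familywise level (default 0.05).
#' @param collapse_delay Also test each role collapsed across conditions.
#' @return Tibble: `role`, `delay` (`"both"` for collapsed rows),
#'   `estimate`, `t`, `df`, `p`, `d`, `n`, `alpha_adjusted`,
#'   `alpha_presented`.
#' @export
role_contrast_tests <- function(data, alpha = 0.05, collapse_delay = FALSE) {
  cols <- c("cue_contrast", "target_contrast", "nontarget_contrast")
  check_columns(data, c("subject_id", "delay", cols), "`data`")
  long <- data %>%
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "role",
                        values_to = "contrast") %>%
    mutate(role = sub("_contrast$", "", .data$role))
  per_cond <- long %>%
    group_by(.data$role, .data$delay) %>%
    dplyr::group_modify(~ one_sample_t(.x$contrast)) %>%
    ungroup()
  out <- per_cond
  if (collapse_delay) {
    collapsed <- long %>%
      group_by(.data$subject_id, .data$role) %>%
      summarise(contrast = mean(.data$contrast), .groups = "drop") %>%
      group_by(.data$role) %>%
      dplyr::group_modify(~ one_sample_t(.x$contrast)) %>%
      ungroup() %>%
      mutate(delay = "both")
    out <- bind_rows(per_cond, collapsed)
  }
  m <- nrow(per_cond)
  adj <- bonferroni_alpha(alpha, m)
  out %>%
    mutate(alpha_adjusted = adj$alpha_adjusted,
           alpha_presented = adj$alpha_presented) %>%
    select("role", "delay", "estimate", "t", "df", "p", "d", "n",
           "alpha_adjusted", "alpha_presented")
}
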