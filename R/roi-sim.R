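#' Parameters of the hippocampal-neocortical coupling simulator
#'
#' Generates subject-level closed-minus-open BOLD contrasts with a known
#' linear coupling: per subject i and delay condition c, the nontarget
#' reinstatement contrast is
#' `alpha_c + beta_c * hipp + u_i + e`, where `hipp` is the subject's
#' hippocampal closed-vs-open contrast in that condition
#' (Normal(`hipp_mean`, `hipp_sd^2`)), `u_i` a subject random intercept
#' shared across the two conditions (Normal(0, `subj_sd^2`)) and `e`
#' residual noise (Normal(0, `resid_sd^2`)). Cue and target channels are
#' generated analogously with their own coefficients (default zero, i.e.
#' null effects).
#'
#' Defaults give a coupling of realistic strength for this kind of design:
#' an across-subject correlation of roughly 0.7 at no delay and 0.45 at
#' delay, a zero intercept at no delay and a positive intercept at delay
#' (reinstatement without a corresponding hippocampal signature); see the
#' methods vignette.
#'
#' @param alpha_nodelay,alpha_delay Condition intercepts: expected nontarget
#'   reinstatement (a.u.) at zero hippocampal contrast.
#' @param beta_nodelay,beta_delay Condition slopes on the hippocampal
#'   contrast.
#' @param hipp_mean,hipp_sd Across-subject distribution of the hippocampal
#'   contrast.
#' @param subj_sd Between-subject random-intercept SD.
#' @param resid_sd Residual SD.
#' @param cue_alpha,cue_beta,target_alpha,target_beta Length-2 numeric
#'   vectors `(no_delay, delay)` for the cue and target channels (default
#'   zeros).
#' @param seed Optional integer seed used as default by the simulator.
#' @return List of class `coupling_params`.
#' @export
#' @examples
#' coupling_params()
coupling_params <- function(alpha_nodelay = 0, alpha_delay = 0.15,
                            beta_nodelay = 0.8, beta_delay = 0.45,
                            hipp_mean = 0.15, hipp_sd = 0.2,
                            subj_sd = 0.12, resid_sd = 0.12,
                            cue_alpha = c(0, 0), cue_beta = c(0, 0),
                            target_alpha = c(0, 0), target_beta = c(0, 0),
                            seed = NULL) {
  for (s in c(hipp_sd = hipp_sd, subj_sd = subj_sd, resid_sd = resid_sd)) {
    if (!is.numeric(s) || s < 0) abort("Standard deviations must be >= 0.")
  }
  for (v in list(cue_alpha, cue_beta, target_alpha, target_beta)) {
    if (length(v) != 2 || !is.numeric(v)) {
      abort("Cue/target coefficients must be numeric length-2 (no_delay, delay).")
    }
  }
  structure(list(alpha = c(no_delay = alpha_nodelay, delay = alpha_delay),
                 beta = c(no_delay = beta_nodelay, delay = beta_delay),
                 hipp_mean = hipp_mean, hipp_sd = hipp_sd,
                 subj_sd = subj_sd, resid_sd = resid_sd,
                 cue_alpha = setNames(cue_alpha, c("no_delay", "delay")),
                 cue_beta = setNames(cue_beta, c("no_delay", "delay")),
                 target_alpha = setNames(target_alpha, c("no_delay", "delay")),
                 target_beta = setNames(target_beta, c("no_delay", "delay")),
                 seed = seed),
            class = "coupling_params")
}

#' Simulate subject-level ROI contrasts
#'
#' @param params A [coupling_params()].
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Optional integer seed; defaults to `params$seed`.
#' @return Tibble with one row per subject x delay condition: `subject_id`,
#'   `delay`, `hipp_contrast`, `nontarget_contrast`, `cue_contrast`,
#'   `target_contrast`.
#' @export
#' @examples
#' simulate_contrasts(coupling_params(seed = 3), n_subjects = 5)
simulate_contrasts <- function(params, n_subjects, seed = params$seed) {
  stopifnot(inherits(params, "coupling_params"))
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be >= 2.")
  }
  n_subjects <- as.integer(n_subjects)
  with_seed(seed, {
    u <- rnorm(n_subjects, 0, params$subj_sd)
    grid <- tidyr::expand_grid(subject_id = seq_len(n_subjects),
                               delay = c("no_delay", "delay"))
    grid %>%
      mutate(
        hipp_contrast = rnorm(n(), params$hipp_mean, params$hipp_sd),
        nontarget_contrast = unname(params$alpha[.data$delay]) +
          unname(params$beta[.data$delay]) * .data$hipp_contrast +
          u[.data$subject_id] + rnorm(n(), 0, params$resid_sd),
        cue_contrast = unname(params$cue_alpha[.data$delay]) +
          unname(params$cue_beta[.data$delay]) * .data$hipp_contrast +
          u[.data$subject_id] + rnorm(n(), 0, params$resid_sd),
        target_contrast = unname(params$target_alpha[.data$delay]) +
          unname(params$target_beta[.data$delay]) * .data$hipp_contrast +
          u[.data$subject_id] + rnorm(n(), 0, params$resid_sd)
      ) %>%
      arrange(.data$subject_id, dplyr::desc(.data$delay))
  })
}

#' Closed-minus-open contrasts from per-role BOLD means
#'
#' Turns per-subject role x loop x condition BOLD means into closed-vs-open
#' contrasts per role. The default baseline subtracts the open-loop mean of
#' the same delay condition; the `open_delay` baseline instead subtracts the
#' open-loop *delay* mean from the closed-loop no-delay mean — the fallback
#' analysis used when the open-loop no-delay condition itself shows
#' dependency and so is a contaminated baseline. The flag affects only the
#' no-delay rows.
#'
#' @param role_means Tibble: `subject_id`, `delay` (`delay` / `no_delay`),
#'   `role` (`cue` / `target` / `nontarget`), `loop`, `bold`.
#' @param baseline `"within_condition"` (default) or `"open_delay"`.
#' @return Tibble: `subject_id`, `delay`, `cue_contrast`, `target_contrast`,
#'   `nontarget_contrast`.
#' @export
compute_contrasts <- function(role_means,
                              baseline = c("within_condition", "open_delay")) {
  baseline <- match.arg(baseline)
  check_columns(role_means, c("subject_id", "delay", "role", "loop", "bold"),
                "`role_means`")
  wide <- role_means %>%
    tidyr::pivot_wider(names_from = "loop", values_from = "bold")
  check_columns(wide, c("closed", "open"), "`role_means` (loop levels)")
  full <- tidyr::expand_grid(subject_id = unique(wide$subject_id),
                             delay = .delays,
                             role = c("cue", "target", "nontarget"))
  wide <- left_join(full, wide, by = c("subject_id", "delay", "role"))
  if (anyNA(wide$closed) || anyNA(wide$open)) {
    bad <- wide[!complete.cases(wide[c("closed", "open")]), ][1, ]
    abort(sprintf("Missing BOLD mean for subject %s, %s, role %s.",
                  bad$subject_id, bad$delay, bad$role))
  }
  open_delay_ref <- wide %>%
    filter(.data$delay == "delay") %>%
    select("subject_id", "role", open_delay = "open")
  wide %>%
    left_join(open_delay_ref, by = c("subject_id", "role")) %>%
    mutate(ref = if (baseline == "open_delay") .data$open_delay else .data$open,
           contrast = .data$closed - .data$ref) %>%
    select("subject_id", "delay", "role", "contrast") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "contrast",
                       names_glue = "{role}_contrast") %>%
    select("subject_id", "delay", "cue_contrast", "target_contrast",
           "nontarget_contrast")
}
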