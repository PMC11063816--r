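# Default per-cell generative parameters. Chosen once so that marginal
# accuracy (1 - p_missing) * (rho * p_hi + (1 - rho) * p_lo) lands near the
# observed cohort means for the four cells (closed/no-delay ~.68,
# open/no-delay ~.62, closed/delay ~.61, open/delay ~.50) with a 1/6 guess
# floor and ~3.5% missing responses; see the methods vignette.
.default_cells <- tibble::tribble(
  ~loop,    ~delay,     ~rho, ~p_hi, ~p_lo,
  "closed", "no_delay", 0.55, 0.92, 0.440,
  "closed", "delay",    0.50, 0.90, 0.364,
  "open",   "no_delay", 0.25, 0.92, 0.550,
  "open",   "delay",    0.10, 0.90, 0.476
)

#' Generative parameters for the retrieval-outcome simulator
#'
#' The simulator draws, per event, a latent all-or-none "holistically
#' accessible" state with cell-specific probability `rho`; every directed
#' test of the event then succeeds independently with probability `p_hi`
#' (accessible) or `p_lo` (not accessible, at or above the 1/6 guessing
#' floor of the six-alternative forced choice). Missing responses occur with
#' probability `p_missing` and are scored incorrect.
#'
#' @param cells Tibble with columns `loop`, `delay`, `rho`, `p_hi`, `p_lo` —
#'   one row per loop x delay cell. Defaults emulate the marginal accuracies
#'   of a typical closed-/open-loop cohort.
#' @param guess Guessing floor (default 1/6, six-alternative forced choice).
#' @param p_missing Probability of a missing (timed-out) response.
#' @param rho_subject_sd Optional SD of logit-scale subject-level jitter on
#'   `rho` (default 0 = homogeneous subjects).
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (median
#'   `exp(rt_meanlog)` seconds); format fidelity only, never used in
#'   statistics.
#' @param seed Optional integer seed used as default by the simulators.
#'
#' @return A list of class `generative_params`.
#' @export
#' @examples
#' generative_params()
#' generative_params(cells = dplyr::mutate(generative_params()$cells, rho = 0))
generative_params <- function(cells = .default_cells, guess = 1 / 6,
                              p_missing = 0.035, rho_subject_sd = 0,
                              rt_meanlog = log(2.86), rt_sdlog = 0.15,
                              seed = NULL) {
  cells <- as_tibble(cells)
  check_columns(cells, c("loop", "delay", "rho", "p_hi", "p_lo"), "`cells`")
  if (nrow(distinct(cells, .data$loop, .data$delay)) != nrow(cells)) {
    abort("`cells` must have one row per loop x delay cell.")
  }
  for (col in c("rho", "p_hi", "p_lo")) {
    purrr::walk(cells[[col]], check_prob, name = col)
  }
  check_prob(guess, "guess")
  check_prob(p_missing, "p_missing")
  if (any(cells$p_lo < guess - 1e-12)) {
    abort("`p_lo` must be at or above the guessing floor in every cell.")
  }
  if (any(cells$p_hi < cells$p_lo)) {
    abort("`p_hi` must be >= `p_lo` in every cell.")
  }
  if (rho_subject_sd < 0) abort("`rho_subject_sd` must be >= 0.")
  structure(list(cells = cells, guess = guess, p_missing = p_missing,
                 rho_subject_sd = rho_subject_sd, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, seed = seed),
            class = "generative_params")
}

#' Expected marginal accuracy per cell
#'
#' Closed form `(1 - p_missing) * (rho * p_hi + (1 - rho) * p_lo)` for each
#' loop x delay cell of a parameter set.
#'
#' @param params A [generative_params()].
#' @return Tibble `loop`, `delay`, `accuracy`.
#' @export
expected_accuracy <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  params$cells %>%
    mutate(accuracy = (1 - params$p_missing) *
             (.data$rho * .data$p_hi + (1 - .data$rho) * .data$p_lo)) %>%
    select("loop", "delay", "accuracy")
}

#' Simulate one subject's retrieval outcomes
#'
#' Applies the all-or-none mixture to every non-null trial of a retrieval
#' schedule: one latent accessibility draw per event, then conditionally
#' independent test outcomes. Missing responses are scored incorrect and get
#' no response time.
#'
#' @param params A [generative_params()].
#' @param schedule Retrieval schedule from [build_retrieval_schedule()].
#' @param subject_id Identifier stored in the output (default 1).
#' @param seed Optional integer seed; defaults to `params$seed`.
#' @return Tibble of outcomes: `subject_id`, `event_id`, `loop`, `delay`,
#'   `cue_role`, `target_role`, `correct` (0/1), `missing` (0/1), `rt_s`
#'   (`NA` when missing).
#' @export
simulate_subject <- function(params, schedule, subject_id = 1L,
                             seed = params$seed) {
  stopifnot(inherits(params, "generative_params"))
  check_columns(schedule,
                c("event_id", "loop", "delay", "cue_role", "target_role"),
                "`schedule`")
  tr <- schedule %>% filter(!is.na(.data$event_id))
  with_seed(seed, {
    cells <- params$cells
    if (params$rho_subject_sd > 0) {
      z <- rnorm(1, 0, params$rho_subject_sd)
      cells <- cells %>%
        mutate(rho = stats::plogis(stats::qlogis(pmin(pmax(.data$rho, 1e-6),
                                                      1 - 1e-6)) + z))
    }
    ev <- tr %>%
      distinct(.data$event_id, .data$loop, .data$delay) %>%
      left_join(cells, by = c("loop", "delay"))
    if (anyNA(ev$rho)) {
      abort("`params$cells` lacks a row for some loop x delay cell in the schedule.")
    }
    ev$holistic <- rbinom(nrow(ev), 1, ev$rho)
    ev$p_test <- ifelse(ev$holistic == 1, ev$p_hi, ev$p_lo)
    out <- tr %>%
      left_join(ev %>% select("event_id", "p_test"), by = "event_id") %>%
      mutate(
        correct = as.integer(runif(n()) < .data$p_test),
        missing = as.integer(runif(n()) < params$p_missing),
        correct = ifelse(.data$missing == 1L, 0L, .data$correct),
        rt_s = ifelse(.data$missing == 1L, NA_real_,
                      pmin(rlnorm(n(), params$rt_meanlog, params$rt_sdlog),
                           .ret_duration)),
        subject_id = subject_id
      )
    out %>%
      select("subject_id", "event_id", "loop", "delay",
             "cue_role", "target_role", "correct", "missing", "rt_s")
  })
}

#' Simulate a cohort of subjects
#'
#' Independent subjects on a common schedule, each with a seed derived
#' deterministically from the master seed.
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects (>= 1).
#' @return Row-bound outcome tibble (see [simulate_subject()]), with
#'   `subject_id` 1..n_subjects.
#' @export
#' @examples
#' cfg <- design_config(seed = 7)
#' sched <- build_retrieval_schedule(generate_events(cfg), cfg)
#' out <- simulate_cohort(generative_params(seed = 7), sched, n_subjects = 3)
#' dplyr::count(out, subject_id)
simulate_cohort <- function(params, schedule, n_subjects,
                            seed = params$seed) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be >= 1.")
  }
  base <- if (is.null(seed)) sample.int(2^30, 1) else seed
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    simulate_subject(params, schedule, subject_id = s,
                     seed = derive_seed(base, s))
  })
}
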