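# All six directed tests, keyed "cue_target"
.dirs <- c("location_person", "location_object", "person_location",
           "person_object", "object_location", "object_person")

dir_key <- function(cue, target) paste(cue, target, sep = "_")

# The four abstract table kinds over roles A (common), B, C. Each pairs two
# directed tests; the table counts events by the joint outcome of the pair.
.table_kinds <- tibble::tribble(
  ~kind,           ~cue_1, ~target_1, ~cue_2, ~target_2,
  "common_cue",    "A",    "B",       "A",    "C",
  "common_target", "B",    "A",       "C",    "A",
  "mixed_ab_ca",   "A",    "B",       "C",    "A",
  "mixed_ba_ac",   "B",    "A",       "A",    "C"
)

#' Enumerate the contingency-table specifications for a loop type
#'
#' A closed loop is tested in all six directions, yielding six tables: for
#' each choice of common element A, one common-cue table (A_B with A_C) and
#' one common-target table (B_A with C_A). An open loop is tested only in
#' the four directions involving its common element A, yielding four
#' tables: common-cue, common-target, and the two mixed pairings
#' (A_B with C_A, and B_A with A_C).
#'
#' @param loop `"closed"` or `"open"`.
#' @param common_role For open loops, the common element's role; must be
#'   `NULL` for closed loops.
#' @return Tibble of table specs: `kind`, `a_role`, `b_role`, `c_role`, and
#'   the two directed tests `cue_1`/`target_1`, `cue_2`/`target_2` (concrete
#'   roles). B and C are the non-A roles in canonical
#'   location < person < object order.
#' @export
#' @examples
#' enumerate_tables("closed")
#' enumerate_tables("open", common_role = "location")
enumerate_tables <- function(loop, common_role = NULL) {
  loop <- match.arg(loop, .loops)
  if (loop == "closed" && !is.null(common_role)) {
    abort("Closed loops have no common element; leave `common_role` NULL.")
  }
  if (loop == "open" &&
      (is.null(common_role) || !common_role %in% .roles)) {
    abort("Open loops require `common_role` (one of location/person/object).")
  }
  a_set <- if (loop == "closed") .roles else common_role
  kinds <- if (loop == "closed") c("common_cue", "common_target") else
    .table_kinds$kind
  purrr::map_dfr(a_set, function(a) {
    bc <- setdiff(.roles, a)
    .table_kinds %>%
      filter(.data$kind %in% kinds) %>%
      mutate(a_role = a, b_role = bc[1], c_role = bc[2],
             dplyr::across(c("cue_1", "target_1", "cue_2", "target_2"),
                           ~ unname(c(A = a, B = bc[1], C = bc[2])[.x]))) %>%
      select("kind", "a_role", "b_role", "c_role",
             "cue_1", "target_1", "cue_2", "target_2")
  })
}

# per-event outcome pair (x = test 1, y = test 2) for a concrete spec
spec_outcome_pair <- function(outcomes, spec, loop, delay) {
  sub <- outcomes %>% filter(.data$loop == !!loop, .data$delay == !!delay)
  if (nrow(sub) == 0) abort(sprintf("No outcomes for %s / %s.", loop, delay))
  if (length(unique(sub$subject_id)) > 1) {
    abort("Contingency tables are per subject; filter to one `subject_id` first.")
  }
  get_dir <- function(cue, target) {
    d <- sub %>% filter(.data$cue_role == cue, .data$target_role == target)
    d %>% select("event_id", "correct")
  }
  x <- get_dir(spec$cue_1, spec$target_1)
  y <- get_dir(spec$cue_2, spec$target_2)
  events <- sort(unique(sub$event_id))
  for (d in list(c(spec$cue_1, spec$target_1), c(spec$cue_2, spec$target_2))) {
    have <- if (identical(d, c(spec$cue_1, spec$target_1))) x$event_id else y$event_id
    lost <- setdiff(events, have)
    if (length(lost) > 0) {
      abort(sprintf("Event %s has no outcome for direction %s -> %s.",
                    lost[1], d[1], d[2]))
    }
  }
  list(x = x$correct[match(events, x$event_id)],
       y = y$correct[match(events, y$event_id)])
}

contingency_cells <- function(x, y) {
  tibble(c11 = sum(x == 1 & y == 1), c10 = sum(x == 1 & y == 0),
         c01 = sum(x == 0 & y == 1), c00 = sum(x == 0 & y == 0),
         n_events = length(x))
}

independent_cells <- function(x, y) {
  n <- length(x)
  p <- mean(x)
  q <- mean(y)
  tibble(c11 = n * p * q, c10 = n * p * (1 - q),
         c01 = n * q * (1 - p), c00 = n * (1 - p) * (1 - q),
         n_events = n)
}

#' Observed 2x2 contingency table for one table spec
#'
#' Counts the events of one subject and condition by the joint outcome of
#' the spec's two directed tests: both correct (`c11`), first only (`c10`),
#' second only (`c01`), both incorrect (`c00`). Missing responses must
#' already be scored incorrect.
#'
#' @param outcomes Outcome tibble for a single subject (see
#'   [simulate_subject()] for the schema).
#' @param spec One row of [enumerate_tables()].
#' @param loop,delay Condition cell to tabulate.
#' @return One-row tibble `c11`, `c10`, `c01`, `c00`, `n_events`.
#' @export
build_observed_table <- function(outcomes, spec, loop, delay) {
  pair <- spec_outcome_pair(outcomes, spec, loop, delay)
  contingency_cells(pair$x, pair$y)
}

#' Independent-model 2x2 contingency table for one table spec
#'
#' Expected cell counts under independent retrieval: with P1 and P2 the
#' subject's mean accuracy for the spec's two directed tests across the
#' condition's events, the expected counts over N events are N*P1*P2,
#' N*P1*(1-P2), N*P2*(1-P1) and N*(1-P1)*(1-P2).
#'
#' @inheritParams build_observed_table
#' @return One-row tibble `c11`, `c10`, `c01`, `c00`, `n_events` (real
#'   valued; cells sum to `n_events`).
#' @export
build_independent_table <- function(outcomes, spec, loop, delay) {
  pair <- spec_outcome_pair(outcomes, spec, loop, delay)
  independent_cells(pair$x, pair$y)
}

#' Proportion of joint retrieval (and joint non-retrieval)
#'
#' The leading-diagonal sum of a 2x2 contingency table divided by the number
#' of events: the proportion of events where both tests succeed or both
#' fail.
#'
#' @param table One-row table from [build_observed_table()] or
#'   [build_independent_table()].
#' @return Proportion in \[0, 1\].
#' @export
joint_retrieval_proportion <- function(table) {
  check_columns(table, c("c11", "c00", "n_events"), "`table`")
  if (any(table$n_events <= 0)) abort("Contingency table has zero events.")
  (table$c11 + table$c00) / table$n_events
}

# wide per-event outcome matrix: one row per subject x event, one column per
# directed test; open-loop events infer their common role from which
# directions were tested
outcomes_wide <- function(outcomes) {
  check_columns(outcomes, c("subject_id", "event_id", "loop", "delay",
                            "cue_role", "target_role", "correct"),
                "`outcomes`")
  if ("missing" %in% names(outcomes) &&
      any(outcomes$missing == 1 & outcomes$correct == 1)) {
    abort("Missing responses must be scored incorrect (`correct` = 0).")
  }
  wide <- outcomes %>%
    mutate(dir = dir_key(.data$cue_role, .data$target_role)) %>%
    select("subject_id", "event_id", "loop", "delay", "dir", "correct") %>%
    tidyr::pivot_wider(names_from = "dir", values_from = "correct",
                       values_fn = function(v) {
                         if (length(v) > 1) {
                           abort("Duplicate outcome rows for one event and direction.")
                         }
                         v
                       })
  for (d in setdiff(.dirs, names(wide))) wide[[d]] <- NA_integer_
  m <- as.matrix(wide[.dirs])
  n_tested <- rowSums(!is.na(m))
  bad_closed <- wide$loop == "closed" & n_tested != 6L
  if (any(bad_closed)) {
    abort(sprintf("Closed-loop event %s of subject %s lacks outcomes for all six directions.",
                  wide$event_id[bad_closed][1], wide$subject_id[bad_closed][1]))
  }
  if (any(wide$loop == "open" & n_tested != 4L)) {
    bad <- which(wide$loop == "open" & n_tested != 4L)[1]
    abort(sprintf("Open-loop event %s of subject %s must have outcomes for exactly four directions.",
                  wide$event_id[bad], wide$subject_id[bad]))
  }
  # common role of an open event = the role taking part in all four tests
  common <- rep(NA_character_, nrow(wide))
  open_i <- which(wide$loop == "open")
  if (length(open_i) > 0) {
    role_of_dir <- strsplit(.dirs, "_")
    for (r in .roles) {
      in_dir <- vapply(role_of_dir, function(p) r %in% p, logical(1))
      hit <- rowSums(!is.na(m[open_i, in_dir, drop = FALSE])) == 4L
      common[open_i[hit]] <- r
    }
    if (anyNA(common[open_i])) {
      abort("Could not infer the common element of some open-loop events from the tested directions.")
    }
  }
  wide$common_role <- common
  wide
}

# relative (A/B/C) outcome columns for open-loop rows
relative_open_outcomes <- function(wide) {
  stopifnot(all(wide$loop == "open"))
  m <- as.matrix(wide[.dirs])
  a <- wide$common_role
  b <- purrr::map_chr(a, ~ setdiff(.roles, .x)[1])
  c_ <- purrr::map_chr(a, ~ setdiff(.roles, .x)[2])
  take_dir <- function(cue, target) {
    m[cbind(seq_len(nrow(m)), match(dir_key(cue, target), .dirs))]
  }
  wide$AB <- take_dir(a, b)
  wide$BA <- take_dir(b, a)
  wide$AC <- take_dir(a, c_)
  wide$CA <- take_dir(c_, a)
  wide
}

# mean data / independent-model joint proportions across a list of test
# pairs, for one subject x condition group
group_joint <- function(pairs) {
  stats <- purrr::map(pairs, function(p) {
    x <- p[[1]]
    y <- p[[2]]
    pq <- c(mean(x), mean(y))
    c(data = mean(x == y),
      indep = pq[1] * pq[2] + (1 - pq[1]) * (1 - pq[2]))
  })
  avg <- Reduce(`+`, stats) / length(stats)
  tibble(n_events = length(pairs[[1]][[1]]),
         p_joint_data = avg[["data"]],
         p_joint_independent = avg[["indep"]])
}

#' Retrieval dependency per subject and condition
#'
#' For every subject and loop x delay cell, builds the observed and
#' independent-model contingency tables (six per closed-loop condition, four
#' per open-loop condition), averages their joint-retrieval proportions
#' without weighting, and reports the dependency: the excess of the observed
#' joint proportion over the independent model. For open loops the tables
#' are role-relative — A is each event's own common element and B/C the
#' remaining roles in canonical order — pooled over all events of the cell.
#'
#' @param outcomes Outcome tibble (any number of subjects); missing
#'   responses must be scored incorrect.
#' @return Tibble: `subject_id`, `loop`, `delay`, `n_events`,
#'   `p_joint_data`, `p_joint_independent`, `dependency`.
#' @export
#' @examples
#' cfg <- design_config(seed = 2)
#' sched <- build_retrieval_schedule(generate_events(cfg), cfg)
#' out <- simulate_cohort(generative_params(seed = 2), sched, 2)
#' dependency_summary(out)
dependency_summary <- function(outcomes) {
  wide <- outcomes_wide(outcomes)

  closed <- wide %>% filter(.data$loop == "closed")
  closed_part <- NULL
  if (nrow(closed) > 0) {
    specs <- enumerate_tables("closed")
    closed_part <- closed %>%
      group_by(.data$subject_id, .data$loop, .data$delay) %>%
      dplyr::group_modify(function(g, key) {
        pairs <- purrr::map(seq_len(nrow(specs)), function(i) {
          list(g[[dir_key(specs$cue_1[i], specs$target_1[i])]],
               g[[dir_key(specs$cue_2[i], specs$target_2[i])]])
        })
        group_joint(pairs)
      }) %>%
      ungroup()
  }

  open <- wide %>% filter(.data$loop == "open")
  open_part <- NULL
  if (nrow(open) > 0) {
    rel <- relative_open_outcomes(open)
    open_part <- rel %>%
      group_by(.data$subject_id, .data$loop, .data$delay) %>%
      dplyr::group_modify(function(g, key) {
        group_joint(list(list(g$AB, g$AC), list(g$BA, g$CA),
                         list(g$AB, g$CA), list(g$BA, g$AC)))
      }) %>%
      ungroup()
  }

  bind_rows(closed_part, open_part) %>%
    mutate(dependency = .data$p_joint_data - .data$p_joint_independent) %>%
    arrange(.data$subject_id, .data$loop, .data$delay)
}

#' Condition-level behavioural summary
#'
#' Cohort means (and SDs) per loop x delay cell of the proportion correct,
#' the observed and independent-model joint-retrieval proportions, and the
#' dependency — the layout of a standard results table for this design.
#'
#' @param outcomes Outcome tibble covering one or more subjects.
#' @return Tibble with one row per loop x delay cell.
#' @export
condition_summary <- function(outcomes) {
  acc <- outcomes %>%
    group_by(.data$subject_id, .data$loop, .data$delay) %>%
    summarise(accuracy = mean(.data$correct), .groups = "drop")
  dep <- dependency_summary(outcomes)
  left_join(acc, dep, by = c("subject_id", "loop", "delay")) %>%
    group_by(.data$loop, .data$delay) %>%
    summarise(
      n_subjects = n(),
      accuracy_mean = mean(.data$accuracy), accuracy_sd = sd(.data$accuracy),
      joint_data_mean = mean(.data$p_joint_data),
      joint_data_sd = sd(.data$p_joint_data),
      joint_independent_mean = mean(.data$p_joint_independent),
      joint_independent_sd = sd(.data$p_joint_independent),
      dependency_mean = mean(.data$dependency),
      dependency_sd = sd(.data$dependency),
      .groups = "drop"
    )
}
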