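# Counterbalanced pair-presentation orders. Closed loops cycle through the
# three pairwise associations in one of three rotations; open loops use the
# first two pairs of the matching rotation, so the first two encoding trials
# of the two loop types are identical in structure. The open-loop order
# determines (and is determined by) the common element.
closed_pair_orders <- list(
  list(c("person", "location"), c("location", "object"), c("object", "person")),
  list(c("location", "object"), c("object", "person"), c("person", "location")),
  list(c("object", "person"), c("person", "location"), c("location", "object"))
)
open_pair_orders <- lapply(closed_pair_orders, function(o) o[1:2])
# common element of each open order = the role shared by its two pairs
open_order_common <- vapply(open_pair_orders, function(o) {
  intersect(o[[1]], o[[2]])
}, character(1))

#' Design configuration for a closed-/open-loop experiment
#'
#' Bundles the factorial counts of the design: the total number of
#' three-element events, the number of events per loop-by-delay cell, and the
#' number of null trials interleaved into each retrieval run.
#'
#' @param n_events Total number of events (default 72).
#' @param n_per_cell Events per loop x delay cell (default 18). Must satisfy
#'   `n_events == 4 * n_per_cell` and be divisible by 3 so that open-loop
#'   common elements can be balanced across the three roles.
#' @param nulls_per_run Null (rest) trials interleaved per retrieval run
#'   (default 18).
#' @param seed Optional integer seed recorded in the config and used as the
#'   default seed by the generators.
#'
#' @return A list of class `design_config`.
#' @export
#' @examples
#' design_config()
#' design_config(n_events = 48, n_per_cell = 12)
design_config <- function(n_events = 72L, n_per_cell = 18L,
                          nulls_per_run = 18L, seed = NULL) {
  n_events <- as.integer(n_events)
  n_per_cell <- as.integer(n_per_cell)
  nulls_per_run <- as.integer(nulls_per_run)
  if (n_events <= 0 || n_per_cell <= 0 || nulls_per_run < 0) {
    abort("All design counts must be positive (nulls_per_run may be 0).")
  }
  if (n_events != 4L * n_per_cell) {
    abort(sprintf("`n_events` (%d) must equal 4 * `n_per_cell` (%d).",
                  n_events, n_per_cell))
  }
  if (n_per_cell %% 3L != 0L) {
    abort(sprintf(paste0("`n_per_cell` (%d) must be divisible by 3 so open-loop ",
                         "common elements balance across roles."), n_per_cell))
  }
  structure(list(n_events = n_events, n_per_cell = n_per_cell,
                 nulls_per_run = nulls_per_run, seed = seed),
            class = "design_config")
}

#' Default element label pools
#'
#' Placeholder location/person/object labels for simulated designs. Real
#' studies would substitute word lists; downstream statistics never depend on
#' label content.
#'
#' @param n Number of labels per role.
#' @return Named list of three character vectors (`location`, `person`,
#'   `object`).
#' @export
default_element_pools <- function(n = 72L) {
  fmt <- function(role) sprintf("%s_%03d", role, seq_len(n))
  setNames(lapply(.roles, fmt), .roles)
}

#' Generate the event structures of a closed-/open-loop design
#'
#' Randomly assigns element labels to three-element events and events to the
#' four loop x delay cells. Open-loop events receive a common element
#' (the role present in both encoded pairs), balanced so that within each
#' encoding session each role is the common element for `n_per_cell / 3`
#' open loops. Closed-loop events are assigned one of the three rotated
#' pair-presentation orders in equal numbers per session.
#'
#' @param config A [design_config()].
#' @param element_pools Named list with `location`, `person` and `object`
#'   character vectors, each holding at least `n_events` distinct labels.
#'   Defaults to [default_element_pools()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A tibble with one row per event: `event_id`, `loop`, `delay`,
#'   `session` (1 = encoded a day before retrieval, i.e. the delay
#'   condition; 2 = encoded immediately before retrieval), `common_role`
#'   (`NA` for closed loops), `order_idx` (which counterbalanced pair order
#'   the event follows), and the `location` / `person` / `object` labels.
#' @export
#' @examples
#' ev <- generate_events(design_config(seed = 1))
#' dplyr::count(ev, loop, delay)
generate_events <- function(config = design_config(),
                            element_pools = default_element_pools(config$n_events),
                            seed = config$seed) {
  stopifnot(inherits(config, "design_config"))
  check_columns(as_tibble(element_pools[.roles]), .roles, "`element_pools`")
  for (role in .roles) {
    pool <- unique(element_pools[[role]])
    if (length(pool) < config$n_events) {
      abort(sprintf("`element_pools$%s` has %d distinct labels; at least %d required.",
                    role, length(pool), config$n_events))
    }
  }
  npc <- config$n_per_cell
  with_seed(seed, {
    cells <- tidyr::expand_grid(loop = .loops, delay = .delays)
    ev <- cells[rep(seq_len(4L), each = npc), ]
    ev <- ev[sample.int(nrow(ev)), ]
    ev$event_id <- seq_len(config$n_events)
    ev$session <- ifelse(ev$delay == "delay", 1L, 2L)
    # balanced common elements / order assignment, within session
    ev$common_role <- NA_character_
    ev$order_idx <- NA_integer_
    for (s in c(1L, 2L)) {
      open_i <- which(ev$session == s & ev$loop == "open")
      common <- sample(rep(.roles, each = npc / 3L))
      ev$common_role[open_i] <- common
      ev$order_idx[open_i] <- match(common, open_order_common)
      closed_i <- which(ev$session == s & ev$loop == "closed")
      ev$order_idx[closed_i] <- sample(rep(1:3, each = npc / 3L))
    }
    for (role in .roles) {
      ev[[role]] <- sample(unique(element_pools[[role]]), config$n_events)
    }
    ev %>%
      select("event_id", "loop", "delay", "session", "common_role",
             "order_idx", dplyr::all_of(.roles)) %>%
      arrange(.data$event_id)
  })
}

#' Encoded pairwise associations of each event
#'
#' Closed loops encode all three pairwise associations; open loops encode the
#' two pairs that share the common element. Pairs are listed in the event's
#' counterbalanced presentation order.
#'
#' @param events Event tibble from [generate_events()].
#' @return Tibble: `event_id`, `pair_idx` (presentation order), `role_1`,
#'   `role_2`.
#' @export
encoded_pairs <- function(events) {
  check_columns(events, c("event_id", "loop", "order_idx"), "`events`")
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ord <- if (events$loop[i] == "closed") {
      closed_pair_orders[[events$order_idx[i]]]
    } else {
      open_pair_orders[[events$order_idx[i]]]
    }
    tibble(event_id = events$event_id[i],
           pair_idx = seq_along(ord),
           role_1 = vapply(ord, `[`, character(1), 1),
           role_2 = vapply(ord, `[`, character(1), 2))
  })
}

# timing constants (seconds)
.enc_fixation <- 0.5
.enc_duration <- 6
.enc_blank <- 0.5
.enc_break <- 10   # rest after every 18 encoding trials
.ret_fixation <- 1
.ret_duration <- 6 # maximum response window; also the null-trial length
.ret_blank <- 1

#' Build an encoding schedule for one session
#'
#' Session 1 presents the events of the delay condition (encoded ~24 h before
#' retrieval), session 2 the no-delay events. Block 1 holds only the first
#' pair of each closed loop; blocks 2 and 3 interleave, in randomized order,
#' the remaining closed-loop pairs with the open-loop pairs, following each
#' event's counterbalanced pair order. On-screen left/right placement is
#' randomized per trial.
#'
#' @param events Event tibble from [generate_events()] (full design; the
#'   function selects the session's events).
#' @param session 1 or 2.
#' @param seed Optional integer seed.
#' @return Tibble of encoding trials: `session`, `block`, `position` (within
#'   block), `event_id`, `loop`, `role_1`/`role_2` (the encoded pair),
#'   `left_role`/`right_role` (screen placement), `onset` (s, stimulus
#'   onset), `duration` (6 s).
#' @export
build_encoding_schedule <- function(events, session, seed = NULL) {
  stopifnot(session %in% c(1L, 2L))
  check_columns(events, c("event_id", "loop", "session", "order_idx"), "`events`")
  ses <- events %>% filter(.data$session == !!session)
  n_closed <- sum(ses$loop == "closed")
  n_open <- sum(ses$loop == "open")
  if (n_closed != n_open || n_closed == 0) {
    abort(sprintf("Session %d must hold equal nonzero closed/open counts; got %d closed, %d open.",
                  session, n_closed, n_open))
  }
  pairs <- encoded_pairs(ses) %>%
    left_join(ses %>% select("event_id", "loop"), by = "event_id")
  with_seed(seed, {
    blocks <- list(
      pairs %>% filter(.data$loop == "closed", .data$pair_idx == 1L),
      pairs %>% filter((.data$loop == "closed" & .data$pair_idx == 2L) |
                         (.data$loop == "open" & .data$pair_idx == 1L)),
      pairs %>% filter((.data$loop == "closed" & .data$pair_idx == 3L) |
                         (.data$loop == "open" & .data$pair_idx == 2L))
    )
    sched <- purrr::imap_dfr(blocks, function(b, blk) {
      b <- b[sample.int(nrow(b)), ]
      b$block <- as.integer(blk)
      b$position <- seq_len(nrow(b))
      b
    })
    flip <- runif(nrow(sched)) < 0.5
    sched$left_role <- ifelse(flip, sched$role_2, sched$role_1)
    sched$right_role <- ifelse(flip, sched$role_1, sched$role_2)
    i <- seq_len(nrow(sched)) - 1L
    sched$onset <- .enc_fixation +
      i * (.enc_fixation + .enc_duration + .enc_blank) +
      .enc_break * (i %/% 18L)
    sched$duration <- .enc_duration
    sched$session <- as.integer(session)
    sched %>%
      select("session", "block", "position", "event_id", "loop",
             "role_1", "role_2", "left_role", "right_role",
             "onset", "duration")
  })
}

#' Build the retrieval schedule
#'
#' Every encoded pair of every event is tested in both cue directions in a
#' six-alternative forced-choice cued-recognition task: six tests per closed
#' loop, four per open loop (the never-encoded, potentially inferable
#' open-loop pair is never tested). Tests are split over two runs with half
#' the events of each loop x delay cell per run; within a run, trials from
#' the same event never occur on successive trials, and `nulls_per_run`
#' 6 s null trials are interleaved at uniformly drawn positions.
#'
#' @param events Event tibble from [generate_events()].
#' @param config The [design_config()] used to generate `events`.
#' @param seed Optional integer seed; defaults to `config$seed`.
#' @param max_retries Bound on rejection-sampling retries for the adjacency
#'   constraint.
#' @return Tibble of retrieval trials: `run`, `position`, `event_id` (`NA`
#'   for null trials), `loop`, `delay`, `cue_role`, `target_role`,
#'   `nontarget_role`, `is_null`, `onset` (s), `duration` (s; the 6 s
#'   maximum response window, also the null-trial length).
#' @export
build_retrieval_schedule <- function(events, config = design_config(),
                                     seed = config$seed,
                                     max_retries = 10000L) {
  stopifnot(inherits(config, "design_config"))
  check_columns(events, c("event_id", "loop", "delay", "order_idx"), "`events`")
  if (nrow(events) != config$n_events) {
    abort(sprintf("`events` has %d rows; config expects %d.",
                  nrow(events), config$n_events))
  }
  if (config$n_per_cell %% 2L != 0L) {
    abort("`n_per_cell` must be even to split each cell across two runs.")
  }
  tests <- encoded_pairs(events)
  tests <- bind_rows(
    tests %>% rename(cue_role = "role_1", target_role = "role_2"),
    tests %>% rename(cue_role = "role_2", target_role = "role_1")
  ) %>%
    left_join(events %>% select("event_id", "loop", "delay"), by = "event_id") %>%
    mutate(nontarget_role = purrr::map2_chr(
      .data$cue_role, .data$target_role,
      ~ setdiff(.roles, c(.x, .y))
    ))
  with_seed(seed, {
    run_of <- events %>%
      group_by(.data$loop, .data$delay) %>%
      mutate(run = sample(rep(1:2, each = n() / 2L))) %>%
      ungroup() %>%
      select("event_id", "run")
    tests <- tests %>% left_join(run_of, by = "event_id")
    # shuffle each run's trials subject to the adjacency constraint, then
    # interleave null trials at uniform positions
    sched <- purrr::map_dfr(1:2, function(r) {
      tr <- tests %>% filter(.data$run == r)
      tr <- order_run_trials(tr, max_retries)
      n_null <- config$nulls_per_run
      n_total <- nrow(tr) + n_null
      null_pos <- sort(sample.int(n_total, n_null))
      full <- tibble(position = seq_len(n_total),
                     is_null = position %in% null_pos)
      tr$position <- full$position[!full$is_null]
      out <- full %>% left_join(tr, by = "position")
      out$run <- as.integer(r)
      slot_len <- ifelse(out$is_null, .ret_duration,
                         .ret_fixation + .ret_duration + .ret_blank)
      out$onset <- c(0, cumsum(slot_len)[-n_total]) +
        ifelse(out$is_null, 0, .ret_fixation)
      out$duration <- .ret_duration
      out
    })
    sched %>%
      select("run", "position", "event_id", "loop", "delay",
             "cue_role", "target_role", "nontarget_role", "is_null",
             "onset", "duration")
  })
}

# uniform order of one run's trials with no same-event neighbours
order_run_trials <- function(tr, max_retries = 10000L) {
  n <- nrow(tr)
  if (n <= 1L) return(tr)
  if (max(table(tr$event_id)) > ceiling(n / 2)) {
    abort("Adjacency constraint unsatisfiable: one event occupies more than half the run.")
  }
  for (try in seq_len(max_retries)) {
    idx <- sample.int(n)
    ev <- tr$event_id[idx]
    if (!any(ev[-1] == ev[-n])) return(tr[idx, , drop = FALSE])
  }
  abort(sprintf(paste0("Could not order %d retrieval trials without same-event ",
                       "neighbours after %d retries."), n, max_retries))
}

#' Classify element roles on retrieval trials
#'
#' On every non-null trial one role is the cue, one the target, and the
#' remaining role is the nontarget whose incidental reinstatement indexes
#' holistic retrieval.
#'
#' @param trials Tibble with `cue_role` and `target_role` columns (e.g. from
#'   [build_retrieval_schedule()]). Null trials are not admissible.
#' @return `trials` with a `nontarget_role` column (recomputed) and a
#'   `role_map` list-column giving the role -> {cue, target, nontarget}
#'   mapping per trial.
#' @export
#' @examples
#' classify_trial_roles(tibble::tibble(cue_role = "location", target_role = "object"))
classify_trial_roles <- function(trials) {
  check_columns(trials, c("cue_role", "target_role"), "`trials`")
  if (("is_null" %in% names(trials) && any(trials$is_null)) ||
      any(is.na(trials$cue_role) | is.na(trials$target_role))) {
    abort("Null trials have no cue/target/nontarget roles.")
  }
  bad <- trials$cue_role == trials$target_role |
    !(trials$cue_role %in% .roles) | !(trials$target_role %in% .roles)
  if (any(bad)) {
    abort(sprintf("Invalid cue/target roles in row %d.", which(bad)[1]))
  }
  trials %>%
    mutate(
      nontarget_role = purrr::map2_chr(.data$cue_role, .data$target_role,
                                       ~ setdiff(.roles, c(.x, .y))),
      role_map = purrr::pmap(list(.data$cue_role, .data$target_role,
                                  .data$nontarget_role),
                             function(cu, ta, no) {
                               setNames(c("cue", "target", "nontarget"),
                                        c(cu, ta, no))
                             })
    )
}
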