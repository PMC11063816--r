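# Shared fixtures and independent straight-line oracles.

roles_ <- c("location", "person", "object")

# small full design + schedule (n_per_cell divisible by 6 so the retrieval
# runs split evenly); 48 events keeps the suite fast
small_design <- function(n_per_cell = 12, seed = 42) {
  cfg <- design_config(n_events = 4 * n_per_cell, n_per_cell = n_per_cell,
                       nulls_per_run = 6, seed = seed)
  ev <- generate_events(cfg)
  list(config = cfg, events = ev,
       schedule = build_retrieval_schedule(ev, cfg, seed = seed + 1))
}

# deterministic outcome table where every test of an event shares the
# event's success value: the all-or-none extreme. `success` is a logical
# vector indexed by event position within each subject x cell.
tied_outcomes <- function(schedule, p_success) {
  tr <- schedule[!schedule$is_null, ]
  ev <- unique(tr[c("event_id", "loop", "delay")])
  ev <- ev[order(ev$event_id), ]
  ev$ok <- 0L
  for (lo in unique(ev$loop)) {
    for (de in unique(ev$delay)) {
      i <- which(ev$loop == lo & ev$delay == de)
      n_on <- round(p_success * length(i))
      ev$ok[i[seq_len(n_on)]] <- 1L
    }
  }
  out <- merge(tr, ev[c("event_id", "ok")], by = "event_id")
  data.frame(subject_id = 1L, event_id = out$event_id, loop = out$loop,
             delay = out$delay, cue_role = out$cue_role,
             target_role = out$target_role, correct = out$ok,
             missing = 0L, rt_s = 2.5)
}

# Brute-force dependency for ONE subject and ONE loop x delay cell, written
# with explicit loops and no shared code with the package internals.
oracle_dependency_cell <- function(out) {
  stopifnot(length(unique(out$loop)) == 1)
  events <- sort(unique(out$event_id))
  val <- function(e, cue, tgt) {
    v <- out$correct[out$event_id == e & out$cue_role == cue &
                       out$target_role == tgt]
    stopifnot(length(v) == 1)
    v
  }
  # per-event A/B/C: A is the common element for open loops (the role taking
  # part in every test of the event); closed loops take all three choices
  table_pairs <- list()
  if (out$loop[1] == "closed") {
    for (a in roles_) {
      bc <- setdiff(roles_, a)
      table_pairs[[length(table_pairs) + 1]] <-
        list(x = function(e, a., b., c.) val(e, a., b.),
             y = function(e, a., b., c.) val(e, a., c.), a = a)
      table_pairs[[length(table_pairs) + 1]] <-
        list(x = function(e, a., b., c.) val(e, b., a.),
             y = function(e, a., b., c.) val(e, c., a.), a = a)
    }
  } else {
    mk <- function(fx, fy) list(x = fx, y = fy, a = NA)
    table_pairs <- list(
      mk(function(e, a., b., c.) val(e, a., b.),
         function(e, a., b., c.) val(e, a., c.)),
      mk(function(e, a., b., c.) val(e, b., a.),
         function(e, a., b., c.) val(e, c., a.)),
      mk(function(e, a., b., c.) val(e, a., b.),
         function(e, a., b., c.) val(e, c., a.)),
      mk(function(e, a., b., c.) val(e, b., a.),
         function(e, a., b., c.) val(e, a., c.))
    )
  }
  event_common <- function(e) {
    sub <- out[out$event_id == e, ]
    for (r in roles_) {
      if (all(r == sub$cue_role | r == sub$target_role)) return(r)
    }
    stop("no common role")
  }
  data_joint <- 0
  indep_joint <- 0
  for (tp in table_pairs) {
    x <- numeric(0)
    y <- numeric(0)
    for (e in events) {
      a <- if (out$loop[1] == "closed") tp$a else event_common(e)
      bc <- setdiff(roles_, a)
      x <- c(x, tp$x(e, a, bc[1], bc[2]))
      y <- c(y, tp$y(e, a, bc[1], bc[2]))
    }
    data_joint <- data_joint + mean(x == y)
    p <- mean(x)
    q <- mean(y)
    indep_joint <- indep_joint + (p * q + (1 - p) * (1 - q))
  }
  k <- length(table_pairs)
  c(data = data_joint / k, indep = indep_joint / k,
    dependency = (data_joint - indep_joint) / k)
}

# random single-subject outcomes on a tiny design (N events per cell)
random_small_outcomes <- function(n_per_cell = 3, seed = 1) {
  stopifnot(n_per_cell %% 3 == 0)
  cfg <- design_config(n_events = 4 * n_per_cell, n_per_cell = n_per_cell,
                       nulls_per_run = 0, seed = seed)
  ev <- generate_events(cfg)
  # build the test list directly (the retrieval scheduler needs even cell
  # splits; outcomes only need the directed tests)
  pr <- encoded_pairs(ev)
  tests <- rbind(
    data.frame(event_id = pr$event_id, cue_role = pr$role_1,
               target_role = pr$role_2),
    data.frame(event_id = pr$event_id, cue_role = pr$role_2,
               target_role = pr$role_1)
  )
  tests <- merge(tests, as.data.frame(ev[c("event_id", "loop", "delay")]),
                 by = "event_id")
  set.seed(seed)
  data.frame(subject_id = 1L, event_id = tests$event_id, loop = tests$loop,
             delay = tests$delay, cue_role = tests$cue_role,
             target_role = tests$target_role,
             correct = rbinom(nrow(tests), 1, runif(1, 0.2, 0.8)),
             missing = 0L, rt_s = 2)
}
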