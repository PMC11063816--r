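test_that("generate_events produces a balanced factorial design", {
  cfg <- design_config(seed = 7)
  ev <- generate_events(cfg)
  expect_equal(nrow(ev), 72)
  cells <- dplyr::count(ev, loop, delay)
  expect_true(all(cells$n == 18))
  # labels unique within role
  for (r in roles_) expect_equal(length(unique(ev[[r]])), 72)
  # open-loop common elements balanced per session: 6 per role
  bal <- dplyr::count(dplyr::filter(ev, loop == "open"),
                      session, common_role)
  expect_true(all(bal$n == 6))
  expect_equal(nrow(bal), 6)
  # closed loops carry no common element
  expect_true(all(is.na(ev$common_role[ev$loop == "closed"])))
})

test_that("generate_events is deterministic in the seed and validates input", {
  cfg <- design_config(seed = 3)
  expect_identical(generate_events(cfg), generate_events(cfg))
  ev_a <- generate_events(cfg, seed = 1)
  ev_b <- generate_events(cfg, seed = 2)
  expect_false(identical(ev_a$location, ev_b$location))
  # pool too small
  pools <- default_element_pools(72)
  pools$person <- pools$person[1:10]
  expect_error(generate_events(cfg, element_pools = pools), "person")
  # divisibility by 3
  expect_error(design_config(n_events = 4, n_per_cell = 1), "divisible by 3")
  expect_error(design_config(n_events = 10, n_per_cell = 3), "4 \\* ")
})

test_that("encoding schedules have the stated block structure", {
  ev <- generate_events(design_config(seed = 11))
  for (s in 1:2) {
    enc <- build_encoding_schedule(ev, s, seed = 20 + s)
    expect_equal(nrow(enc), 90)
    expect_equal(sum(enc$loop == "closed"), 54)
    expect_equal(sum(enc$loop == "open"), 36)
    expect_equal(dplyr::count(enc, block)$n, c(18, 36, 36))
    # block 1 is exclusively closed-loop pairs
    expect_true(all(enc$loop[enc$block == 1] == "closed"))
    # each event contributes exactly one pair per applicable block
    per_ev <- dplyr::count(enc, event_id, block)
    expect_true(all(per_ev$n == 1))
    per_ev_tot <- dplyr::count(enc, event_id, loop)
    expect_true(all(per_ev_tot$n[per_ev_tot$loop == "closed"] == 3))
    expect_true(all(per_ev_tot$n[per_ev_tot$loop == "open"] == 2))
    # onsets strictly increasing
    expect_true(all(diff(enc$onset) > 0))
  }
})

test_that("closed and open pair orders share their two-pair prefix", {
  # the first two pairs of each closed-loop rotation must be exactly an
  # open-loop order, so the two loop types are indistinguishable until the
  # third encoding trial
  ev <- generate_events(design_config(seed = 5))
  enc <- dplyr::bind_rows(build_encoding_schedule(ev, 1, seed = 1),
                          build_encoding_schedule(ev, 2, seed = 2))
  open_orders <- dplyr::filter(enc, loop == "open") |>
    dplyr::arrange(event_id, block) |>
    dplyr::group_by(event_id) |>
    dplyr::summarise(key = paste(role_1, role_2, collapse = ";"))
  closed_prefix <- dplyr::filter(enc, loop == "closed", block <= 2) |>
    dplyr::arrange(event_id, block) |>
    dplyr::group_by(event_id) |>
    dplyr::summarise(key = paste(role_1, role_2, collapse = ";"))
  expect_true(all(closed_prefix$key %in% unique(open_orders$key)))
  # the three orders are used equally often per session and loop type
  ord <- dplyr::count(ev, session, loop, order_idx)
  expect_true(all(ord$n == 6))
})

test_that("retrieval schedules satisfy all stated count constraints", {
  cfg <- design_config(seed = 13)
  ev <- generate_events(cfg)
  ret <- build_retrieval_schedule(ev, cfg, seed = 14)
  nonnull <- dplyr::filter(ret, !is_null)
  expect_equal(nrow(nonnull), 360)
  expect_equal(sum(nonnull$run == 1), 180)
  expect_equal(sum(ret$is_null & ret$run == 1), 18)
  expect_equal(sum(ret$is_null & ret$run == 2), 18)
  # six tests per closed loop, four per open loop
  per_ev <- dplyr::count(nonnull, event_id)
  per_ev <- dplyr::left_join(per_ev,
                             dplyr::select(ev, event_id, loop), by = "event_id")
  expect_true(all(per_ev$n[per_ev$loop == "closed"] == 6))
  expect_true(all(per_ev$n[per_ev$loop == "open"] == 4))
  # every encoded pair tested in both directions, exactly once each
  pairs <- encoded_pairs(ev)
  for (i in sample(nrow(pairs), 30)) {
    fwd <- sum(nonnull$event_id == pairs$event_id[i] &
                 nonnull$cue_role == pairs$role_1[i] &
                 nonnull$target_role == pairs$role_2[i])
    rev <- sum(nonnull$event_id == pairs$event_id[i] &
                 nonnull$cue_role == pairs$role_2[i] &
                 nonnull$target_role == pairs$role_1[i])
    expect_equal(c(fwd, rev), c(1, 1))
  }
  # the never-encoded open-loop pair is never tested: open events only show
  # directions involving their common element
  open_tr <- dplyr::left_join(dplyr::filter(nonnull, loop == "open"),
                              dplyr::select(ev, event_id, common_role),
                              by = "event_id")
  expect_true(all(open_tr$cue_role == open_tr$common_role |
                    open_tr$target_role == open_tr$common_role))
  # nine events of each cell per run
  ev_run <- dplyr::distinct(nonnull, run, event_id, loop, delay)
  spread <- dplyr::count(ev_run, run, loop, delay)
  expect_true(all(spread$n == 9))
  # onsets strictly increasing within run
  for (r in 1:2) expect_true(all(diff(ret$onset[ret$run == r]) > 0))
})

test_that("no two successive trials come from the same event", {
  # adjacency holds for the full schedule (nulls have no event) and for the
  # non-null subsequence flanking the nulls
  cfg <- design_config(seed = 17)
  for (s in 1:25) {
    ret <- build_retrieval_schedule(generate_events(cfg, seed = s), cfg,
                                    seed = 1000 + s)
    for (r in 1:2) {
      ids <- ret$event_id[ret$run == r]
      adj <- sum(ids[-1] == ids[-length(ids)], na.rm = TRUE)
      expect_equal(adj, 0)
      ids2 <- ids[!is.na(ids)]
      expect_equal(sum(ids2[-1] == ids2[-length(ids2)]), 0)
    }
  }
  # the constrained-shuffle primitive alone, hammered harder
  tr <- data.frame(event_id = rep(1:36, times = rep(c(6L, 4L), each = 18)))
  set.seed(99)
  for (i in 1:1000) {
    perm <- loopmem:::order_run_trials(tr)$event_id
    expect_equal(sum(perm[-1] == perm[-length(perm)]), 0)
  }
})

test_that("retrieval scheduling is deterministic and errors are informative", {
  cfg <- design_config(seed = 23)
  ev <- generate_events(cfg)
  expect_identical(build_retrieval_schedule(ev, cfg, seed = 5),
                   build_retrieval_schedule(ev, cfg, seed = 5))
  expect_false(identical(build_retrieval_schedule(ev, cfg, seed = 5),
                         build_retrieval_schedule(ev, cfg, seed = 6)))
  expect_error(build_retrieval_schedule(ev[1:10, ], cfg), "72")
  # an unsatisfiable adjacency constraint is reported, not looped forever
  tr <- data.frame(event_id = c(1, 1, 1, 1, 2))
  expect_error(loopmem:::order_run_trials(tr), "unsatisfiable")
})

test_that("classify_trial_roles maps the remaining role to nontarget", {
  got <- classify_trial_roles(tibble::tibble(
    cue_role = c("location", "person"), target_role = c("object", "location")
  ))
  expect_equal(got$nontarget_role, c("person", "object"))
  expect_equal(got$role_map[[1]][["person"]], "nontarget")
  expect_equal(got$role_map[[2]][["object"]], "nontarget")
  expect_error(
    classify_trial_roles(tibble::tibble(cue_role = NA_character_,
                                        target_role = "object",
                                        is_null = TRUE)),
    "Null trials")
  expect_error(
    classify_trial_roles(tibble::tibble(cue_role = "person",
                                        target_role = "person")),
    "Invalid")
})
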