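# Schedules travel as BIDS-style events TSV (onset/duration/trial_type
# first, custom columns after); analysis tables as plain CSV. Every writer
# prepends '#'-comment metadata lines (seed, config hash) that the readers
# skip.

outcomes_schema <- c("subject_id", "event_id", "loop", "delay",
                     "cue_role", "target_role", "correct", "missing", "rt_s")
contrasts_schema <- c("subject_id", "delay", "hipp_contrast",
                      "nontarget_contrast", "cue_contrast", "target_contrast")

write_with_meta <- function(x, path, meta, delim) {
  lines <- character(0)
  if (length(meta) > 0) {
    lines <- sprintf("# %s: %s", names(meta),
                     vapply(meta, as.character, character(1)))
  }
  body <- readr::format_delim(x, delim = delim, na = "")
  writeLines(c(lines, sub("\n$", "", body)), path, useBytes = TRUE)
  invisible(path)
}

read_meta <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1)
    if (length(l) == 0 || !startsWith(l, "#")) break
    hdr <- c(hdr, l)
  }
  if (length(hdr) == 0) return(list())
  kv <- strsplit(sub("^#\\s*", "", hdr), ":\\s*")
  setNames(lapply(kv, function(p) paste(p[-1], collapse = ": ")),
           vapply(kv, `[`, character(1), 1))
}

coerce_int <- function(df, cols) {
  for (col in intersect(cols, names(df))) df[[col]] <- as.integer(df[[col]])
  df
}

#' Write / read a BIDS-style events TSV
#'
#' Schedules are written with `onset`, `duration` and `trial_type` as the
#' leading columns (the BIDS events dialect), followed by the schedule's own
#' columns. `trial_type` is derived as `loop_delay` (or `"null"` /
#' `"encoding"`) when absent. Metadata (`seed`, `config_hash`, ...) is
#' stored in `#`-comment header lines.
#'
#' @param x Schedule tibble from [build_encoding_schedule()] or
#'   [build_retrieval_schedule()].
#' @param path Output .tsv path.
#' @param meta Named list of metadata scalars for the comment header.
#' @return `path`, invisibly (writer); a tibble with the metadata in
#'   attribute `"meta"` (reader).
#' @export
write_events_tsv <- function(x, path, meta = list()) {
  check_columns(x, c("onset", "duration"), "events table")
  if (!"trial_type" %in% names(x)) {
    x$trial_type <- if ("is_null" %in% names(x)) {
      ifelse(x$is_null, "null", paste(x$loop, x$delay, sep = "_"))
    } else if ("loop" %in% names(x)) {
      paste0("encoding_", x$loop)
    } else "trial"
  }
  x <- x %>% select("onset", "duration", "trial_type", dplyr::everything())
  write_with_meta(x, path, meta, "\t")
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  x <- readr::read_tsv(path, comment = "#", na = "",
                       show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("onset", "duration", "trial_type"), basename(path))
  x <- coerce_int(x, c("session", "block", "position", "event_id", "run"))
  if ("is_null" %in% names(x)) x$is_null <- as.logical(x$is_null)
  attr(x, "meta") <- read_meta(path)
  x
}

#' Write / read retrieval-outcome and ROI-contrast CSVs
#'
#' Plain CSV with a `#`-comment metadata header; the readers validate the
#' column schema and name any missing column.
#'
#' @param x Outcomes tibble ([simulate_subject()] schema) or contrasts
#'   tibble ([simulate_contrasts()] schema).
#' @param path File path.
#' @param meta Named list of metadata scalars.
#' @return `path` invisibly (writers); validated tibble with metadata in
#'   attribute `"meta"` (readers).
#' @export
write_outcomes_csv <- function(x, path, meta = list()) {
  check_columns(x, outcomes_schema, "outcomes table")
  write_with_meta(x[outcomes_schema], path, meta, ",")
}

#' @rdname write_outcomes_csv
#' @export
read_outcomes_csv <- function(path) {
  x <- readr::read_csv(path, comment = "#", na = "",
                       show_col_types = FALSE, progress = FALSE)
  check_columns(x, outcomes_schema, basename(path))
  x <- coerce_int(x, c("event_id", "correct", "missing"))
  bad <- which(!x$correct %in% c(0L, 1L) | !x$missing %in% c(0L, 1L))
  if (length(bad) > 0) {
    abort(sprintf("Column `correct`/`missing` must be 0/1; first offending row: %d.",
                  bad[1]))
  }
  if (any(x$missing == 1L & x$correct == 1L)) {
    abort("Rows with `missing` = 1 must have `correct` = 0.")
  }
  attr(x, "meta") <- read_meta(path)
  x
}

#' @rdname write_outcomes_csv
#' @export
write_contrasts_csv <- function(x, path, meta = list()) {
  check_columns(x, contrasts_schema, "contrasts table")
  write_with_meta(x[contrasts_schema], path, meta, ",")
}

#' @rdname write_outcomes_csv
#' @export
read_contrasts_csv <- function(path) {
  x <- readr::read_csv(path, comment = "#", na = "",
                       show_col_types = FALSE, progress = FALSE)
  check_columns(x, contrasts_schema, basename(path))
  bad_delay <- which(!x$delay %in% .delays)
  if (length(bad_delay) > 0) {
    abort(sprintf("Column `delay` must be 'delay' or 'no_delay'; first offending row: %d.",
                  bad_delay[1]))
  }
  attr(x, "meta") <- read_meta(path)
  x
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may set any of: `seed`, `n_subjects`, `baseline`, `alpha`,
#' `design` (fields of [design_config()]), `behavior` (fields of
#' [generative_params()], with `cells` as a list of per-cell blocks),
#' `coupling` (fields of [coupling_params()]), `robustness`
#' (`k_max`, `iters`, `alpha`). Unset fields keep package defaults.
#'
#' @param path .yaml/.yml or .json file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  design <- do.call(design_config, c(raw$design, list()))
  behavior_args <- raw$behavior
  if (!is.null(behavior_args$cells)) {
    behavior_args$cells <- bind_rows(lapply(behavior_args$cells, as_tibble))
  }
  behavior <- do.call(generative_params, c(behavior_args, list()))
  coupling <- do.call(coupling_params, c(raw$coupling, list()))
  pipeline_config(
    design = design, behavior = behavior, coupling = coupling,
    n_subjects = raw$n_subjects %||% 50L,
    baseline = raw$baseline %||% "within_condition",
    alpha = raw$alpha %||% 0.05,
    robustness = utils::modifyList(list(k_max = 20L, iters = 50L,
                                        alpha = 0.008),
                                   raw$robustness %||% list()),
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
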