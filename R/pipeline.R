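#' End-to-end pipeline configuration
#'
#' Bundles the sub-configurations of a full simulated study: design
#' generation, behavioural simulation, dependency and behavioural
#' statistics, ROI-contrast simulation, and the coupling GLMM with its
#' leave-k-out robustness settings.
#'
#' @param design A [design_config()].
#' @param behavior A [generative_params()].
#' @param coupling A [coupling_params()].
#' @param n_subjects Cohort size (default 50).
#' @param baseline Contrast baseline mode, `"within_condition"` or
#'   `"open_delay"` (metadata for downstream consumers; the simulator
#'   emits contrasts directly).
#' @param alpha Familywise level for the behavioural tests.
#' @param robustness List with `k_max`, `iters`, `alpha` for
#'   [robustness_analysis()]; set to `NULL` to skip the robustness stage.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            behavior = generative_params(),
                            coupling = coupling_params(),
                            n_subjects = 50L,
                            baseline = c("within_condition", "open_delay"),
                            alpha = 0.05,
                            robustness = list(k_max = 20L, iters = 50L,
                                              alpha = 0.008),
                            seed = 1L) {
  stopifnot(inherits(design, "design_config"),
            inherits(behavior, "generative_params"),
            inherits(coupling, "coupling_params"))
  baseline <- match.arg(baseline)
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  structure(list(design = design, behavior = behavior, coupling = coupling,
                 n_subjects = as.integer(n_subjects), baseline = baseline,
                 alpha = alpha, robustness = robustness,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the full simulated-study pipeline
#'
#' design -> encoding/retrieval schedules -> simulated retrieval outcomes ->
#' dependency + behavioural statistics -> simulated ROI contrasts ->
#' coupling GLMM -> leave-k-out robustness. Writes every stage's table
#' (TSV/CSV/JSON) plus a manifest with the config hash, seed and per-file
#' checksums. Identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory (created if absent).
#' @param quiet Suppress stage messages.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create `%s`.", out_dir))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  meta <- list(seed = seed, config_hash = config_hash(config))
  files <- character(0)
  emit <- function(name, writer, x) {
    path <- file.path(out_dir, name)
    writer(x, path, meta = meta)
    files <<- c(files, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  say("design: generating %d events", config$design$n_events)
  events <- stage("design", generate_events(config$design,
                                            seed = derive_seed(seed, 1)))
  encoding <- stage("design", bind_rows(
    build_encoding_schedule(events, 1, seed = derive_seed(seed, 2)),
    build_encoding_schedule(events, 2, seed = derive_seed(seed, 3))
  ))
  retrieval <- stage("design",
                     build_retrieval_schedule(events, config$design,
                                              seed = derive_seed(seed, 4)))
  emit("encoding_schedule.tsv", write_events_tsv, encoding)
  emit("retrieval_schedule.tsv", write_events_tsv, retrieval)
  say("design: %d encoding trials, %d retrieval trials",
      nrow(encoding), sum(!retrieval$is_null))

  say("simulate: %d subjects", config$n_subjects)
  outcomes <- stage("simulate",
                    simulate_cohort(config$behavior, retrieval,
                                    config$n_subjects,
                                    seed = derive_seed(seed, 5)))
  emit("outcomes.csv", write_outcomes_csv, outcomes)

  say("dependency: %d outcome rows", nrow(outcomes))
  dep <- stage("dependency", dependency_summary(outcomes))
  emit("dependency.csv", function(x, path, meta) {
    write_with_meta(x, path, meta, ",")
  }, dep)

  say("stats: behavioural inference")
  stats_report <- stage("stats", behav_stats_report(outcomes,
                                                    alpha = config$alpha))
  emit("behav_stats.json", function(x, path, meta) {
    jsonlite::write_json(c(meta, lapply(unclass(x), as.data.frame)),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }, stats_report)

  say("contrasts: simulating ROI data (baseline: %s)", config$baseline)
  contrasts <- stage("contrasts",
                     simulate_contrasts(config$coupling, config$n_subjects,
                                        seed = derive_seed(seed, 6)))
  emit("contrasts.csv", write_contrasts_csv, contrasts)

  say("glmm: fitting coupling model")
  fit <- stage("glmm", fit_glmm(contrasts))
  emit("glmm_report.json", function(x, path, meta) {
    jsonlite::write_json(c(meta, list(contrasts = as.data.frame(tidy(x)),
                                      fit = as.data.frame(glance(x)),
                                      role_tests = as.data.frame(
                                        role_contrast_tests(contrasts)))),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }, fit)

  if (!is.null(config$robustness)) {
    say("robustness: leave-k-out, k <= %d, %d iterations",
        config$robustness$k_max, config$robustness$iters)
    rob <- stage("robustness",
                 robustness_analysis(contrasts,
                                     k_max = config$robustness$k_max,
                                     iters = config$robustness$iters,
                                     alpha = config$robustness$alpha,
                                     seed = derive_seed(seed, 7)))
    emit("robustness.csv", function(x, path, meta) {
      write_with_meta(as_tibble(x), path, meta, ",")
    }, rob)
  }

  manifest <- list(
    package = "loopmem",
    version = as.character(utils::packageVersion("loopmem")),
    seed = seed,
    config_hash = config_hash(config),
    n_subjects = config$n_subjects,
    artifacts = lapply(setNames(files, files), function(f) {
      path <- file.path(out_dir, f)
      list(md5 = unname(tools::md5sum(path)), bytes = file.size(path))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: %d artifacts in %s", length(files), out_dir)
  invisible(manifest)
}
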