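# End-to-end orchestration: simulate (or load) -> segment -> detect ->
# score -> epoch analysis -> subject metrics -> group statistics -> report.

#' Build a pipeline configuration
#'
#' @param simulate List of arguments for [generate_cohort()] (used when
#'   `gaze_paths` is `NULL`): `n_subjects_per_group`, optionally
#'   `group_profiles`, `trace`.
#' @param gaze_paths Optional named list: per subject, a list with `gaze`
#'   and `events` CSV paths, bypassing simulation.
#' @param subject_metadata Data.frame with `subject_id`, `group`, `age`,
#'   `cag`; required with `gaze_paths`.
#' @param paradigm,kinematics Session configuration.
#' @param detection List of [detect_saccades()] options.
#' @param epoch_mode `"fixed"` (90-140 ms) or `"detected"` (delimit the
#'   express window from the pooled anti-trial histogram and reclassify).
#' @param metric_options List of [summarize_subject()] options.
#' @param out_dir Output directory; `NULL` for no file output.
#' @param make_figures Write SRT-distribution and summary figures.
#' @param seed Master seed for simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(n_subjects_per_group = 23),
                            gaze_paths = NULL,
                            subject_metadata = NULL,
                            paradigm = paradigm_config(),
                            kinematics = kinematic_model(),
                            detection = list(),
                            epoch_mode = c("fixed", "detected"),
                            metric_options = list(),
                            out_dir = NULL,
                            make_figures = FALSE,
                            seed = 1L) {
  epoch_mode <- match.arg(epoch_mode)
  structure(list(simulate = simulate, gaze_paths = gaze_paths,
                 subject_metadata = subject_metadata, paradigm = paradigm,
                 kinematics = kinematics, detection = detection,
                 epoch_mode = epoch_mode, metric_options = metric_options,
                 out_dir = out_dir, make_figures = make_figures,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `paradigm` and `kinematics` sections onto [paradigm_config()] /
#' [kinematic_model()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$paradigm)) {
    args$paradigm <- do.call(paradigm_config, y$paradigm)
  }
  if (!is.null(y$kinematics)) {
    args$kinematics <- do.call(kinematic_model, y$kinematics)
  }
  for (f in c("simulate", "detection", "epoch_mode", "metric_options",
              "out_dir", "make_figures", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, segments each recording into trials,
#' detects saccades, scores trials, delimits the express epoch, summarizes
#' each subject, and runs the group statistics. Deterministic given the
#' configuration seed. When `out_dir` is set, writes the scored-trial
#' table, subject-metrics table, statistics report (JSON), the resolved
#' configuration, an exclusion log, and (optionally) figures.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `scored` (per-subject list),
#'   `metrics`, `stats`, `express_window`, `exclusions`, `config`, and —
#'   for simulated cohorts — `cohort` (with ground truth).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  result <- tryCatch({
    if (is.null(config$gaze_paths)) {
      sim_args <- utils::modifyList(
        list(paradigm = config$paradigm, kinematics = config$kinematics,
             seed = config$seed),
        config$simulate)
      cohort <- do.call(generate_cohort, sim_args)
      metadata <- cohort$metadata
      sessions <- cohort$sessions
    } else {
      cohort <- NULL
      metadata <- config$subject_metadata
      if (is.null(metadata)) {
        stop("subject_metadata is required when loading recordings")
      }
      sessions <- lapply(config$gaze_paths, function(p) {
        list(gaze = read_gaze(p$gaze), events = read_events(p$events))
      })
      names(sessions) <- names(config$gaze_paths)
    }

    stage <- "detect/score"
    ecc <- config$paradigm$stimulus_eccentricity
    scored <- lapply(sessions, function(s) {
      if (is.null(s$gaze)) {
        score_from_truth(s$truth)
      } else {
        windows <- segment_trials(s$gaze, s$events)
        det <- do.call(detect_session,
                       c(list(windows = windows), config$detection))
        score_session(det, stimulus_eccentricity = ecc)
      }
    })
    names(scored) <- names(sessions)

    stage <- "epoch"
    pooled <- do.call(rbind, scored)
    window <- tryCatch(
      detect_express_window(srt_histogram(pooled)),
      error = function(e) NULL)
    if (config$epoch_mode == "detected" && !is.null(window) &&
        window$end > window$start) {
      scored <- lapply(scored, classify_by_window, window = window)
    }

    stage <- "metrics"
    metrics <- do.call(summarize_cohort,
                       c(list(scored_by_subject = scored,
                              metadata = metadata),
                         config$metric_options))

    stage <- "stats"
    # cohorts too small for the 2x2 design still produce tables/metrics
    stats_res <- tryCatch(group_statistics(metrics), error = function(e) {
      message("group statistics skipped: ", conditionMessage(e))
      NULL
    })

    exclusions <- data.frame(
      subject_id = metrics$subject_id,
      excluded_trials = vapply(scored, function(s)
        sum(s$outcome == "excluded"), integer(1)),
      flagged_trials = vapply(scored, function(s)
        sum(s$flagged), integer(1)))

    structure(list(scored = scored, metrics = metrics, stats = stats_res,
                   express_window = window, exclusions = exclusions,
                   config = config, cohort = cohort),
              class = "pipeline_result")
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) write_pipeline_outputs_(result)
  result
}

write_pipeline_outputs_ <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- result$config$out_dir
  pooled <- data.table::rbindlist(result$scored, idcol = "subject_id")
  data.table::fwrite(pooled, file.path(od, "scored_trials.csv"))
  data.table::fwrite(result$metrics, file.path(od, "subject_metrics.csv"))
  data.table::fwrite(result$exclusions, file.path(od, "exclusions.csv"))

  st <- result$stats
  report <- list(
    anova = if (is.null(st)) NULL else
      lapply(st$anova, function(a) as.list(as.data.frame(a))),
    correlations = if (is.null(st)) NULL else
      lapply(st$correlations, function(cr)
        if (is.null(cr)) NULL else cr[c("r", "df", "p", "n")]),
    express_window = if (is.null(result$express_window)) NULL else
      result$express_window[c("start", "end", "alpha")],
    notes = c("per-bin binomial tests are uncorrected for multiple bins",
              "no multiple-comparison correction across behavioral ANOVAs"))
  jsonlite::write_json(report, file.path(od, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg <- result$config
  cfg_list <- list(seed = cfg$seed, epoch_mode = cfg$epoch_mode,
                   paradigm = unclass(cfg$paradigm),
                   kinematics = unclass(cfg$kinematics))
  yaml::write_yaml(cfg_list, file.path(od, "resolved_config.yaml"))

  if (isTRUE(cfg$make_figures)) {
    p1 <- plot_srt_distribution(pooled)
    ggplot2::ggsave(file.path(od, "srt_distributions.png"), p1,
                    width = 9, height = 6, dpi = 150)
    p2 <- plot_group_summary(result$metrics)
    ggplot2::ggsave(file.path(od, "group_summary.png"), p2,
                    width = 9, height = 4, dpi = 150)
  }
  invisible(od)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$metrics), "subjects;",
      "express window",
      if (is.null(x$express_window)) "n/a" else
        sprintf("[%g, %g] ms", x$express_window$start, x$express_window$end),
      "\n")
  if (!is.null(x$stats)) print(x$stats$anova$mean_srt)
  invisible(x)
}
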