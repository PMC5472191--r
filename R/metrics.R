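# Per-subject behavioral summary metrics.

#' Disease-burden score
#'
#' `age x (CAG - 35.5)`: the standard age-by-expansion interaction used as a
#' progression covariate in Huntington's disease.
#'
#' @param age Years.
#' @param cag CAG repeat length.
#' @return Numeric; `NA` when `cag` is missing.
#' @examples
#' disease_burden(49.6, 44.2)  # 431.52
#' @export
disease_burden <- function(age, cag) {
  ifelse(is.na(cag) | is.na(age), NA_real_, age * (cag - 35.5))
}

#' Summarize one subject's scored trials
#'
#' Computes, separately for pro and anti trials: mean SRT and its
#' coefficient of variation (sample SD / mean x 100%) over correct saccades
#' with SRT in `srt_range` (default 90-1000 ms); the percentages of
#' anticipatory, express, regular-latency and no-response trials (over all
#' valid, i.e. non-excluded, trials of the condition — these four sum to
#' 100); the overall direction-error percentage (errors over correct +
#' error trials, anticipatory trials excluded from the denominator since
#' their direction is at chance); and the error percentages within the
#' express and regular epochs. Epoch error rates are conditional by default
#' (errors in the epoch / trials in the epoch); set
#' `error_denominator = "responses"` to express them instead as shares of
#' all non-anticipatory responses.
#'
#' @param scored Scored-trial data.frame for one subject.
#' @param metadata Optional one-row list/data.frame with `subject_id`,
#'   `group`, `age`, `cag`.
#' @param srt_range SRT inclusion range for mean/CV, ms.
#' @param min_valid_trials Flag (not drop) conditions with fewer valid
#'   trials than this.
#' @param error_denominator `"epoch"` (conditional rates) or `"responses"`.
#' @return A one-row data.frame with per-condition columns suffixed `_pro` /
#'   `_anti` (`mean_srt`, `cv_srt`, `pct_anticipatory`, `pct_express`,
#'   `pct_regular`, `pct_no_response`, `pct_direction_error`,
#'   `pct_error_express`, `pct_error_regular`, `n_valid`), `anti_effect`,
#'   metadata columns and `disease_burden`.
#' @export
summarize_subject <- function(scored, metadata = NULL,
                              srt_range = c(90, 1000),
                              min_valid_trials = 20,
                              error_denominator = c("epoch", "responses")) {
  error_denominator <- match.arg(error_denominator)
  out <- list()
  for (cond in c("pro", "anti")) {
    s <- scored[scored$condition == cond, , drop = FALSE]
    valid <- s[s$outcome != "excluded", , drop = FALSE]
    nv <- nrow(valid)
    sfx <- paste0("_", cond)
    out[[paste0("n_valid", sfx)]] <- nv
    out[[paste0("low_trial_flag", sfx)]] <- nv < min_valid_trials

    ok <- valid$outcome == "correct" & valid$srt >= srt_range[1] &
      valid$srt <= srt_range[2]
    srts <- valid$srt[ok]
    if (length(srts) >= 1) {
      m <- mean(srts)
      cv <- if (length(srts) >= 2) stats::sd(srts) / m * 100 else 0
      out[[paste0("mean_srt", sfx)]] <- m
      out[[paste0("cv_srt", sfx)]] <- cv
    } else {
      out[[paste0("mean_srt", sfx)]] <- NA_real_
      out[[paste0("cv_srt", sfx)]] <- NA_real_
    }

    pct <- function(x) if (nv == 0) NA_real_ else 100 * sum(x) / nv
    out[[paste0("pct_anticipatory", sfx)]] <-
      pct(valid$outcome == "anticipatory")
    out[[paste0("pct_express", sfx)]] <- pct(valid$epoch == "express")
    out[[paste0("pct_regular", sfx)]] <- pct(valid$epoch == "regular")
    out[[paste0("pct_no_response", sfx)]] <-
      pct(valid$outcome == "no_response")

    resp <- valid[valid$outcome %in% c("correct", "direction_error"), ,
                  drop = FALSE]
    out[[paste0("pct_direction_error", sfx)]] <-
      if (nrow(resp) == 0) NA_real_ else
        100 * mean(resp$outcome == "direction_error")
    for (ep in c("express", "regular")) {
      inep <- resp[resp$epoch == ep, , drop = FALSE]
      denom <- if (error_denominator == "epoch") nrow(inep) else nrow(resp)
      out[[paste0("pct_error_", ep, sfx)]] <-
        if (denom == 0) NA_real_ else
          100 * sum(inep$outcome == "direction_error") / denom
    }
  }
  out$anti_effect <- out$mean_srt_anti - out$mean_srt_pro
  if (!is.null(metadata)) {
    for (f in c("subject_id", "group", "age", "cag")) {
      if (!is.null(metadata[[f]])) out[[f]] <- metadata[[f]]
    }
    if (!is.null(metadata$age) && !is.null(metadata$cag)) {
      out$disease_burden <- disease_burden(metadata$age, metadata$cag)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Anti-effect: mean anti-SRT minus mean pro-SRT
#'
#' The latency cost of suppressing the reflexive saccade and generating the
#' inverted voluntary one.
#'
#' @param metrics A subject-metrics row from [summarize_subject()], or a
#'   list with `mean_srt_anti` and `mean_srt_pro`.
#' @return ms; `NA` when either condition mean is missing.
#' @export
anti_effect <- function(metrics) {
  a <- metrics$mean_srt_anti
  p <- metrics$mean_srt_pro
  if (is.null(a) || is.null(p)) return(NA_real_)
  a - p
}

#' Summarize every subject of a cohort
#'
#' Maps scored sessions to the subject-metrics table that feeds the group
#' statistics.
#'
#' @param scored_by_subject Named list of scored-trial data.frames.
#' @param metadata Cohort metadata (`subject_id`, `group`, `age`, `cag`).
#' @param ... Passed to [summarize_subject()].
#' @return A data.frame, one row per subject.
#' @export
summarize_cohort <- function(scored_by_subject, metadata, ...) {
  rows <- lapply(seq_along(scored_by_subject), function(i) {
    id <- names(scored_by_subject)[i]
    md <- metadata[metadata$subject_id == id, , drop = FALSE]
    summarize_subject(scored_by_subject[[i]],
                      metadata = as.list(md), ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a subject-metrics table to long (subject x task) format
#'
#' Produces the layout the mixed-design ANOVA consumes: one row per subject
#' and task with columns `subject_id`, `group`, `task` and one column per
#' requested measure.
#'
#' @param metrics Subject-metrics data.frame from [summarize_cohort()].
#' @param measures Character vector of per-condition measures (base names
#'   without the `_pro`/`_anti` suffix).
#' @return A long-format data.frame.
#' @export
metrics_long <- function(metrics,
                         measures = c("mean_srt", "cv_srt",
                                      "pct_direction_error",
                                      "pct_error_express",
                                      "pct_error_regular",
                                      "pct_anticipatory")) {
  rows <- lapply(c("pro", "anti"), function(task) {
    d <- data.frame(subject_id = metrics$subject_id,
                    group = metrics$group,
                    task = task, stringsAsFactors = FALSE)
    for (m in measures) d[[m]] <- metrics[[paste0(m, "_", task)]]
    d
  })
  do.call(rbind, rows)
}
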