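# Group-level statistical battery: 2x2 mixed-design ANOVA with partial eta
# squared, two-sample Kolmogorov-Smirnov comparison of SRT distributions,
# two-tailed Pearson correlation, Shapiro-Wilk normality annotation.
#
# The mixed ANOVA is computed by explicit sums-of-squares decomposition into
# its between-subject stratum (group, tested against subjects-within-group)
# and within-subject stratum (task and group x task, tested against the
# subject x task residual). Unequal group sizes are handled by the
# unweighted-means (Type III equivalent) solution with the harmonic mean of
# the group sizes; for balanced designs this coincides with the classical
# decomposition.

#' Two-by-two mixed-design ANOVA (between group x within task)
#'
#' @param data Long-format data.frame with one row per subject x task.
#' @param dv Name of the dependent-variable column.
#' @param subject,group,task Column names of the design factors. `group`
#'   must have exactly 2 levels between subjects and `task` exactly 2
#'   levels within subjects.
#' @return A data.frame of class `mixed_anova` with one row per effect
#'   (`group`, `task`, `group:task`): `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, `ss_effect`, `ss_error`. Subjects with an incomplete
#'   task pair are dropped with a message. With zero error variance the
#'   statistics are reported as `NaN` (degenerate).
#' @examples
#' d <- expand.grid(subject_id = sprintf("s%d", 1:8), task = c("pro", "anti"))
#' d$group <- rep(rep(c("a", "b"), each = 4), 2)
#' d$y <- rnorm(16)
#' mixed_anova_2x2(d, "y")
#' @export
mixed_anova_2x2 <- function(data, dv, subject = "subject_id",
                            group = "group", task = "task") {
  d <- data.frame(s = as.character(data[[subject]]),
                  g = as.character(data[[group]]),
                  t = as.character(data[[task]]),
                  y = as.numeric(data[[dv]]), stringsAsFactors = FALSE)
  d <- d[!is.na(d$y), , drop = FALSE]
  n_tasks <- sort(unique(d$t))
  if (length(n_tasks) != 2 || length(unique(d$g)) != 2) {
    stop("design must have exactly 2 groups and 2 tasks")
  }
  cnt <- table(d$s)
  incomplete <- names(cnt)[cnt != 2]
  if (length(incomplete) > 0) {
    message("dropping ", length(incomplete),
            " subject(s) with incomplete task data: ",
            paste(incomplete, collapse = ", "))
    d <- d[!d$s %in% incomplete, , drop = FALSE]
  }
  subjects <- unique(d$s)
  N <- length(subjects)
  if (N < 4) stop("need at least 2 complete subjects per group")

  subj_group <- tapply(d$g, d$s, function(x) x[1])
  groups <- sort(unique(d$g))
  n_g <- table(factor(subj_group, levels = groups))
  n_h <- length(groups) / sum(1 / as.numeric(n_g))   # harmonic mean

  cell <- tapply(d$y, list(d$g, d$t), mean)           # 2 x 2 cell means
  u_g <- rowMeans(cell)                               # unweighted margins
  u_t <- colMeans(cell)
  u <- mean(cell)

  ss_group <- 2 * n_h * sum((u_g - u)^2)
  ss_task <- 2 * n_h * sum((u_t - u)^2)
  ss_int <- n_h * sum((sweep(sweep(cell, 1, u_g), 2, u_t) + u)^2)

  subj_mean <- tapply(d$y, d$s, mean)
  grp_of <- subj_group[names(subj_mean)]
  grp_mean_subj <- tapply(subj_mean, grp_of, mean)    # mean of subject means
  ss_subj_within <- 2 * sum((subj_mean - grp_mean_subj[grp_of])^2)

  # within-subject residual: observation minus cell mean minus subject effect
  fitted <- cell[cbind(d$g, d$t)] +
    (subj_mean[d$s] - grp_mean_subj[subj_group[d$s]])
  ss_resid <- sum((d$y - fitted)^2)

  df_between <- N - 2
  df_within <- N - 2
  eff <- data.frame(
    effect = c("group", "task", "group:task"),
    ss_effect = c(ss_group, ss_task, ss_int),
    ss_error = c(ss_subj_within, ss_resid, ss_resid),
    df_num = 1,
    df_den = c(df_between, df_within, df_within),
    stringsAsFactors = FALSE)
  eff$F <- (eff$ss_effect / eff$df_num) / (eff$ss_error / eff$df_den)
  eff$p <- stats::pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$partial_eta_sq <- eff$ss_effect / (eff$ss_effect + eff$ss_error)
  class(eff) <- c("mixed_anova", "data.frame")
  eff
}

#' @export
print.mixed_anova <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-11s F(%d,%d) = %.3f, p = %.3f, partial eta^2 = %.3f\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$p[i],
                x$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test on SRT distributions
#'
#' Computes the maximum gap D between the two empirical cumulative
#' distributions, the scaled statistic `K = D * sqrt(n m / (n + m))`, and
#' the asymptotic p-value from the Kolmogorov distribution
#' `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 K^2)`.
#'
#' @param x,y Numeric samples.
#' @return A list of class `ks_result`: `D`, `K`, `p`, `n`, `m`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both samples must be nonempty")
  pts <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pts)
  fy <- stats::ecdf(y)(pts)
  D <- max(abs(fx - fy))
  K <- D * sqrt(n * m / (n + m))
  p <- kolmogorov_sf_(K)
  structure(list(D = D, K = K, p = p, n = n, m = m), class = "ks_result")
}

# asymptotic Kolmogorov survival function
kolmogorov_sf_ <- function(k) {
  if (k < 1e-8) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * k^2))
  min(max(p, 0), 1)
}

#' Two-tailed Pearson correlation
#'
#' Pearson r with the two-tailed p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return A list of class `pearson_result`: `r`, `df`, `p`, `n`. With
#'   zero variance in either input, `r` and `p` are `NA` and `reason`
#'   explains why.
#' @export
pearson_two_tailed <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, df = n - 2, p = NA_real_, n = n,
                          reason = "zero variance"),
                     class = "pearson_result"))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  structure(list(r = r, df = df, p = p, n = n, reason = NULL),
            class = "pearson_result")
}

#' Shapiro-Wilk normality annotation
#'
#' Thin wrapper around [stats::shapiro.test()] used to annotate report
#' variables; out-of-range or degenerate samples yield a reason code
#' instead of an error.
#'
#' @param values Numeric sample.
#' @return A list: `W`, `p`, `n`, and `reason` (`NULL` when the test ran).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    return(list(W = NA_real_, p = NA_real_, n = n,
                reason = "sample size outside 3..5000"))
  }
  if (stats::sd(values) == 0) {
    return(list(W = NA_real_, p = NA_real_, n = n,
                reason = "zero variance"))
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, n = n, reason = NULL)
}

#' Run the full group-statistics battery on a subject-metrics table
#'
#' For each per-condition measure: a 2x2 mixed-design ANOVA
#' (group x task). Plus the anticipatory-vs-direction-error Pearson
#' correlation within each group (anti condition), and Shapiro-Wilk
#' annotations of each measure. No multiple-comparison correction is
#' applied across measures, and the KS comparison of pooled SRT
#' distributions is available via [ks_two_sample()] on scored trials.
#'
#' @param metrics Subject-metrics table from [summarize_cohort()].
#' @param measures Per-condition measures to test.
#' @return A list of class `group_stats`: `anova` (named list of
#'   `mixed_anova` tables), `correlations`, `normality`.
#' @export
group_statistics <- function(metrics,
                             measures = c("mean_srt", "cv_srt",
                                          "pct_direction_error",
                                          "pct_error_express",
                                          "pct_error_regular",
                                          "pct_anticipatory")) {
  long <- metrics_long(metrics, measures)
  anovas <- lapply(measures, function(m) mixed_anova_2x2(long, m))
  names(anovas) <- measures

  cors <- lapply(split(metrics, metrics$group), function(g) {
    if (nrow(g) >= 3 &&
        all(c("pct_anticipatory_anti", "pct_direction_error_anti") %in%
              names(g))) {
      tryCatch(pearson_two_tailed(g$pct_anticipatory_anti,
                                  g$pct_direction_error_anti),
               error = function(e) NULL)
    } else NULL
  })

  norm <- lapply(measures, function(m) {
    list(pro = normality_check(metrics[[paste0(m, "_pro")]]),
         anti = normality_check(metrics[[paste0(m, "_anti")]]))
  })
  names(norm) <- measures

  structure(list(anova = anovas, correlations = cors, normality = norm),
            class = "group_stats")
}
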