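# Group statistics: mixed ANOVA vs an independent least-squares oracle,
# KS against a brute-force ECDF scan, Pearson p against quadrature.

toy_long <- function(seed = 1, n_per_group = 4, effect = 0) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(2 * n_per_group))
  grp <- rep(c("a", "b"), each = n_per_group)
  d <- expand.grid(subject_id = subj, task = c("pro", "anti"),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject_id, subj)]
  d$y <- rnorm(nrow(d), sd = 1) +
    ifelse(d$group == "b" & d$task == "anti", effect, 0)
  d
}

test_that("mixed ANOVA reproduces aov's stratified decomposition", {
  for (seed in 1:4) {
    d <- toy_long(seed, n_per_group = 4, effect = seed / 2)
    ours <- mixed_anova_2x2(d, "y")
    fit <- summary(stats::aov(y ~ group * task + Error(subject_id/task),
                              data = d))
    btw <- fit[["Error: subject_id"]][[1]]
    wth <- fit[["Error: subject_id:task"]][[1]]
    expect_equal(ours$F[ours$effect == "group"], btw["group", "F value"],
                 tolerance = 1e-10)
    expect_equal(ours$F[ours$effect == "task"], wth["task", "F value"],
                 tolerance = 1e-10)
    expect_equal(ours$F[ours$effect == "group:task"],
                 wth["group:task", "F value"], tolerance = 1e-10)
    expect_equal(ours$p[ours$effect == "group"], btw["group", "Pr(>F)"],
                 tolerance = 1e-10)
    # partial eta^2 from the same SS as the oracle table
    expect_equal(ours$partial_eta_sq[ours$effect == "task"],
                 wth["task", "Sum Sq"] /
                   (wth["task", "Sum Sq"] + wth["Residuals", "Sum Sq"]),
                 tolerance = 1e-10)
  }
})

test_that("degrees of freedom follow the 2x2 mixed design", {
  d <- toy_long(5, n_per_group = 23)
  ours <- mixed_anova_2x2(d, "y")
  expect_equal(ours$df_den, rep(44, 3))
  expect_equal(ours$df_num, rep(1, 3))
})

test_that("constant response is degenerate, not a crash", {
  d <- toy_long(1)
  d$y <- 5
  ours <- mixed_anova_2x2(d, "y")
  expect_true(all(is.nan(ours$F)))
})

test_that("incomplete subjects are dropped with a message", {
  d <- toy_long(2, n_per_group = 4)
  d <- d[!(d$subject_id == "s01" & d$task == "anti"), ]
  expect_message(ours <- mixed_anova_2x2(d, "y"), "s01")
  expect_equal(ours$df_den[1], 5)   # 7 subjects - 2
})

test_that("ANOVA is invariant to row order", {
  d <- toy_long(3, effect = 1)
  a <- mixed_anova_2x2(d, "y")
  b <- mixed_anova_2x2(d[sample(nrow(d)), ], "y")
  expect_equal(a$F, b$F)
})

test_that("interaction injected at the generator level is detected", {
  profs <- list(control = control_profile(direction_error_prob_regular = 0.15),
                patient = patient_profile(direction_error_prob_regular = 0.45,
                                          direction_error_prob_pro = 0.02))
  hits <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(23, group_profiles = profs,
                          paradigm = small_paradigm(trials_per_block = 120),
                          seed = 1000 + r, trace = FALSE)
    scored <- lapply(co$sessions, function(s) score_from_truth(s$truth))
    m <- summarize_cohort(scored, co$metadata)
    a <- mixed_anova_2x2(metrics_long(m), "pct_direction_error")
    hits <- hits + (a$p[a$effect == "group:task"] < 0.05)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("KS statistic matches a brute-force ECDF scan", {
  set.seed(10)
  for (r in 1:10) {
    x <- rnorm(50); y <- rnorm(50, mean = r / 10)
    res <- ks_two_sample(x, y)
    pts <- c(x, y)
    D_ref <- max(vapply(pts, function(p)
      abs(mean(x <= p) - mean(y <= p)), numeric(1)))
    expect_equal(res$D, D_ref, tolerance = 1e-12)
    expect_equal(res$D, unname(stats::ks.test(x, y)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("KS edge cases: identical samples D = 0, disjoint supports D = 1", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$D, 0)
  res <- ks_two_sample(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$D, 1)
  expect_equal(res$K, 1 * sqrt(9 / 6))
})

test_that("K reduces to D sqrt(n/2) for equal sample sizes", {
  set.seed(11)
  x <- rnorm(40); y <- rnorm(40)
  res <- ks_two_sample(x, y)
  expect_equal(res$K, res$D * sqrt(40 / 2))
})

test_that("asymptotic KS p matches the Kolmogorov series at reported K", {
  # value in the regime the scaled statistic K ~ 2 occupies
  p <- antisaccade:::kolmogorov_sf_(2.008)
  ref <- 2 * sum((-1)^(0:99) * exp(-2 * ((1:100)^2) * 2.008^2))
  expect_equal(p, ref)
  expect_lt(p, 0.01)
  expect_equal(antisaccade:::kolmogorov_sf_(0), 1)
})

test_that("Pearson r and two-tailed p match oracles", {
  set.seed(12)
  x <- rnorm(23); y <- x + rnorm(23)
  res <- pearson_two_tailed(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$df, 21)
  # quadrature oracle: two-tailed tail mass of the t density
  tval <- res$r * sqrt(res$df / (1 - res$r^2))
  dens <- function(u) dt(u, res$df)
  p_ref <- 2 * stats::integrate(dens, abs(tval), Inf,
                                rel.tol = 1e-12)$value
  expect_equal(res$p, p_ref, tolerance = 1e-6)

  expect_equal(pearson_two_tailed(x, x)$r, 1)
  y0 <- c(1, -1, 1, -1); x0 <- c(1, 1, -1, -1)  # orthogonal by construction
  expect_equal(pearson_two_tailed(x0, y0)$r, 0)
  expect_equal(pearson_two_tailed(x0, y0)$p, 1)
})

test_that("Pearson handles degenerate input with a reason code", {
  res <- pearson_two_tailed(rep(1, 10), rnorm(10))
  expect_true(is.na(res$r))
  expect_equal(res$reason, "zero variance")
  expect_error(pearson_two_tailed(1:2, 1:2), "at least 3")
})

test_that("Shapiro-Wilk wrapper is calibrated on normal and skewed samples", {
  set.seed(13)
  norm_p <- vapply(1:60, function(i) normality_check(rnorm(50))$p, numeric(1))
  expect_gte(mean(norm_p > 0.05), 0.9)
  exp_p <- vapply(1:60, function(i) normality_check(rexp(200))$p, numeric(1))
  expect_gte(mean(exp_p < 0.05), 0.9)
  expect_equal(normality_check(rep(2, 10))$reason, "zero variance")
  expect_equal(normality_check(rnorm(2))$reason,
               "sample size outside 3..5000")
})

test_that("group_statistics runs the full battery on a small cohort", {
  co <- generate_cohort(6, paradigm = small_paradigm(trials_per_block = 60),
                        seed = 50, trace = FALSE)
  scored <- lapply(co$sessions, function(s) score_from_truth(s$truth))
  m <- summarize_cohort(scored, co$metadata)
  gs <- group_statistics(m)
  expect_named(gs$anova, c("mean_srt", "cv_srt", "pct_direction_error",
                           "pct_error_express", "pct_error_regular",
                           "pct_anticipatory"))
  expect_s3_class(gs$anova$mean_srt, "mixed_anova")
  expect_length(gs$correlations, 2)
})
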