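test_that("exact signed-rank V and p match full sign enumeration", {
  set.seed(31)
  for (n in c(5, 8, 12)) {
    for (rep in 1:5) {
      x <- round(stats::rnorm(n, 0.2), 3)
      y <- round(stats::rnorm(n), 3)
      if (any(x == y) || any(duplicated(abs(x - y)))) next
      got <- wilcoxon_signed_exact(x, y)
      oracle <- enumerate_signed_rank(x - y)
      expect_equal(got$statistic, oracle$v)
      expect_equal(got$p_value, oracle$p_two_sided)
      expect_true(got$exact)
      # and agrees with the stats:: implementation
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value)
    }
  }
})

test_that("one-sided direction anchors: all-positive and all-negative pairs", {
  # n = 12, every difference positive: V = 12*13/2 = 78
  x12 <- 1:12 + (1:12) / 10
  res <- wilcoxon_signed_exact(x12, 1:12)
  expect_equal(res$statistic, 78)
  expect_equal(res$p_value, 2 * (1 / 2^12))
  expect_true(res$exact)
  # every difference negative: V = 0, same two-sided p
  res0 <- wilcoxon_signed_exact(1:12, x12)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, res$p_value)
  # n = 14, all positive: V = 14*15/2 = 105
  res14 <- wilcoxon_signed_exact(1:14 + (1:14) / 10, 1:14)
  expect_equal(res14$statistic, 105)
  expect_equal(res14$p_value, 2 * (1 / 2^14))
})

test_that("zero differences are dropped and ties fall back to the normal approximation", {
  res <- wilcoxon_signed_exact(c(1, 2, 3, 5, 7), c(1, 1, 1, 1, 1))
  expect_equal(res$n_zero_dropped, 1L)
  expect_equal(res$n_used, 4L)
  expect_equal(res$statistic, 10)  # all remaining positive: 4*5/2
  all_zero <- wilcoxon_signed_exact(c(1, 2), c(1, 2))
  expect_true(is.na(all_zero$p_value))
  tied <- wilcoxon_signed_exact(c(2, 3, 4, 5), c(1, 2, 3, 1))
  expect_false(tied$exact)
  ref <- suppressWarnings(stats::wilcox.test(c(2, 3, 4, 5), c(1, 2, 3, 1),
                                             paired = TRUE, exact = FALSE,
                                             correct = FALSE))
  expect_equal(tied$p_value, ref$p.value)
})

test_that("Shapiro-Wilk check flags skew and rejects degenerate input", {
  set.seed(41)
  expect_gt(shapiro_check(stats::rnorm(500))$p_value, 0.001)
  skewed <- stats::rlnorm(500, 0, 1.5)
  expect_lt(shapiro_check(skewed)$p_value, 1e-6)
  expect_error(shapiro_check(c(1, 1, 1, 1)), "constant")
  expect_error(shapiro_check(c(1, 2)), "3")
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(51)
  p <- stats::runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj[order(p)]))  # order-preserving
  expect_true(all(adj <= 1))
  # an all-equal vector is a fixed point of the step-up rule
  expect_equal(bh_adjust(rep(0.04, 6)), rep(0.04, 6))
})

test_that("the on/off battery detects strong isochrony with maximal V", {
  sim <- simulate_colony(
    simulation_config(sigma_vocal = 0.04, sigma_motoric = 0.04,
                      p_sir_insertion = 0, displays_per_individual_mean = 8),
    seed = 7
  )
  rt <- interval_ratios_table(sequence_intervals(sim$observations),
                              rhythm_scheme())
  fl <- apply_inclusion_filters(rt)
  rt <- rt[rt$individual_id %in% fl$overall, ]
  prof <- density_profile(rt, rhythm_scheme())
  bat <- on_off_battery(prof, rhythm_scheme())
  n_ind <- length(unique(prof$individual_id))
  iso_row <- bat[bat$comparison == "1:1 on vs off", ]
  expect_equal(iso_row$statistic, n_ind * (n_ind + 1) / 2)
  expect_lt(iso_row$p_adjusted, 0.05)
  iso_all <- bat[bat$comparison == "isochrony vs off-isochrony", ]
  expect_lt(iso_all$p_adjusted, 0.05)
  # comparisons with no non-zero differences are reported as non-tests (NA)
  expect_true(all(bat$p_adjusted >= bat$p_value, na.rm = TRUE))
  expect_error(on_off_battery(prof[prof$individual_id ==
                                     prof$individual_id[[1]], ]),
               "2 individuals")
})

test_that("LMM recovers a known mode effect on CV and degenerates to OLS", {
  # known effect: vocal sequences noisier than motoric by construction
  sim <- simulate_colony(
    simulation_config(sigma_vocal = 0.25, sigma_motoric = 0.08,
                      displays_per_individual_mean = 8,
                      p_sir_insertion = 0),
    seed = 13
  )
  st <- sequence_stats(sequence_intervals(sim$observations))
  fit <- fit_cv_lmm(st)
  expect_s3_class(fit, "mixed_model_result")
  mode_row <- fit$terms[fit$terms$term == "modevocal", ]
  # truth: CV of a lognormal is sqrt(exp(sigma^2)-1); directed displays have
  # 1.6x sigma and the additive model averages the two context strata, so the
  # mode coefficient targets the context-weighted CV gap
  cv_of <- function(s) sqrt(exp(s^2) - 1)
  truth_gap <- 0.6 * (cv_of(0.25) - cv_of(0.08)) +
    0.4 * (cv_of(0.25 * 1.6) - cv_of(0.08 * 1.6))
  expect_gt(mode_row$estimate, 0)
  expect_lt(abs(mode_row$estimate - truth_gap), 0.08)
  expect_lt(mode_row$p_value, 0.01)
  expect_gt(mode_row$statistic, 0)
  expect_true(all(fit$varcorr$variance >= 0))

  # zero random-effect variance: fixed effects equal ordinary least squares
  set.seed(61)
  design <- expand.grid(mode = c("vocal", "motoric"),
                        context = c("directed", "undirected"),
                        stringsAsFactors = FALSE)
  toy <- tibble::tibble(
    individual_id = rep(sprintf("I%02d", 1:12), each = 4),
    display_id = sprintf("D%03d", 1:48),
    sequence_id = sprintf("S%03d", 1:48),
    mode = rep(design$mode, 12),
    context = rep(design$context, 12),
    zoo = rep(c("A", "B"), each = 24),
    group = "g", n_intervals = 5L, mean_ioi_s = 0.5,
    cv_unbiased = stats::rnorm(48, 0.3, 0.05)  # no individual structure
  )
  fit0 <- suppressMessages(fit_cv_lmm(toy))
  ols <- stats::lm(cv_unbiased ~ zoo + mode + context, data = toy)
  expect_true(fit0$singular)  # flagged, not hidden
  expect_equal(fit0$terms$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("GLMM recovers the directedness effect on isochrony rate", {
  sim <- simulate_colony(
    simulation_config(displays_per_individual_mean = 10), seed = 17
  )
  rt <- interval_ratios_table(sequence_intervals(sim$observations),
                              rhythm_scheme())
  fit <- fit_isochrony_glmm(rt)
  und <- fit$terms[fit$terms$term == "contextundirected", ]
  expect_gt(und$estimate, 0)  # undirected more isochronous (smaller jitter)
  expect_lt(und$p_value, 0.05)
  mode_row <- fit$terms[fit$terms$term == "modevocal", ]
  expect_lt(mode_row$estimate, 0)  # vocal less isochronous than motoric
  expect_equal(unique(fit$terms$statistic_name), "Z")
  expect_equal(sort(fit$varcorr$group),
               sort(c("individual_id", "display_id")))
})

test_that("AIC screening keeps real covariates and rejects pure noise", {
  sim <- simulate_colony(
    simulation_config(displays_per_individual_mean = 8), seed = 19
  )
  rt <- interval_ratios_table(sequence_intervals(sim$observations),
                              rhythm_scheme())
  set.seed(71)
  rt$noise <- sample(c("u", "v"), nrow(rt), replace = TRUE)
  base <- fit_isochrony_glmm(rt, fixed = c("zoo", "mode"))
  with_ctx <- fit_isochrony_glmm(rt, fixed = c("zoo", "mode", "context"))
  with_noise <- fit_isochrony_glmm(rt, fixed = c("zoo", "mode", "noise"))
  cmp <- compare_models_aic(list(base = base, context = with_ctx,
                                 noise = with_noise))
  expect_equal(cmp$model[[1]], "context")  # true generative covariate wins
  expect_gt(cmp$aic[cmp$model == "noise"], cmp$aic[cmp$model == "context"])
  # identical specs give identical AIC
  cmp2 <- compare_models_aic(list(a = base, b = base))
  expect_equal(cmp2$aic[[1]], cmp2$aic[[2]])
  # differing rows are rejected
  half <- fit_isochrony_glmm(rt[seq_len(nrow(rt) %/% 2), ],
                             fixed = c("zoo", "mode"))
  expect_error(compare_models_aic(list(base, half)), "differing")
})
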