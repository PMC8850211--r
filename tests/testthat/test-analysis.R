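test_that("pooled ROC matches exhaustive enumeration on small instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed, discrete = seed %% 2 == 0)
    got <- roc_from_vectors(inst$x, inst$y)
    want <- bf_roc(inst$x, inst$y)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("a perfect predictor reaches the (1, 1) operating point", {
  y <- c(rep(TRUE, 5), rep(FALSE, 8))
  curve <- roc_from_vectors(as.numeric(y), y)
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 1))
  expect_equal(auroc(curve), 1)
})

test_that("ROC is undefined without both classes", {
  expect_error(roc_from_vectors(stats::runif(5), rep(TRUE, 5)), "undefined")
  expect_error(roc_from_vectors(stats::runif(5), rep(FALSE, 5)), "undefined")
})

test_that("AUROC equals the pair-ranking probability (ties half-counted)", {
  expect_equal(auroc(roc_from_vectors(rep(0.5, 10),
                                      rep(c(TRUE, FALSE), 5))), 0.5)
  for (seed in 1:60) {
    inst <- random_instance(seed + 500, n_max = 200,
                            discrete = seed %% 2 == 0)
    expect_equal(auroc(roc_from_vectors(inst$x, inst$y)),
                 bf_auroc_pairs(inst$x, inst$y), tolerance = 1e-12)
  }
})

test_that("AUROC of a label-independent predictor is 0.5 on average", {
  aurocs <- vapply(1:200, function(seed) {
    withr::with_seed(seed, {
      x <- stats::runif(60)
      y <- sample(rep(c(TRUE, FALSE), 30))
    })
    auroc(roc_from_vectors(x, y))
  }, numeric(1))
  se <- stats::sd(aurocs) / sqrt(length(aurocs))
  expect_lt(abs(mean(aurocs) - 0.5), 3 * se)
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  inst <- random_instance(42, n_max = 150)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = inst$y, predictor = inst$x,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )))
  expect_equal(auroc(roc_from_vectors(inst$x, inst$y)), want,
               tolerance = 1e-12)
})

test_that("Youden optimum equals brute-force threshold search", {
  for (seed in 1:60) {
    inst <- random_instance(seed + 1000, discrete = seed %% 3 == 0)
    curve <- roc_from_vectors(inst$x, inst$y)
    got <- youden_cutoff(curve)
    want <- bf_youden(inst$x, inst$y)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    # inclusive empirical percentile of the cut-off
    expect_equal(got$percentile, 100 * mean(inst$x <= got$cutoff))
  }
})

test_that("a separable instance yields J = 1 at the separating threshold", {
  x <- c(rep(0.9, 4), rep(0.1, 6))
  y <- x > 0.5
  res <- youden_cutoff(roc_from_vectors(x, y))
  expect_equal(res$youden_j, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
})

test_that("deviant-value masks use a strict cut-off", {
  z <- c(0, 0.15, 0.2, 1)
  expect_equal(deviant_value_mask(z, 0.15), c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(deviant_value_mask(z, 1)))
  expect_true(all(deviant_value_mask(z + 0.01, 0)))
  for (seed in 1:20) {
    withr::with_seed(seed, {
      v <- stats::runif(50); cut <- stats::runif(1)
    })
    expect_equal(deviant_value_mask(v, cut), v > cut)
  }
})

test_that("agreement index is the Jaccard index of the two masks", {
  m <- rep(TRUE, 10)
  expect_equal(agreement_index(m, m)$ai, 1)
  expect_equal(agreement_index(c(m, rep(FALSE, 10)),
                               c(rep(FALSE, 10), m))$ai, 0)
  # A = [0, 10) s, B = [5, 15) s on a 1-s grid -> 5 / 15
  grid <- 0:19
  a <- grid >= 0 & grid < 10
  b <- grid >= 5 & grid < 15
  res <- agreement_index(a, b)
  expect_equal(res$ai, 5 / 15)
  expect_equal(res$seconds_intersection, 5)
  expect_equal(res$seconds_union, 15)

  expect_true(is.na(agreement_index(rep(FALSE, 5), rep(FALSE, 5))$ai))
  expect_error(agreement_index(rep(TRUE, 3), rep(TRUE, 4)), "grid")
})

test_that("agreement index is symmetric, bounded and matches set counting", {
  for (seed in 1:40) {
    withr::with_seed(seed, {
      a <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.3, 0.7))
      b <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.3, 0.7))
    })
    ai <- agreement_index(a, b)$ai
    expect_equal(ai, bf_jaccard(a, b))
    expect_equal(ai, agreement_index(b, a)$ai)
    if (!is.na(ai)) expect_true(ai >= 0 && ai <= 1)
    if (any(a | b)) {
      expect_equal(agreement_index(a, a)$ai, if (any(a)) 1 else NA_real_)
    }
  }
})

test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  tied <- spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(tied$rho, bf_spearman(c(1, 2, 2, 3), c(1, 3, 2, 4)))
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)$rho))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Spearman matches the mid-rank Pearson oracle and cor.test", {
  for (seed in 1:60) {
    withr::with_seed(seed, {
      n <- sample(5:40, 1)
      x <- sample(1:8, n, replace = TRUE)   # heavy ties
      y <- sample(1:8, n, replace = TRUE)
    })
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    got <- spearman_rho(x, y)
    expect_equal(got$rho, bf_spearman(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("per-subject analysis flags undefined correlations and medians match", {
  cohort <- simulate_cohort(n_subjects = 6, config = small_protocol(),
                            seed = 33)
  series <- cohort_series(cohort)
  res <- individual_analysis(series)
  expect_equal(nrow(res), 6)
  # the calmest subject (episode rate 0) should have few or no errors;
  # a constant error-rate series must be flagged undefined
  flat <- make_session(seq(0, 169, by = 1.7) + 0.5,
                       rep("regular", 100), rep(TRUE, 100),
                       rt_ms = stats::rnorm(100, 400, 30))
  flat_series <- session_series(flat, config = small_protocol())
  flat_res <- individual_analysis(flat_series)
  expect_true(is.na(flat_res$rho_rt))
  expect_true(is.na(flat_res$rho_rtv))

  med <- stats::median(res$rho_rtv, na.rm = TRUE)
  expect_equal(med, stats::median(sort(res$rho_rtv[!is.na(res$rho_rtv)])))
})

test_that("meta-correlation recovers identity and vanishes under permutation", {
  errs <- c(0, 2, 5, 9, 14, 30)
  expect_equal(meta_correlation(errs, errs)$rho, 1)
  rhos <- vapply(1:200, function(seed) {
    stat <- withr::with_seed(seed, sample(errs))
    meta_correlation(stat, errs)$rho
  }, numeric(1))
  se <- stats::sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 3 * se)
})

test_that("cohort analysis produces a coherent report object", {
  cohort <- simulate_cohort(n_subjects = 8, config = small_protocol(),
                            seed = 77)
  qc <- analyze_cohort(cohort)
  g <- glance(qc)
  expect_equal(g$n_subjects, 8)
  expect_true(g$auroc_rt >= 0 && g$auroc_rt <= 1)
  expect_true(g$auroc_rtv >= 0 && g$auroc_rtv <= 1)
  expect_true(g$rtv_cutoff_percentile >= 0 && g$rtv_cutoff_percentile <= 100)
  td <- tidy(qc)
  expect_equal(nrow(td), 8)
  expect_true(all(c("ai", "total_errors", "rho_rt", "rho_rtv") %in% names(td)))
  # the fixed cut-off path applies the supplied threshold verbatim
  qc_fixed <- analyze_cohort(cohort, cutoff_mode = "fixed",
                             fixed_cutoff = 0.15)
  expect_equal(qc_fixed$rtv_cutoff_used, 0.15)
})

test_that("plot constructors return ggplot objects", {
  cohort <- simulate_cohort(n_subjects = 2, config = small_protocol(),
                            seed = 5)
  series <- cohort_series(cohort)
  qc <- analyze_cohort(cohort)
  expect_s3_class(ggplot2::autoplot(qc$roc_rtv), "ggplot")
  expect_s3_class(plot_session_series(series), "ggplot")
})
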