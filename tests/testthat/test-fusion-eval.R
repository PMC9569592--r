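# Bootstrap fusion evaluation: normalization, iterations, grid, comparisons.

small_fixture <- function(seed = 71, n = 60, g = 8, effect = 1.2) {
  cfg <- generator_config(n_samples = n, n_genes = g,
                          n_informative = max(2, g %/% 2),
                          effect_size = effect, seed = seed)
  ds <- generate_dataset(cfg, withr::local_tempdir(.local_envir = parent.frame()))
  list(x = ds$expression, risk = attr(ds$clinical, "clinical_score"),
       y = ds$clinical$label)
}

test_that("z-score normalization is fitted on train and applied to test", {
  z <- zscore_normalize(cbind(a = c(1, 2, 3)), cbind(a = c(2, 5)))
  expect_equal(as.vector(z$train), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(as.vector(z$test), c(0, 3), tolerance = 1e-12)

  zc <- zscore_normalize(cbind(a = rep(4, 5)), cbind(a = c(1, 9)))
  expect_true(all(zc$train == 0) && all(zc$test == 0))

  expect_error(zscore_normalize(cbind(a = 1:3), cbind(b = 1:2)), "absent")
})

test_that("out-of-bag fraction matches the (1 - 1/n)^n limit", {
  n <- 200
  y <- factor(rep(c("benign", "malignant"), c(120, 80)))
  fracs <- vapply(1:1000, function(b) {
    length(fusionlab:::draw_inbag(y, b, seed = 5)$oob) / n
  }, numeric(1))
  expect_lt(abs(mean(fracs) - (1 - 1 / n)^n), 0.01)
})

test_that("late fusion records n_features + 1 features including the risk", {
  fx <- small_fixture()
  rec <- run_iteration(fx$x, fx$risk, fx$y, strategy = "late",
                       method = "wilcoxon", n_features = 3, iteration = 2,
                       seed = 9)
  sel <- rec$selected[[1]]
  expect_length(sel, 4)
  expect_true("malignancy_risk" %in% sel)
  expect_true(rec$accuracy >= 0 && rec$accuracy <= 1)
  expect_gt(rec$n_oob, 0)
})

test_that("no fusion with all features selects the full gene panel", {
  fx <- small_fixture()
  for (m in c("wilcoxon", "relieff")) {
    rec <- run_iteration(fx$x, fx$risk, fx$y, strategy = "none", method = m,
                         n_features = 8, seed = 9, k_neighbors = 5)
    expect_setequal(rec$selected[[1]], paste0("gene_00", 1:8))
  }
})

test_that("clinical_only uses the risk feature alone", {
  fx <- small_fixture()
  rec <- run_iteration(fx$x, fx$risk, fx$y, strategy = "clinical_only",
                       method = "wilcoxon", n_features = 5, seed = 9)
  expect_identical(rec$selected[[1]], "malignancy_risk")
})

test_that("experiment grids are reproducible and share in-bag draws", {
  fx <- small_fixture()
  ex1 <- run_experiment(fx$x, fx$risk, fx$y, strategies = c("late", "none"),
                        methods = "wilcoxon", n_features = c(2, 4), B = 10,
                        seed = 13)
  ex2 <- run_experiment(fx$x, fx$risk, fx$y, strategies = c("late", "none"),
                        methods = "wilcoxon", n_features = c(2, 4), B = 10,
                        seed = 13)
  expect_equal(tidy(ex1), tidy(ex2), tolerance = 1e-12)
  # a run with only one strategy sees the same draws, hence same accuracies
  ex3 <- run_experiment(fx$x, fx$risk, fx$y, strategies = "none",
                        methods = "wilcoxon", n_features = 2, B = 10,
                        seed = 13)
  a1 <- ex1$cells$accuracies[[which(ex1$cells$strategy == "none" &
                                      ex1$cells$n_features == 2)]]
  expect_identical(ex3$cells$accuracies[[1]], a1)
})

test_that("early and late fusion coincide at the full feature complement", {
  fx <- small_fixture()
  g <- 8
  ex_early <- run_experiment(fx$x, fx$risk, fx$y, strategies = "early",
                             methods = c("wilcoxon", "relieff"),
                             n_features = g + 1, B = 15, seed = 17,
                             k_neighbors = 5)
  ex_late <- run_experiment(fx$x, fx$risk, fx$y, strategies = "late",
                            methods = c("wilcoxon", "relieff"),
                            n_features = g, B = 15, seed = 17,
                            k_neighbors = 5)
  for (m in c("wilcoxon", "relieff")) {
    acc_e <- ex_early$cells$accuracies[[which(ex_early$cells$method == m)]]
    acc_l <- ex_late$cells$accuracies[[which(ex_late$cells$method == m)]]
    expect_identical(acc_e, acc_l)
  }
})

test_that("stronger models win at larger sizes under strong signal", {
  fx <- small_fixture(seed = 73, n = 80, g = 12, effect = 1.5)
  ex <- run_experiment(fx$x, fx$risk, fx$y, strategies = "none",
                       methods = "wilcoxon", n_features = c(1, 6), B = 25,
                       seed = 19)
  cells <- tidy(ex)
  expect_gte(cells$median_acc[cells$n_features == 6],
             cells$median_acc[cells$n_features == 1])
})

test_that("accuracy summaries are medians with percentile intervals", {
  s <- summarize_accuracy(c(0.8, 0.9, 1.0))
  expect_equal(s$median_acc, 0.9)
  s2 <- summarize_accuracy(rep(0.7, 5))
  expect_equal(c(s2$ci_low, s2$median_acc, s2$ci_high), rep(0.7, 3))
  set.seed(21)
  draws <- runif(4000)
  s3 <- summarize_accuracy(draws)
  expect_lt(abs(s3$ci_low - 0.025), 0.01)
  expect_lt(abs(s3$ci_high - 0.975), 0.01)
  expect_error(summarize_accuracy(0.5), "2 accuracy")
})

test_that("model comparison is a two-sided Mann-Whitney test", {
  expect_equal(compare_models(c(0.8, 0.9, 0.7), c(0.8, 0.9, 0.7)), 1,
               tolerance = 1e-9)
  expect_equal(compare_models(rep(0.9, 4), rep(0.9, 4)), 1)
  expect_equal(compare_models(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
})

test_that("model comparison p-values are calibrated under the null", {
  set.seed(22)
  ps <- vapply(1:1000, function(i) {
    compare_models(rnorm(30), rnorm(30))
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("invalid grids and sizes are rejected", {
  fx <- small_fixture()
  expect_error(run_iteration(fx$x, fx$risk, fx$y, strategy = "none",
                             method = "wilcoxon", n_features = 9),
               "out of range")
  expect_warning(
    ex <- run_experiment(fx$x, fx$risk, fx$y, strategies = "none",
                         methods = "wilcoxon", n_features = c(2, 9), B = 5,
                         seed = 1),
    "dropping"
  )
  expect_equal(nrow(ex$cells), 1)
  expect_error(
    suppressWarnings(run_experiment(fx$x, fx$risk, fx$y, strategies = "none",
                                    methods = "wilcoxon", n_features = 20,
                                    B = 5)),
    "empty"
  )
})

test_that("tidiers and plots expose the grid", {
  fx <- small_fixture()
  ex <- run_experiment(fx$x, fx$risk, fx$y,
                       strategies = c("early", "none", "clinical_only"),
                       methods = "wilcoxon", n_features = c(2, 4), B = 8,
                       seed = 3)
  td <- tidy(ex)
  expect_true(all(c("strategy", "method", "n_features", "median_acc",
                    "ci_low", "ci_high", "kuncheva") %in% names(td)))
  expect_true(all(td$ci_low <= td$median_acc & td$median_acc <= td$ci_high))
  gl <- glance(ex)
  expect_equal(gl$n_cells, nrow(td))
  expect_s3_class(autoplot(ex), "ggplot")
  expect_s3_class(autoplot(stability_curve(ex)), "ggplot")
})
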