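test_that("confusion matrices count, group and percentage correctly", {
  cm <- confusion_matrix(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))
  expect_true(all(cm$counts == diag(5)))
  # grouping collapses 5x5 cells by partition sums
  truth <- c(0, 0, 1, 2, 3, 4, 2, 3)
  pred <- c(0, 1, 1, 3, 2, 4, 0, 4)
  g <- confusion_matrix(truth, pred, grouping = grouping_3class())
  expect_identical(g$counts["hyperglycemia", "hyperglycemia"], 4L)
  expect_identical(g$counts["control", "hypoglycemia"], 1L)
  expect_identical(g$counts["hyperglycemia", "control"], 1L)
  expect_equal(sum(g$counts), length(truth))
  # hand-built percentages
  cm3 <- confusion_matrix(rep(c("a", "b"), c(4, 6)),
                          c("a", "a", "b", "b", rep("b", 5), "a"))
  expect_equal(cm3$percent["a", "a"], 50)
  expect_equal(cm3$percent["b", "b"], round(100 * 5 / 6, 2))
  expect_equal(unname(rowSums(cm3$percent)), c(100, 100), tolerance = 0.02)
  expect_error(confusion_matrix(c(0, 7), c(0, 0), grouping = grouping_3class()),
               "not covered")
  expect_error(confusion_matrix(0:1, 0), "equal length")
})

test_that("class metrics agree with direct confusion arithmetic", {
  set.seed(44)
  truth <- sample(0:4, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.6, truth, sample(0:4, 500, replace = TRUE))
  cm <- confusion_matrix(truth, pred)
  m <- class_metrics(cm)
  raw <- attr(m, "raw")
  for (i in seq_len(5)) {
    k <- as.integer(raw$class[i])
    tp <- sum(pred == k & truth == k)
    fn <- sum(pred != k & truth == k)
    fp <- sum(pred == k & truth != k)
    tn <- sum(pred != k & truth != k)
    expect_equal(raw$sensitivity[i], 100 * tp / (tp + fn), tolerance = 1e-12)
    expect_equal(raw$specificity[i], 100 * tn / (tn + fp), tolerance = 1e-12)
    expect_equal(raw$precision[i], 100 * tp / (tp + fp), tolerance = 1e-12)
    expect_equal(raw$balanced_accuracy[i],
                 (raw$sensitivity[i] + raw$specificity[i]) / 2)
  }
  # an undefined metric is missing, not zero
  cm0 <- confusion_matrix(c(1, 1, 0, 0), c(0, 0, 0, 0))
  m0 <- class_metrics(cm0)
  expect_true(is.na(m0$precision[m0$class == "1"]))
})

test_that("binary reduction pools all decompensation classes", {
  expect_identical(as.character(binary_reduction(c(3, 0, 1))),
                   c("decompensated", "nondecompensated", "decompensated"))
  # true 3 / predicted 2 counts as a correct decompensation call
  cm <- confusion_matrix(binary_reduction(3), binary_reduction(2))
  expect_identical(cm$counts["decompensated", "decompensated"], 1L)
  expect_error(binary_reduction(5), "0..4")
})

test_that("binary reduction can only gain recall over exact-class prediction", {
  fit <- fixture("small_fit", function()
    glyc_ecoc(small_features(), specs = candidate_specs()[c("A", "B", "G", "H", "I")],
              budget = 3, optimize = FALSE, seed = 31))
  truth <- fit$validation$truth
  pred <- fit$validation$pred
  # set-union argument: within each true decompensation category, calling
  # *any* decompensation is at least as frequent as calling the exact class
  for (k in 1:4) {
    in_k <- truth == k
    if (!any(in_k)) next
    expect_gte(mean(pred[in_k] > 0), mean(pred[in_k] == k))
  }
  bin <- confusion_matrix(as.character(binary_reduction(truth)),
                          as.character(binary_reduction(pred)))
  bin_sens <- attr(class_metrics(bin), "raw")$sensitivity[
    rownames(bin$counts) == "decompensated"]
  # and the pooled binary sensitivity equals the truth-weighted union recall
  expect_equal(bin_sens, 100 * mean(pred[truth > 0] > 0))
})

test_that("cross-validation refits per fold and reports mean/SD summaries", {
  cv <- cross_validate(small_features(), k = 3,
                       specs = candidate_specs()[c("A", "B", "G", "H", "I")],
                       budget = 2, seed = 17)
  expect_s3_class(cv, "glyc_cv")
  expect_identical(cv$n_folds_used, 3L)
  expect_identical(sort(unique(cv$folds$fold)), 1:3)
  expect_identical(nrow(cv$summary), 3L)   # control / hypo / hyper
  expect_true(all(is.finite(cv$summary$sensitivity[, "mean"])))
  # a class absent from the data leaves every fold incomplete
  ftr <- mk_features(sprintf("C%03d", 1:60), rep(0:3, 15),
                     data.frame(x = rnorm(60)))
  w <- capture_warnings(expect_error(cross_validate(ftr, k = 3, budget = 1, seed = 1),
                                     "all folds"))
  expect_length(w, 3)
  expect_true(all(grepl("skipped", w)))
})

test_that("horizon summaries reproduce medians, IQRs and missing categories", {
  t0 <- as.POSIXct("2016-05-01", tz = "UTC")
  manifest <- data.frame(
    case_id = sprintf("C%d", 1:4),
    category = c(1L, 1L, 1L, 0L),
    window_start = rep(t0, 4),
    window_end = t0 + c(24, 48, 96, 240) * 3600,
    horizon_hours = c(3, 7, 15, NA), n_rows = c(5L, 5L, 5L, 9L))
  lab <- structure(list(events = NULL, manifest = manifest),
                   class = "glyc_labels")
  hs <- horizon_summary(lab)
  expect_identical(nrow(hs), 2L)           # categories 2-4 absent
  expect_equal(hs$horizon_median_h[hs$category == 1], 7)
  expect_equal(hs$horizon_q1_h[hs$category == 1], 5)
  expect_equal(hs$lookback_median_d[hs$category == 1], 2)
  expect_true(is.na(hs$horizon_median_h[hs$category == 0]))
  # constructed constant pre-event gap is recovered exactly
  labs <- do.call(rbind, lapply(1:6, function(i)
    mk_labs(sprintf("E%d", i), "glucose", c(5.5, 6, 3.1), c(1, 10, 14))))
  coh <- mk_cohort(labs, cases = sprintf("E%d", 1:6), stay_h = 48)
  hs2 <- horizon_summary(label_cohort(coh))
  expect_equal(hs2$horizon_median_h[hs2$category == 1], 4)
})

test_that("importance reports cover each member and pool the union", {
  fit <- fixture("small_fit", function()
    glyc_ecoc(small_features(), specs = candidate_specs()[c("A", "B", "G", "H", "I")],
              budget = 3, optimize = FALSE, seed = 31))
  rep5 <- importance_report(fit, top_n = 10)
  expect_length(rep5$per_model, 5)
  expect_true(all(lengths(rep5$per_model) == 10))
  expect_true(length(rep5$union) >= 10)
  expect_true(all(unlist(lapply(rep5$per_model, names)) %in% rep5$union))
})
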