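test_that("the default model library matches the published class combinations", {
  sp <- candidate_specs()
  expect_identical(names(sp), LETTERS[1:9])
  expect_identical(sp$A$positive_set, 1:4)
  expect_identical(sp$B$positive_set, 1L)
  expect_identical(sp$G$positive_set, c(1L, 4L))
  expect_identical(sp$H$positive_set, 2:4)
  expect_identical(sp$I$positive_set, 3:4)
  expect_error(candidate_specs(extra = list(C = 1)), "duplicate")
  expect_error(binary_spec("X", integer(0)), "non-empty")
  expect_error(binary_spec("X", 0:4), "subset of 1..4")
})

test_that("instance construction weights classes by inverse frequency", {
  ft <- mk_features(sprintf("C%04d", 1:1000),
                    c(rep(1, 100), rep(0, 900)),
                    data.frame(x = rnorm(1000)))
  inst <- make_instances(ft, binary_spec("B", 1))
  expect_identical(sum(inst$y), 100L)
  w_pos <- unique(inst$weights[inst$y == 1])
  w_neg <- unique(inst$weights[inst$y == 0])
  expect_equal(w_pos / w_neg, 9)
  expect_equal(mean(inst$weights), 1)
  # balanced classes: all weights one
  ftb <- mk_features(sprintf("C%04d", 1:100), rep(c(1, 0), 50),
                     data.frame(x = rnorm(100)))
  expect_true(all(make_instances(ftb, binary_spec("B", 1))$weights == 1))
})

test_that("cases decompensating outside the positive set serve as controls", {
  # one case with mild + moderate hyperglycemia, one control case
  ft <- mk_features(c("C1", "C1", "C2", sprintf("D%02d", 1:20)),
                    c(2, 3, 0, rep(c(1, 0), 10)),
                    data.frame(x = 1:23))
  inst <- make_instances(ft, binary_spec("B", 1))
  expect_true("C1" %in% inst$case_id)
  expect_identical(inst$y[inst$case_id == "C1"], 0L)
  # the earliest-category instance represents the control case exactly once
  expect_identical(sum(inst$case_id == "C1"), 1L)
  expect_equal(unname(inst$X[inst$case_id == "C1", "x"][[1]]), 1)
  expect_error(make_instances(ft, binary_spec("Z", 4)), "both classes")
})

test_that("the case split honours the ratio and is reproducible", {
  s <- split_cases(sprintf("C%04d", 1:1000), 0.7, 42)
  expect_identical(length(s$train), 700L)
  expect_identical(length(s$test), 300L)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), sprintf("C%04d", 1:1000))
  expect_identical(split_cases(sprintf("C%04d", 1:1000), 0.7, 42), s)
  s10 <- split_cases(sprintf("C%02d", 1:10), 0.7, 1)
  expect_identical(lengths(s10), c(train = 7L, test = 3L))
  expect_error(split_cases(sprintf("C%04d", 1:100), 1.2, 1), "between 0 and 1")
  expect_error(split_cases(c("a", "b"), 0.7, 1), "at least 10")
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    y <- rbinom(80, 1, 0.4)
    sc <- rnorm(80) + y * runif(1, 0, 2)
    want <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE)))
    expect_equal(dysglyc:::auc_score(sc, y), want, tolerance = 1e-12)
  }
})

test_that("threshold metrics satisfy the informedness identity", {
  set.seed(12)
  y <- rbinom(200, 1, 0.3)
  sc <- runif(200)
  m <- dysglyc:::binary_threshold_metrics(sc, y, 0.5)
  pred <- as.integer(sc >= 0.5)
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  expect_equal(m[["sensitivity"]], tp / (tp + fn))
  expect_equal(m[["specificity"]], tn / (tn + fp))
  expect_equal(m[["precision"]], tp / (tp + fp))
  expect_equal(m[["informedness"]], m[["sensitivity"]] + m[["specificity"]] - 1)
})

test_that("degenerate searches and inputs are handled", {
  set.seed(77)
  n <- 120
  ft <- mk_features(sprintf("C%03d", 1:n), rbinom(n, 1, 0.5),
                    data.frame(x = rnorm(n), z = rnorm(n)))
  ft$x <- ft$x + 2 * ft$category
  inst <- make_instances(ft, binary_spec("B", 1))
  m <- train_binary(binary_spec("B", 1), inst, budget = 1, seed = 3)
  expect_s3_class(m, "trained_binary")
  expect_true(is.finite(m$metrics[["auc"]]))
  expect_error(train_binary(binary_spec("B", 1),
                            list(X = inst$X, y = rep(1L, nrow(inst$X)),
                                 weights = rep(1, nrow(inst$X)),
                                 case_id = inst$case_id),
                            budget = 1, seed = 1), "single-class")
  expect_error(train_binary(binary_spec("B", 1), inst, budget = 0, seed = 1),
               "budget")
})

test_that("inverse-frequency weighting makes training robust to majority duplication", {
  set.seed(99)
  n <- 400
  cats <- rep(c(1, 0, 0, 0), n / 4)
  ft <- mk_features(sprintf("C%03d", 1:n), cats,
                    data.frame(x = rnorm(n) + 1.5 * (cats == 1),
                               z = rnorm(n)))
  inst <- make_instances(ft, binary_spec("B", 1))
  # duplicate every control instance in place (same cases, so the case-level
  # split is unchanged) and recompute inverse-frequency weights
  dup <- which(inst$y == 0)
  idx <- c(seq_along(inst$y), dup)
  inst2 <- list(X = inst$X[idx, ], y = inst$y[idx],
                case_id = inst$case_id[idx])
  freq <- table(inst2$y)[as.character(inst2$y)]
  inst2$weights <- as.numeric(1 / freq); inst2$weights <- inst2$weights / mean(inst2$weights)
  m1 <- train_binary(binary_spec("B", 1), inst, budget = 1, seed = 5)
  m2 <- train_binary(binary_spec("B", 1), inst2, budget = 1, seed = 5)
  expect_equal(m1$metrics[["auc"]], m2$metrics[["auc"]], tolerance = 0.08)
})

test_that("importance is gain-based, non-negative and ignores constant features", {
  set.seed(15)
  n <- 300
  cats <- rbinom(n, 1, 0.4)
  ft <- mk_features(sprintf("C%03d", 1:n), cats,
                    data.frame(x = rnorm(n) + 2 * cats, z = rnorm(n),
                               const = rep(1, n)))
  inst <- make_instances(ft, binary_spec("B", 1))
  m <- train_binary(binary_spec("B", 1), inst, budget = 3, seed = 2)
  imp <- importance(m)
  expect_true(all(imp >= 0))
  expect_gt(sum(imp), 0)
  expect_identical(imp[["const"]], 0)
  expect_identical(names(imp)[1], "x")
  expect_error(importance(list()), "trained binary")
})

test_that("the injected signal analytes dominate variable importance", {
  imp <- importance(strong_model())
  top15 <- names(imp)[1:15]
  sig <- c("glucose", "lactate", "crp", "wbc", "cortisol", "triglycerides")
  hit <- vapply(sig, function(a) any(startsWith(top15, paste0(a, "__"))),
                logical(1))
  expect_gte(sum(hit), 5)
})
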