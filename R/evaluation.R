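#' Grouping map collapsing the three hyperglycemia grades
#'
#' @return named character vector mapping classes 0-4 to
#'   control/hypoglycemia/hyperglycemia
#' @export
grouping_3class <- function() {
  c("0" = "control", "1" = "hypoglycemia", "2" = "hyperglycemia",
    "3" = "hyperglycemia", "4" = "hyperglycemia")
}

#' Confusion matrix with row-relative percentages
#'
#' @param truth,pred equal-length label vectors (classes 0-4, or already
#'   grouped labels)
#' @param grouping optional named map applied to both vectors first, e.g.
#'   [grouping_3class()]
#' @return list of class `glyc_confusion` with integer `counts` and
#'   row-relative `percent` matrices (rows = true class)
#' @export
confusion_matrix <- function(truth, pred, grouping = NULL) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  if (!is.null(grouping)) {
    unknown <- setdiff(unique(c(truth, pred)), names(grouping))
    if (length(unknown))
      stop("labels not covered by the grouping map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    lev <- unique(unname(grouping))
    truth <- factor(unname(grouping[as.character(truth)]), levels = lev)
    pred <- factor(unname(grouping[as.character(pred)]), levels = lev)
  } else {
    lev <- sort(unique(c(as.character(truth), as.character(pred))))
    truth <- factor(as.character(truth), levels = lev)
    pred <- factor(as.character(pred), levels = lev)
  }
  counts <- table(true = truth, predicted = pred)
  pct <- 100 * prop.table(counts + 0, margin = 1)
  structure(list(counts = unclass(counts), percent = round_half_up(pct, 2)),
            class = "glyc_confusion")
}

#' @export
print.glyc_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true class):\n")
  print(x$counts)
  cat("\nRow-relative %:\n")
  print(x$percent)
  invisible(x)
}

#' One-vs-rest class metrics from a confusion matrix
#'
#' For every class: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)` and balanced accuracy `(sens+spec)/2`, reported as
#' percentages. A metric with zero denominator is missing.
#'
#' @param cm a `glyc_confusion`
#' @param digits decimals for display rounding (half-up); raw values are in
#'   the `raw` attribute
#' @return data.frame, one row per class
#' @export
class_metrics <- function(cm, digits = 2) {
  stopifnot(inherits(cm, "glyc_confusion"))
  M <- cm$counts
  n <- sum(M)
  out <- data.frame(class = rownames(M),
                    sensitivity = NA_real_, specificity = NA_real_,
                    precision = NA_real_, balanced_accuracy = NA_real_,
                    stringsAsFactors = FALSE)
  raw <- out
  for (i in seq_len(nrow(M))) {
    tp <- M[i, i]; fn <- sum(M[i, ]) - tp
    fp <- sum(M[, i]) - tp; tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    bacc <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
    raw[i, 2:5] <- c(sens, spec, prec, bacc)
    out[i, 2:5] <- round_half_up(c(sens, spec, prec, bacc), digits)
  }
  attr(out, "raw") <- raw
  out
}

#' Reduce multiclass labels to the binary decompensation question
#'
#' Class 0 maps to `"nondecompensated"`, classes 1-4 to `"decompensated"`.
#'
#' @param labels integer classes 0-4
#' @return factor with the two reduced levels
#' @export
binary_reduction <- function(labels) {
  if (!all(labels %in% 0:4)) stop("labels must be in 0..4", call. = FALSE)
  factor(ifelse(labels == 0, "nondecompensated", "decompensated"),
         levels = c("decompensated", "nondecompensated"))
}

#' k-fold cross-validated pipeline evaluation
#'
#' Partitions the cases into k folds, refits the full
#' train / select / decode pipeline on each training complement and decodes
#' the held-out fold. Folds whose held-out truth does not contain all five
#' classes are skipped with a warning. Metrics are computed per fold on the
#' 3-class grouping and summarized as mean (SD).
#'
#' @param features a `glyc_features` table
#' @param k number of folds (>= 2)
#' @param specs,budget,optimize,ga passed to [glyc_ecoc()]
#' @param seed integer seed (fold assignment and refits)
#' @return list of class `glyc_cv`: `folds` (long data.frame of per-fold
#'   per-class metrics), `summary` (mean and SD per metric and class)
#' @export
cross_validate <- function(features, k = 5, specs = candidate_specs(),
                           budget = 10, optimize = FALSE, ga = ga_control(),
                           seed = 1L) {
  stopifnot(inherits(features, "glyc_features"))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  cases <- unique(features$case_id)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k), length(cases))))
  names(fold_of) <- cases
  res <- list()
  for (f in seq_len(k)) {
    test_rows <- fold_of[features$case_id] == f
    truth <- features$category[test_rows]
    if (length(unique(truth)) < 5) {
      warning(sprintf("fold %d skipped: not all classes present", f))
      next
    }
    fit <- glyc_ecoc(subset_features(features, !test_rows), specs = specs,
                     budget = budget, optimize = optimize, ga = ga,
                     seed = child_seed(seed, f))
    pred <- predict(fit, subset_features(features, test_rows))
    cm <- confusion_matrix(truth, pred, grouping = grouping_3class())
    m <- class_metrics(cm)
    m$fold <- f
    res[[length(res) + 1]] <- m
  }
  if (!length(res)) stop("all folds were skipped", call. = FALSE)
  folds <- do.call(rbind, res)
  agg <- stats::aggregate(folds[c("sensitivity", "specificity", "precision",
                                  "balanced_accuracy")],
                          by = list(class = folds$class),
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        sd = sd(x, na.rm = TRUE)))
  structure(list(folds = folds, summary = agg, k = k,
                 n_folds_used = length(res)),
            class = "glyc_cv")
}

#' @export
print.glyc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d folds evaluated)\n", x$k,
              x$n_folds_used))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s sens %.1f (%.1f)  spec %.1f (%.1f)  prec %.1f (%.1f)  bal.acc %.1f (%.1f)\n",
                s$class[i],
                s$sensitivity[i, "mean"], s$sensitivity[i, "sd"],
                s$specificity[i, "mean"], s$specificity[i, "sd"],
                s$precision[i, "mean"], s$precision[i, "sd"],
                s$balanced_accuracy[i, "mean"], s$balanced_accuracy[i, "sd"]))
  }
  invisible(x)
}

#' Prediction-horizon and look-back summaries per category
#'
#' @param labels a `glyc_labels`
#' @return data.frame per category: number of instances, median and IQR of
#'   the look-back window length (days) and, for event categories, of the
#'   prediction horizon (hours)
#' @export
horizon_summary <- function(labels) {
  stopifnot(inherits(labels, "glyc_labels"))
  m <- labels$manifest
  out <- lapply(0:4, function(k) {
    rows <- m[m$category == k, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    lb_days <- hours_between(rows$window_start, rows$window_end) / 24
    qs <- quantile(lb_days, c(0.25, 0.5, 0.75), names = FALSE)
    hz <- rows$horizon_hours
    hq <- if (k == 0) rep(NA_real_, 3)
          else quantile(hz, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    data.frame(category = k, n = nrow(rows),
               lookback_median_d = qs[2], lookback_q1_d = qs[1],
               lookback_q3_d = qs[3],
               horizon_median_h = hq[2], horizon_q1_h = hq[1],
               horizon_q3_h = hq[3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Population-level variable importance of an ensemble
#'
#' Top-k gain-based importances per member model plus the union of the
#' top-k sets across members.
#'
#' @param fit a fitted `glyc_ecoc`
#' @param top_n variables per member (default 10)
#' @return list with `per_model` (named list of sorted importance vectors)
#'   and `union` (character vector of the union set)
#' @export
importance_report <- function(fit, top_n = 10) {
  stopifnot(inherits(fit, "glyc_ecoc"))
  per <- lapply(fit$models, function(m) head(importance(m), top_n))
  union_set <- unique(unlist(lapply(per, names)))
  list(per_model = per, union = union_set)
}
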