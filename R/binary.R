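#' Binary model specification
#'
#' A binary model distinguishes a positive set of decompensation categories
#' from all other cases (controls).
#'
#' @param label short model label ("A".."I" for the default library)
#' @param positive_set subset of `1:4`
#' @return object of class `binary_spec`
#' @export
binary_spec <- function(label, positive_set) {
  positive_set <- sort(unique(as.integer(positive_set)))
  if (length(positive_set) == 0 || !all(positive_set %in% 1:4))
    stop("positive_set must be a non-empty subset of 1..4", call. = FALSE)
  structure(list(label = label, positive_set = positive_set),
            class = "binary_spec")
}

#' @export
print.binary_spec <- function(x, ...) {
  cat(sprintf("binary model %s: positive classes {%s}\n", x$label,
              paste(x$positive_set, collapse = ",")))
  invisible(x)
}

#' The default library of candidate binary model types
#'
#' Nine clinically motivated class combinations, A-I. A (any decompensation),
#' B (hypoglycemia only), G (hypoglycemia + severe hyperglycemia), H (all
#' hyperglycemia) and I (moderate + severe hyperglycemia) form the published
#' best ensemble; C-F are single-category and mixed fillers for the
#' composition search and are configurable.
#'
#' @param extra optional named list `label -> positive set` replacing C-F
#' @return list of [binary_spec()]s
#' @export
candidate_specs <- function(extra = NULL) {
  base <- list(A = 1:4, B = 1, C = 2, D = 3, E = 4, F = c(1, 3, 4),
               G = c(1, 4), H = 2:4, I = 3:4)
  if (!is.null(extra)) base[names(extra)] <- extra
  specs <- Map(binary_spec, names(base), base)
  sets <- vapply(specs, function(s) paste(s$positive_set, collapse = ","),
                 character(1))
  if (anyDuplicated(sets))
    stop("duplicate positive sets in candidate specs: ",
         paste(sets[duplicated(sets)], collapse = "; "), call. = FALSE)
  specs
}

#' Build the training instances for one binary model
#'
#' Positives are the (case, category) instances whose category belongs to the
#' positive set, each with its category-specific look-back window. Controls
#' are cases with no category in the positive set: never-decompensated cases
#' contribute their full-stay instance, decompensated-elsewhere cases the
#' window of their earliest event. Inverse-frequency class weights are
#' normalized to mean 1.
#'
#' @param features a `glyc_features` table
#' @param spec a [binary_spec()]
#' @return list with `X` (numeric predictor matrix), `y` (0/1), `weights`,
#'   `case_id`
#' @export
make_instances <- function(features, spec) {
  stopifnot(inherits(features, "glyc_features"), inherits(spec, "binary_spec"))
  cat <- features$category
  pos_rows <- which(cat %in% spec$positive_set)
  pos_cases <- unique(features$case_id[pos_rows])
  ctrl_all <- which(!(features$case_id %in% pos_cases))
  # one control instance per case: category 0 row if present, else earliest
  # event (lowest window end; ties by category)
  cf <- features[ctrl_all, c("case_id", "category")]
  ord <- order(cf$case_id, cf$category)
  ctrl_rows <- ctrl_all[ord][!duplicated(cf$case_id[ord])]
  rows <- c(pos_rows, ctrl_rows)
  y <- c(rep(1L, length(pos_rows)), rep(0L, length(ctrl_rows)))
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be present to build weighted instances",
         call. = FALSE)
  freq <- table(y)[as.character(y)]
  w <- as.numeric(1 / freq)
  w <- w / mean(w)
  list(X = feature_matrix(features)[rows, , drop = FALSE], y = y, weights = w,
       case_id = features$case_id[rows])
}

#' Case-level train/test split
#'
#' @param cases vector of case identifiers (duplicates allowed; the split is
#'   over unique cases)
#' @param ratio training fraction in (0, 1); default 0.7
#' @param seed integer seed
#' @return list with `train` and `test` case-id vectors;
#'   `length(train) == round(ratio * n)`
#' @export
split_cases <- function(cases, ratio = 0.7, seed = 1L) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly between 0 and 1", call. = FALSE)
  u <- unique(cases)
  n <- length(u)
  if (n < 10) stop("need at least 10 cases to split", call. = FALSE)
  n_train <- round(ratio * n)
  sh <- with_seed(seed, sample(u))
  list(train = sh[seq_len(n_train)], test = sh[(n_train + 1):n])
}

# rank-based AUC (equivalent to the Wilcoxon statistic); ties get mid-ranks
auc_score <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_threshold_metrics <- function(scores, y, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  c(precision = prec, sensitivity = sens, specificity = spec,
    auc = auc_score(scores, y), informedness = sens + spec - 1)
}

# stochastic hyperparameter draw for the boosted-tree search
draw_params <- function(n) {
  data.frame(
    max_depth = sample(2:8, n, TRUE),
    eta = exp(runif(n, log(0.02), log(0.3))),
    nrounds = sample(c(50L, 100L, 150L, 200L), n, TRUE),
    subsample = runif(n, 0.6, 1),
    colsample_bytree = runif(n, 0.5, 1),
    min_child_weight = sample(c(1, 3, 5, 10), n, TRUE),
    lambda = runif(n, 0, 5)
  )
}

#' Train one binary gradient-boosted model with stochastic grid search
#'
#' Cases are split 70/30; a random search over the boosted-tree
#' hyperparameter space (depth, learning rate, number of trees, row and
#' column subsampling, minimum child weight, L2 regularization) trains each
#' candidate on the 70% partition with inverse-frequency instance weights and
#' scores it on the withheld 30%. The candidate maximizing the selection
#' metric is retained together with its withheld-split metrics (precision,
#' sensitivity, specificity, AUC ROC, informedness) and gain-based variable
#' importance. Missing feature values are routed through the learner's
#' sparsity-aware default directions; no imputation is performed.
#'
#' @param spec a [binary_spec()]
#' @param instances output of [make_instances()]
#' @param budget number of random hyperparameter draws (>= 1); the published
#'   analysis used 2000-4000, desk-scale runs use far fewer
#' @param seed integer seed controlling the split and the search
#' @param selection metric used to pick the retained model
#' @param split_ratio training fraction of the case split
#' @return object of class `trained_binary`
#' @export
train_binary <- function(spec, instances, budget = 100, seed = 1L,
                         selection = c("auc", "precision", "sensitivity",
                                       "informedness"),
                         split_ratio = 0.7) {
  selection <- match.arg(selection)
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  y <- instances$y
  if (length(unique(y)) < 2)
    stop("single-class outcome: cannot train a binary model", call. = FALSE)
  sp <- split_cases(instances$case_id, split_ratio, seed)
  tr <- instances$case_id %in% sp$train
  if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
    stop("a split partition lost one class; use more cases", call. = FALSE)
  dtrain <- xgboost::xgb.DMatrix(instances$X[tr, , drop = FALSE],
                                 label = y[tr], weight = instances$weights[tr],
                                 missing = NA)
  dtest <- xgboost::xgb.DMatrix(instances$X[!tr, , drop = FALSE],
                                label = y[!tr], missing = NA)
  grid <- with_seed(child_seed(seed, 17L), draw_params(budget))
  best <- NULL
  for (i in seq_len(budget)) {
    params <- list(objective = "binary:logistic", tree_method = "hist",
                   max_depth = grid$max_depth[i], eta = grid$eta[i],
                   subsample = grid$subsample[i],
                   colsample_bytree = grid$colsample_bytree[i],
                   min_child_weight = grid$min_child_weight[i],
                   lambda = grid$lambda[i], nthread = 1)
    fit <- with_seed(child_seed(seed, 100L + i),
                     xgboost::xgb.train(params, dtrain,
                                        nrounds = grid$nrounds[i], verbose = 0))
    sc <- predict(fit, dtest)
    met <- binary_threshold_metrics(sc, y[!tr])
    if (is.null(best) || isTRUE(met[[selection]] > best$metrics[[selection]])) {
      best <- list(fit = fit, metrics = met, params = grid[i, ],
                   test_scores = sc)
    }
  }
  structure(list(spec = spec, model = best$fit,
                 metrics = best$metrics, params = best$params,
                 feature_names = colnames(instances$X),
                 split = sp, seed = seed, selection = selection,
                 n_train = sum(tr), n_test = sum(!tr)),
            class = "trained_binary")
}

#' @export
print.trained_binary <- function(x, ...) {
  cat(sprintf("trained binary model %s (positives {%s}), %d/%d train/test\n",
              x$spec$label, paste(x$spec$positive_set, collapse = ","),
              x$n_train, x$n_test))
  m <- x$metrics
  cat(sprintf("  withheld: AUC %.3f, precision %.3f, sensitivity %.3f, informedness %.3f\n",
              m[["auc"]], m[["precision"]], m[["sensitivity"]],
              m[["informedness"]]))
  invisible(x)
}

#' @export
predict.trained_binary <- function(object, newdata, type = c("prob", "vote"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "glyc_features")) feature_matrix(newdata)
       else as.matrix(newdata)
  X <- X[, object$feature_names, drop = FALSE]
  p <- predict(object$model, xgboost::xgb.DMatrix(X, missing = NA))
  if (type == "prob") p else as.integer(p >= threshold)
}

#' Gain-based variable importance of a trained binary model
#'
#' The importance of a variable is the loss reduction attributable to splits
#' on it, weighted by the covered instances and averaged over the whole tree
#' ensemble; variables never split on score 0.
#'
#' @param model a `trained_binary`
#' @return named numeric vector over all features, decreasing
#' @export
importance <- function(model) {
  if (!inherits(model, "trained_binary"))
    stop("importance() expects a trained binary model", call. = FALSE)
  imp <- xgboost::xgb.importance(model = model$model)
  out <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  sort(out, decreasing = TRUE)
}
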