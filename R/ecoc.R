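#' Default clinical tie-break priority
#'
#' When two or more classes tie at minimal Hamming distance the more severe
#' one wins: hypoglycemia > severe hyperglycemia > moderate hyperglycemia >
#' nondecompensated > mild hyperglycemia. Mild hyperglycemia ranks last to
#' reduce false alarms.
#'
#' @return integer permutation of 0:4, most urgent first
#' @export
tiebreak_priority <- function() c(1L, 4L, 3L, 0L, 2L)

#' Build the class codeword matrix of an ensemble
#'
#' Row k (class k-1) holds the *ideal result*: bit j is 1 iff the class
#' belongs to model j's positive set. Class 0 is the all-zero codeword. At
#' least `ceiling(log2(5)) = 3` binary models are required to give the five
#' classes distinct codewords.
#'
#' @param specs list of [binary_spec()]s (or `trained_binary`s)
#' @return 5 x L 0/1 matrix, rownames "0".."4", colnames the model labels
#' @export
build_codewords <- function(specs) {
  specs <- lapply(specs, function(s) if (inherits(s, "trained_binary")) s$spec else s)
  L <- length(specs)
  if (L < 3)
    stop("an ensemble needs at least ceiling(log2(5)) = 3 binary models",
         call. = FALSE)
  C <- vapply(specs, function(s) as.integer(0:4 %in% s$positive_set),
              integer(5))
  dimnames(C) <- list(as.character(0:4),
                      unname(vapply(specs, function(s) s$label, character(1))))
  key <- apply(C, 1, paste, collapse = "")
  if (anyDuplicated(key)) {
    dup <- split(as.character(0:4), key)
    dup <- dup[lengths(dup) > 1]
    stop("codeword collision between classes: ",
         paste(vapply(dup, paste, character(1), collapse = ","),
               collapse = "; "), call. = FALSE)
  }
  C
}

#' Decode vote bit strings by minimal Hamming distance
#'
#' Each row of `votes` is a case-specific bit string of binary-model votes;
#' the predicted class is the one whose ideal codeword has minimal Hamming
#' distance, ties resolved by the clinical priority order.
#'
#' @param votes 0/1 matrix (n x L) or a single length-L vector
#' @param codewords 5 x L codeword matrix from [build_codewords()]
#' @param priority tie-break permutation of 0:4, most urgent first
#' @return integer vector of predicted classes 0-4
#' @examples
#' C <- build_codewords(candidate_specs()[c("A", "B", "G", "H", "I")])
#' decode_votes(c(1, 0, 0, 0, 0), C)   # control outranks mild hyperglycemia
#' @export
decode_votes <- function(votes, codewords, priority = tiebreak_priority()) {
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  votes <- as.matrix(votes)
  if (ncol(votes) != ncol(codewords))
    stop(sprintf("vote length %d does not match codeword length %d",
                 ncol(votes), ncol(codewords)), call. = FALSE)
  priority <- as.integer(priority)
  if (!all(sort(priority) == 0:4))
    stop("priority must be a permutation of 0..4", call. = FALSE)
  # Hamming(v, c) = sum(v) + sum(c) - 2 v.c
  D <- matrix(rowSums(votes), nrow(votes), 5) +
    matrix(rowSums(codewords), nrow(votes), 5, byrow = TRUE) -
    2 * votes %*% t(codewords)
  Dp <- D[, as.character(priority), drop = FALSE]
  priority[max.col(-Dp, ties.method = "first")]
}

#' Per-model votes and decoded class for feature instances
#'
#' @param features a `glyc_features` table (or predictor matrix)
#' @param models list of `trained_binary` models
#' @param codewords codeword matrix of the models
#' @param thresholds per-model vote thresholds on predicted probability
#' @param priority tie-break order
#' @return data.frame with the decoded `class` and one vote column per model
#' @export
predict_case <- function(features, models, codewords = build_codewords(models),
                         thresholds = rep(0.5, length(models)),
                         priority = tiebreak_priority()) {
  if (length(models) != ncol(codewords))
    stop("one trained model per codeword column is required", call. = FALSE)
  if (length(thresholds) == 1) thresholds <- rep(thresholds, length(models))
  V <- vapply(seq_along(models), function(j)
    predict(models[[j]], features, type = "vote", threshold = thresholds[j]),
    integer(if (inherits(features, "glyc_features")) nrow(features)
            else nrow(as.matrix(features))))
  if (is.null(dim(V))) V <- matrix(V, nrow = 1)
  cls <- decode_votes(V, codewords, priority)
  out <- data.frame(class = cls)
  out[colnames(codewords)] <- as.data.frame(V)
  out
}

# macro-averaged per-class precision of decoded predictions; classes never
# predicted contribute 0 (a composition that refuses to call a class earns
# no credit for it)
macro_precision <- function(truth, pred, classes = 0:4) {
  pr <- vapply(classes, function(k) {
    tp <- sum(pred == k & truth == k); fp <- sum(pred == k & truth != k)
    if (tp + fp == 0) 0 else tp / (tp + fp)
  }, numeric(1))
  mean(pr[classes %in% unique(truth)])
}

# macro-averaged one-vs-rest PR-curve area using -Hamming distance as the
# class score (alternative "average precision" reading)
macro_pr_auc <- function(truth, votes, codewords) {
  D <- matrix(rowSums(votes), nrow(votes), 5) +
    matrix(rowSums(codewords), nrow(votes), 5, byrow = TRUE) -
    2 * votes %*% t(codewords)
  ap <- vapply(0:4, function(k) {
    yk <- as.integer(truth == k)
    if (!any(yk == 1)) return(NA_real_)
    sc <- -D[, k + 1]
    o <- order(sc, decreasing = TRUE)
    yk <- yk[o]
    prec <- cumsum(yk) / seq_along(yk)
    sum(prec * yk) / sum(yk)
  }, numeric(1))
  mean(ap, na.rm = TRUE)
}

ensemble_feasible <- function(specs) {
  if (length(specs) < 3) return(FALSE)
  !inherits(try(build_codewords(specs), silent = TRUE), "try-error")
}

#' Fitness of a candidate ensemble composition
#'
#' Decodes the validation votes of the selected members and returns the
#' configured average-precision readout. Infeasible masks (< 3 members or
#' colliding codewords) score `-Inf`.
#'
#' @param mask logical inclusion vector over the candidate models
#' @param votes n x L matrix of all candidates' validation votes
#' @param truth true classes 0-4 of the validation instances
#' @param specs candidate [binary_spec()]s (column order of `votes`)
#' @param priority tie-break order
#' @param fitness `"macro_precision"` (default) or `"pr_auc"`
#' @return scalar fitness
#' @export
ensemble_fitness <- function(mask, votes, truth, specs,
                             priority = tiebreak_priority(),
                             fitness = c("macro_precision", "pr_auc")) {
  fitness <- match.arg(fitness)
  mask <- as.logical(mask)
  sub <- specs[mask]
  if (!ensemble_feasible(sub)) return(-Inf)
  C <- build_codewords(sub)
  V <- votes[, mask, drop = FALSE]
  if (fitness == "macro_precision") {
    macro_precision(truth, decode_votes(V, C, priority))
  } else macro_pr_auc(truth, V, C)
}

#' Select the ensemble composition with a genetic algorithm
#'
#' Searches the space of inclusion bitmasks over the candidate binary models
#' (exponential in the number of candidates) for the composition maximizing
#' average precision of the decoded multiclass predictions on validation
#' data. Standard GA: tournament selection, uniform crossover, per-bit
#' mutation, elitism. Deterministic given the seed.
#'
#' @param votes n x L validation vote matrix of all candidates
#' @param truth true classes 0-4
#' @param specs candidate [binary_spec()]s
#' @param ga a [ga_control()]
#' @param seed integer seed
#' @param priority,fitness see [ensemble_fitness()]
#' @return list with `mask` (logical), `fitness`, `trace` (per-generation
#'   best) and `n_evaluated` (distinct masks scored)
#' @export
optimize_composition <- function(votes, truth, specs, ga = ga_control(),
                                 seed = 1L, priority = tiebreak_priority(),
                                 fitness = "macro_precision") {
  L <- length(specs)
  stopifnot(ncol(votes) == L)
  cache <- new.env(parent = emptyenv())
  evalmask <- function(m) {
    key <- paste(as.integer(m), collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- ensemble_fitness(m, votes, truth, specs, priority, fitness)
    cache[[key]] <- f
    f
  }
  mut_rate <- ga$mutation_rate %||% (1 / L)
  with_seed(seed, {
    pop <- matrix(runif(ga$pop_size * L) < 0.5, ga$pop_size, L)
    pop[1, ] <- TRUE                      # seed the full ensemble
    fit <- apply(pop, 1, evalmask)
    trace <- numeric(ga$generations)
    for (g in seq_len(ga$generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- pop[ord[seq_len(min(ga$elitism, nrow(pop)))], , drop = FALSE]
      while (nrow(newpop) < ga$pop_size) {
        pick <- function() {
          cand <- sample.int(nrow(pop), ga$tournament_size, replace = TRUE)
          pop[cand[which.max(fit[cand])], ]
        }
        p1 <- pick(); p2 <- pick()
        child <- ifelse(runif(L) < ga$crossover_rate, p1, p2)
        flip <- runif(L) < mut_rate
        child[flip] <- !child[flip]
        newpop <- rbind(newpop, child)
      }
      pop <- newpop
      fit <- apply(pop, 1, evalmask)
      trace[g] <- max(fit)
    }
    keys <- sort(ls(cache))               # deterministic tie-break
    vals <- vapply(keys, function(k) cache[[k]], numeric(1))
    best_key <- keys[which.max(vals)]
    best_fit <- cache[[best_key]]
    if (!is.finite(best_fit))
      stop("no feasible ensemble composition exists among the candidates",
           call. = FALSE)
    mask <- as.logical(as.integer(strsplit(best_key, "")[[1]]))
    list(mask = mask, fitness = best_fit, trace = trace,
         n_evaluated = length(ls(cache)))
  })
}

#' Fit the second-level error-correcting multiclass classifier
#'
#' The main fitting function of the package. Given a derived feature table it
#' (1) splits the cases 70/30, (2) trains one gradient-boosted binary model
#' per candidate class combination via stochastic hyperparameter search
#' (candidates scored on the withheld 30%), (3) collects the candidates'
#' votes on the withheld instances and, optionally, (4) selects the ensemble
#' composition with a genetic algorithm maximizing average precision of the
#' Hamming-decoded multiclass predictions. The returned object predicts new
#' instances by voting and minimal-Hamming-distance decoding with clinical
#' tie-breaking.
#'
#' @param features a `glyc_features` table from [derive_features()]
#' @param specs candidate model library, see [candidate_specs()]
#' @param budget hyperparameter draws per binary model
#' @param selection per-model retained-metric criterion (default AUC ROC)
#' @param optimize if `TRUE` run the GA composition search; if `FALSE` keep
#'   all candidates (they must be feasible)
#' @param ga [ga_control()] settings
#' @param priority clinical tie-break order
#' @param threshold vote threshold on predicted probability
#' @param split_ratio case-level training fraction
#' @param fitness GA readout, `"macro_precision"` or `"pr_auc"`
#' @param seed integer seed for split, search and GA
#' @return object of class `glyc_ecoc` with members `models`, `codewords`,
#'   `mask`, `thresholds`, `priority`, `validation` (held-out votes, truth
#'   and metrics) and `ga` (trace)
#' @seealso [predict.glyc_ecoc()], [cross_validate()]
#' @export
glyc_ecoc <- function(features, specs = candidate_specs(), budget = 100,
                      selection = "auc", optimize = TRUE, ga = ga_control(),
                      priority = tiebreak_priority(), threshold = 0.5,
                      split_ratio = 0.7, fitness = "macro_precision",
                      seed = 1L) {
  stopifnot(inherits(features, "glyc_features"))
  cl <- match.call()
  sp <- split_cases(features$case_id, split_ratio, seed)
  val_rows <- features$case_id %in% sp$test
  models <- vector("list", length(specs))
  names(models) <- vapply(specs, function(s) s$label, character(1))
  for (j in seq_along(specs)) {
    inst <- make_instances(features, specs[[j]])
    models[[j]] <- train_binary(specs[[j]], inst, budget = budget,
                                seed = child_seed(seed, j),
                                selection = selection,
                                split_ratio = split_ratio)
  }
  val_feat <- subset_features(features, val_rows)
  V <- vapply(models, function(m)
    predict(m, val_feat, type = "vote", threshold = threshold),
    integer(nrow(val_feat)))
  truth <- features$category[val_rows]
  if (optimize) {
    opt <- optimize_composition(V, truth, specs, ga = ga,
                                seed = child_seed(seed, 999L),
                                priority = priority, fitness = fitness)
    mask <- opt$mask
  } else {
    mask <- rep(TRUE, length(specs))
    if (!ensemble_feasible(specs))
      stop("the fixed candidate set is not a feasible ensemble", call. = FALSE)
    opt <- list(fitness = ensemble_fitness(mask, V, truth, specs, priority,
                                           fitness),
                trace = numeric(0), n_evaluated = 1L)
  }
  member <- which(mask)
  codewords <- build_codewords(specs[member])
  pred_val <- decode_votes(V[, member, drop = FALSE], codewords, priority)
  structure(list(
    call = cl,
    specs = specs, mask = mask,
    models = models[member],
    codewords = codewords,
    thresholds = rep(threshold, length(member)),
    priority = priority,
    split = sp,
    validation = list(votes = V, truth = truth, pred = pred_val,
                      fitness = opt$fitness),
    ga = list(trace = opt$trace, n_evaluated = opt$n_evaluated),
    encodings = attr(features, "encodings"),
    seed = seed
  ), class = "glyc_ecoc")
}

#' Predict decompensation classes for new instances
#'
#' @param object a fitted [glyc_ecoc()]
#' @param newdata a `glyc_features` table (or predictor matrix with matching
#'   columns)
#' @param type `"class"` (integer classes 0-4) or `"votes"` (data.frame with
#'   the decoded class and the per-model vote bits)
#' @param ... unused
#' @return see `type`
#' @export
predict.glyc_ecoc <- function(object, newdata, type = c("class", "votes"),
                              ...) {
  type <- match.arg(type)
  out <- predict_case(newdata, object$models, object$codewords,
                      object$thresholds, object$priority)
  if (type == "class") out$class else out
}

#' @export
print.glyc_ecoc <- function(x, ...) {
  cat("Error-correcting multiclass dysglycemia classifier\n")
  cat(sprintf("  members (%d of %d candidates): %s\n", ncol(x$codewords),
              length(x$specs), paste(colnames(x$codewords), collapse = ", ")))
  cat(sprintf("  validation fitness (macro precision): %.3f on %d held-out instances\n",
              x$validation$fitness, length(x$validation$truth)))
  invisible(x)
}

#' @export
summary.glyc_ecoc <- function(object, ...) {
  cm5 <- confusion_matrix(object$validation$truth, object$validation$pred)
  cm3 <- confusion_matrix(object$validation$truth, object$validation$pred,
                          grouping = grouping_3class())
  member_metrics <- t(vapply(object$models, function(m) m$metrics, numeric(5)))
  out <- list(members = colnames(object$codewords),
              codewords = object$codewords,
              member_metrics = member_metrics,
              confusion_5class = cm5, confusion_3class = cm3,
              class_metrics = class_metrics(cm3),
              fitness = object$validation$fitness)
  class(out) <- "summary.glyc_ecoc"
  out
}

#' @export
print.summary.glyc_ecoc <- function(x, ...) {
  cat("Second-level ensemble:", paste(x$members, collapse = ", "), "\n\n")
  cat("Codewords (classes x members):\n")
  print(x$codewords)
  cat("\nBinary member metrics (withheld split):\n")
  print(round(x$member_metrics, 3))
  cat("\n3-class confusion (rows true, % relative to true class):\n")
  print(x$confusion_3class$percent)
  cat("\nPer-class metrics (%):\n")
  print(x$class_metrics)
  invisible(x)
}

#' Plot the fitted ensemble
#'
#' `which = "ga"` shows the per-generation best fitness of the composition
#' search; `which = "importance"` the top gain-based variable importances of
#' each member model.
#'
#' @param x a `glyc_ecoc`
#' @param which `"ga"` or `"importance"`
#' @param top_n importances shown per member
#' @param ... passed to the underlying plot
#' @return `x`, invisibly
#' @export
plot.glyc_ecoc <- function(x, which = c("ga", "importance"), top_n = 10, ...) {
  which <- match.arg(which)
  if (which == "ga") {
    tr <- x$ga$trace
    if (!length(tr)) {
      warning("no GA trace recorded (fixed composition)")
      return(invisible(x))
    }
    plot(seq_along(tr), tr, type = "b", xlab = "generation",
         ylab = "best fitness (average precision)",
         main = "Ensemble composition search", ...)
  } else {
    old <- graphics::par(mfrow = c(1, length(x$models)),
                         mar = c(4, 8, 2, 1))
    on.exit(graphics::par(old))
    for (nm in names(x$models)) {
      imp <- head(importance(x$models[[nm]]), top_n)
      graphics::barplot(rev(imp), horiz = TRUE, las = 1, cex.names = 0.6,
                        main = paste("model", nm), xlab = "gain")
    }
  }
  invisible(x)
}
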