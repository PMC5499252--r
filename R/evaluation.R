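# Confusion-matrix metrics and the repeated stratified k-fold
# cross-validation protocol.  AD is the positive class throughout.

#' Confusion counts from true and predicted labels
#'
#' @param truth,predicted Character vectors of "AD"/"HC" labels.
#' @return Object of class `confusion_counts`: list `tp`, `fn`, `fp`,
#'   `tn` (AD = positive).
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (!all(c(truth, predicted) %in% c("AD", "HC")))
    stop("labels must be 'AD' or 'HC'", call. = FALSE)
  structure(list(tp = sum(truth == "AD" & predicted == "AD"),
                 fn = sum(truth == "AD" & predicted == "HC"),
                 fp = sum(truth == "HC" & predicted == "AD"),
                 tn = sum(truth == "HC" & predicted == "HC")),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, and recall
#' (= sensitivity).  A ratio with a zero denominator is reported as
#' `NaN` with a warning, never silently as 0.
#'
#' @param counts A `confusion_counts` object, or `NULL` if the four
#'   counts are given directly.
#' @param tp,fn,fp,tn Non-negative integers (AD = positive class),
#'   used when `counts` is `NULL`.
#' @return Named numeric vector `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `recall`.
#' @examples
#' classification_metrics(tp = 46, fn = 4, fp = 6, tn = 44)
#' @export
classification_metrics <- function(counts = NULL, tp = 0, fn = 0, fp = 0, tn = 0) {
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "confusion_counts"))
    tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  }
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- tp + fn + fp + tn
  if (n == 0L) stop("at least one sample is required", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator)", call. = FALSE)
      NaN
    } else num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  c(accuracy = (tp + tn) / n,
    sensitivity = sens,
    specificity = ratio(tn, tn + fp, "specificity"),
    precision = ratio(tp, tp + fp, "precision"),
    recall = sens)
}

#' Stratified fold assignment
#'
#' Partitions the indices into `k` folds whose sizes differ by at most
#' one and whose per-class counts differ by at most one, using a seeded
#' shuffle.  Within each class the shuffled members are dealt in blocks
#' of `floor(n_class/k)` and the remainder goes to the currently
#' smallest folds (ties broken at random), which balances the totals.
#'
#' @param labels Character vector of class labels.
#' @param k Number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector in `1..k`, one fold id per element of
#'   `labels`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("cannot make %d folds from %d subjects", k, n),
                  call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  sizes <- integer(k)
  for (cl in sample(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      warning(sprintf("class %s has %d members, fewer than %d folds: some folds will lack it",
                      cl, length(idx), k), call. = FALSE)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    # folds ordered by current size (random tie-break) receive the
    # larger share first
    ord <- order(sizes + stats::runif(k))
    per <- rep(base, k)
    if (extra > 0L) per[ord[seq_len(extra)]] <- base + 1L
    pos <- 1L
    for (f in seq_len(k)) {
      if (per[f] > 0L) {
        fold[idx[pos:(pos + per[f] - 1L)]] <- f
        pos <- pos + per[f]
      }
      sizes[f] <- sizes[f] + per[f]
    }
  }
  fold
}

#' Repeated stratified cross-validation of the score + network pipeline
#'
#' For each of `runs` repetitions: draw fresh stratified folds; for each
#' fold, fit the principal-component reduction on the nine training
#' folds only (unless `pca_mode = "global"`, which fits once on all
#' subjects and mimics reducing before splitting), train the network on
#' the training scores, classify the held-out fold, and pool all
#' held-out predictions of the run into one confusion matrix.  Metrics
#' are aggregated over runs as mean and sample standard deviation;
#' per-fold metrics (computed on each fold's own pooled predictions)
#' are also retained, with their own SD, since small positive-class
#' counts per fold make the two aggregations differ.
#'
#' @param x Features: a `cad_features` object or numeric matrix
#'   (subjects x features).  If `pca = FALSE` the columns are used as
#'   scores directly.
#' @param labels "AD"/"HC" labels (taken from `x` if absent and `x` is
#'   a `cad_features` object).
#' @param runs Number of repetitions (default 50).
#' @param k Folds per repetition (default 10).
#' @param seed Master seed; per-run seeds are spawned from it so any
#'   single run is reproducible in isolation.
#' @param pca Reduce features to principal-component scores within the
#'   protocol (default `TRUE`).
#' @param pca_mode `"per-fold"` (default; fit the reduction on training
#'   folds only) or `"global"` (fit once on all subjects before
#'   cross-validation; optimistic, provided for comparison).
#' @param variance Cumulative-variance threshold for component
#'   selection (default 0.90).
#' @param pcs Fixed component count overriding the threshold rule.
#' @param hidden Hidden-layer size (default 10).
#' @param max_iterations,mse_goal SCG stopping rule per fold.
#' @param class_costs Passed to [train_scg()]; default `"balanced"`.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `cad_cv`: `per_run` (data frame of pooled
#'   per-run metrics), `mean`, `sd` (over runs), `per_fold`, `sd_folds`,
#'   `counts` (summed confusion counts over all runs), `folds` (list of
#'   per-run fold assignments), `config`, plus `runs`, `k`, `seed`.
#' @export
run_cv <- function(x, labels = NULL, runs = 50L, k = 10L, seed = 1L,
                   pca = TRUE, pca_mode = c("per-fold", "global"),
                   variance = 0.90, pcs = NULL, hidden = 10L,
                   max_iterations = 300L, mse_goal = 1e-4,
                   class_costs = "balanced", threshold = 0.5) {
  pca_mode <- match.arg(pca_mode)
  if (inherits(x, "cad_features")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(labels)) stop("`labels` are required", call. = FALSE)
  stopifnot(nrow(x) == length(labels), all(labels %in% c("AD", "HC")))
  targets <- as.numeric(labels == "AD")

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, runs)

  global_model <- NULL
  if (pca && pca_mode == "global") {
    global_model <- fit_pca(x, variance_threshold = variance)
    if (!is.null(pcs)) global_model$k_selected <- as.integer(pcs)
  }

  metric_names <- c("accuracy", "sensitivity", "specificity", "precision", "recall")
  per_run <- matrix(NA_real_, runs, length(metric_names),
                    dimnames = list(NULL, metric_names))
  per_fold <- list()
  fold_assignments <- vector("list", runs)
  total <- list(tp = 0L, fn = 0L, fp = 0L, tn = 0L)

  for (r in seq_len(runs)) {
    fold <- stratified_folds(labels, k, seed = run_seeds[r])
    fold_assignments[[r]] <- fold
    pred <- character(length(labels))
    for (f in seq_len(k)) {
      tr <- which(fold != f); va <- which(fold == f)
      if (length(unique(labels[tr])) < 2L)
        stop(sprintf("training folds of run %d, fold %d contain a single class",
                     r, f), call. = FALSE)
      if (pca) {
        model <- if (pca_mode == "global") global_model
                 else {
                   m <- fit_pca(x[tr, , drop = FALSE], variance_threshold = variance)
                   if (!is.null(pcs)) m$k_selected <- min(as.integer(pcs), m$k_max)
                   m
                 }
        s_tr <- pca_transform(model, x[tr, , drop = FALSE])
        s_va <- pca_transform(model, x[va, , drop = FALSE])
      } else {
        s_tr <- x[tr, , drop = FALSE]; s_va <- x[va, , drop = FALSE]
      }
      cfg <- scg_config(max_iterations = max_iterations, mse_goal = mse_goal,
                        seed = run_seeds[r] %% 100000L + 1000L * f,
                        class_costs = class_costs)
      fit <- train_scg(s_tr, targets[tr], sizes = c(ncol(s_tr), hidden, 1L),
                       config = cfg)
      pred[va] <- fnn_classify(fit$weights, s_va, threshold)
      fm <- suppressWarnings(
        classification_metrics(confusion_counts(labels[va], pred[va])))
      per_fold[[length(per_fold) + 1L]] <-
        c(run = r, fold = f, fm)
    }
    cc <- confusion_counts(labels, pred)
    total <- Map(`+`, total, cc[c("tp", "fn", "fp", "tn")])
    per_run[r, ] <- suppressWarnings(classification_metrics(cc))
  }

  per_fold <- as.data.frame(do.call(rbind, per_fold))
  structure(list(
    per_run = as.data.frame(per_run),
    mean = colMeans(per_run),
    sd = apply(per_run, 2L, stats::sd),
    per_fold = per_fold,
    sd_folds = vapply(metric_names, function(m)
      stats::sd(per_fold[[m]], na.rm = TRUE), numeric(1)),
    counts = total,
    folds = fold_assignments,
    config = list(pca = pca, pca_mode = pca_mode, variance = variance,
                  pcs = pcs, hidden = hidden,
                  max_iterations = max_iterations, mse_goal = mse_goal,
                  class_costs = class_costs, threshold = threshold),
    runs = runs, k = k, seed = seed
  ), class = "cad_cv")
}

#' @export
print.cad_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d x %d-fold stratified cross-validation (seed %d)\n",
              x$runs, x$k, x$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-11s %.*f +/- %.*f\n", m, digits, x$mean[m], digits, x$sd[m]))
  invisible(x)
}
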