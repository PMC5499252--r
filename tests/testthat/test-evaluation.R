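test_that("metric formulas are exact on hand-computable counts", {
  m <- classification_metrics(tp = 5, fn = 0, fp = 0, tn = 5)
  expect_equal(unname(m), rep(1, 5))

  m <- classification_metrics(tp = 46, fn = 4, fp = 6, tn = 44)
  expect_equal(m[["accuracy"]], 0.90)
  expect_equal(m[["sensitivity"]], 0.92)
  expect_equal(m[["specificity"]], 0.88)
  expect_equal(m[["precision"]], 46 / 52)
  expect_equal(m[["precision"]], 0.8846, tolerance = 1e-4)
  expect_identical(m[["recall"]], m[["sensitivity"]])

  w <- capture_warnings(
    m0 <- classification_metrics(tp = 0, fn = 0, fp = 0, tn = 10))
  expect_match(w, "sensitivity is undefined", all = FALSE)
  expect_match(w, "precision is undefined", all = FALSE)
  expect_equal(m0[["specificity"]], 1)
  expect_true(is.nan(m0[["sensitivity"]]))
  expect_error(classification_metrics(tp = 0, fn = 0, fp = 0, tn = 0),
               "at least one sample")
})

test_that("confusion counts tabulate AD as the positive class", {
  truth <- c("AD", "AD", "HC", "HC", "HC")
  pred  <- c("AD", "HC", "AD", "HC", "HC")
  cc <- confusion_counts(truth, pred)
  expect_identical(unlist(cc[c("tp", "fn", "fp", "tn")], use.names = FALSE),
                   c(1L, 1L, 1L, 2L))
  expect_error(confusion_counts(c("AD", "XX"), c("AD", "AD")), "AD.*HC|labels")
})

test_that("stratified folds balance sizes and class counts", {
  labels <- c(rep("AD", 28), rep("HC", 98))
  fold <- stratified_folds(labels, 10, seed = 3)
  sizes <- tabulate(fold, 10)
  expect_true(all(sizes %in% c(12L, 13L)))
  ad_per_fold <- tabulate(fold[labels == "AD"], 10)
  expect_true(all(ad_per_fold %in% c(2L, 3L)))
  # determinism
  expect_identical(fold, stratified_folds(labels, 10, seed = 3))
  expect_false(identical(fold, stratified_folds(labels, 10, seed = 4)))
  # 10 subjects, 10 folds: singletons
  fold1 <- suppressWarnings(stratified_folds(rep(c("AD", "HC"), 5), 10, seed = 1))
  expect_identical(sort(tabulate(fold1, 10)), rep(1L, 10))
  expect_error(stratified_folds(labels, 1), "at least 2")
  expect_warning(stratified_folds(c(rep("AD", 3), rep("HC", 40)), 10, seed = 1),
                 "fewer than 10 folds")
})

test_that("fold partition invariants hold across random label mixes", {
  set.seed(202)
  for (rep in 1:8) {
    n <- sample(30:90, 1)
    labels <- sample(c("AD", "HC"), n, replace = TRUE, prob = c(0.3, 0.7))
    if (length(unique(labels)) < 2) next
    for (k in c(2, 5, 10)) {
      fold <- suppressWarnings(stratified_folds(labels, k, seed = rep))
      expect_identical(sort(unique(fold)), seq_len(k))   # partition, no gaps
      sizes <- tabulate(fold, k)
      expect_lte(diff(range(sizes)), 1L)
      for (cl in unique(labels))
        expect_lte(diff(range(tabulate(fold[labels == cl], k))), 1L)
    }
  }
})

test_that("cross-validation is near-perfect on well-separated scores", {
  set.seed(90)
  n <- 60
  scores <- rbind(matrix(rnorm(3 * n / 2), n / 2, 3),
                  matrix(rnorm(3 * n / 2, mean = 8), n / 2, 3))
  labels <- rep(c("HC", "AD"), each = n / 2)
  cv <- run_cv(scores, labels, runs = 5, k = 10, seed = 5, pca = FALSE,
               hidden = 4, max_iterations = 150)
  expect_gte(cv$mean[["accuracy"]], 0.95)
})

test_that("cross-validation is at chance when labels carry no signal", {
  set.seed(91)
  n <- 60
  scores <- matrix(rnorm(5 * n), n, 5)
  labels <- sample(rep(c("HC", "AD"), each = n / 2))
  cv <- run_cv(scores, labels, runs = 10, k = 10, seed = 6, pca = FALSE,
               hidden = 4, max_iterations = 100)
  expect_lt(abs(cv$mean[["accuracy"]] - 0.5), 0.15)
})

test_that("cross-validation reports are self-consistent and reproducible", {
  set.seed(92)
  n <- 40
  x <- matrix(rnorm(20 * n), n, 20)
  x[1:15, 1:4] <- x[1:15, 1:4] + 1.5
  labels <- c(rep("AD", 15), rep("HC", 25))
  cv1 <- run_cv(x, labels, runs = 2, k = 5, seed = 17, variance = 0.8,
                hidden = 3, max_iterations = 80)
  cv2 <- run_cv(x, labels, runs = 2, k = 5, seed = 17, variance = 0.8,
                hidden = 3, max_iterations = 80)
  expect_identical(cv1$per_run, cv2$per_run)
  expect_identical(cv1$folds, cv2$folds)
  # every run's pooled confusion counts cover the whole cohort
  expect_identical(Reduce(`+`, cv1$counts), 80L)
  # mean/sd recomputable from the stored per-run metrics
  expect_equal(unname(cv1$mean["accuracy"]), mean(cv1$per_run$accuracy))
  expect_equal(unname(cv1$sd["accuracy"]), sd(cv1$per_run$accuracy))
  # fold-level table covers runs x folds
  expect_identical(nrow(cv1$per_fold), 10L)
})

test_that("degenerate training folds raise a named error", {
  set.seed(93)
  x <- matrix(rnorm(40), 20, 2)
  labels <- c("AD", rep("HC", 19))
  expect_error(suppressWarnings(
    run_cv(x, labels, runs = 1, k = 10, seed = 1, pca = FALSE)),
    "single class")
})
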