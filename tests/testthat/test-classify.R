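# Classifier bank, tuning protocol and metrics.

# balanced synthetic feature table: each class sits at its own centroid in
# all 11 feature dimensions, `sep` centroid spacing against unit-ish noise
toy_windows <- function(n_per_class = 40, classes = c("a", "b", "c"),
                        sep = 5, seed = 3) {
  set.seed(seed)
  signs <- rep(c(1, -1), length.out = 11)
  rows <- lapply(seq_along(classes), function(ci) {
    x <- matrix(0.5 * rnorm(n_per_class * 11), ncol = 11,
                dimnames = list(NULL, wearlc:::.feature_names))
    x <- sweep(x, 2, signs * ci * sep, "+")
    df <- as.data.frame(x)
    df$label <- classes[ci]
    df$cycle <- rep(1:10, length.out = n_per_class)
    df$activity <- classes[ci]
    df$session <- 1L
    df
  })
  w <- do.call(rbind, rows)
  split_by_cycles(w)
}

test_that("weighted F1 matches a hand-computed confusion", {
  truth <- factor(c("a", "a", "a", "b", "b", "c"))
  pred <- factor(c("a", "a", "b", "b", "b", "b"), levels = levels(truth))
  # class a: P=1, R=2/3, F1=0.8; class b: P=1/2, R=1, F1=2/3; class c: 0
  expect_equal(weighted_f1(truth, pred),
               (3 * 0.8 + 2 * (2 / 3) + 1 * 0) / 6)
  expect_equal(weighted_f1(truth, truth), 1)
})

test_that("well-separated classes are classified perfectly by every model", {
  w <- toy_windows(sep = 8)
  res <- train_and_evaluate(w, seed = 2)
  expect_setequal(res$model, c("knn", "logistic", "svm", "tree", "rf", "xgb"))
  expect_true(all(res$accuracy == 1))
  expect_true(all(res$weighted_f1 == 1))
})

test_that("label-shuffled features score near the chance rate", {
  w <- toy_windows(n_per_class = 60, classes = c("a", "b", "c"), sep = 6)
  set.seed(99)
  w$label <- sample(w$label)
  res <- train_and_evaluate(w, models = c("knn", "tree"), seed = 2)
  expect_true(all(abs(res$accuracy - 1 / 3) < 0.25))
})

test_that("tuning results and confusion matrices are reported", {
  w <- toy_windows(sep = 8)
  res <- train_and_evaluate(w, models = c("knn", "rf"), seed = 2)
  tun <- attr(res, "tuning")
  expect_named(tun, c("knn", "rf"))
  expect_true(all(c("k", "cv_accuracy") %in% names(tun$knn)))
  conf <- attr(res, "confusion")
  expect_equal(sum(conf$knn), sum(w$partition == "test"))
  expect_match(res$best_params[res$model == "knn"], "^k=")
})

test_that("degenerate label sets are rejected", {
  w <- toy_windows(classes = c("a", "b"))
  w$label <- "a"
  expect_error(train_and_evaluate(w), "at least 2 classes")
})
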