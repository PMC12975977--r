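# Classifier bank with small conventional hyperparameter grids, 4-fold
# cross-validated tuning on the train+validation windows, and test-set
# evaluation with accuracy and weighted F1.

#' Default hyperparameter grids for the classifier bank
#'
#' Small conventional grids per model, fixed so that every run is
#' reproducible and logged in the result.
#'
#' @return Named list of data.frames, one per model.
#' @export
default_grids <- function() {
  list(
    knn = expand.grid(k = c(3, 5, 7, 11)),
    logistic = expand.grid(decay = c(0, 0.01)),
    svm = expand.grid(cost = c(0.1, 1, 10), kernel = "radial",
                      stringsAsFactors = FALSE),
    tree = expand.grid(cp = c(0.001, 0.01)),
    rf = expand.grid(ntree = c(100, 300), mtry = c(2, 3)),
    xgb = expand.grid(nrounds = c(60), max_depth = c(3, 6), eta = c(0.3))
  )
}

.fit_predict <- function(model, params, x_train, y_train, x_test, seed) {
  set.seed(seed)
  switch(model,
    knn = class::knn(x_train, x_test, y_train, k = params$k),
    logistic = {
      df <- data.frame(x_train, .y = y_train)
      fit <- nnet::multinom(.y ~ ., data = df, decay = params$decay,
                            maxit = 300, MaxNWts = 10000, trace = FALSE)
      factor(predict(fit, newdata = data.frame(x_test)),
             levels = levels(y_train))
    },
    svm = {
      fit <- e1071::svm(x_train, y_train, cost = params$cost,
                        kernel = params$kernel)
      predict(fit, x_test)
    },
    tree = {
      df <- data.frame(x_train, .y = y_train)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          cp = params$cp)
      factor(predict(fit, newdata = data.frame(x_test), type = "class"),
             levels = levels(y_train))
    },
    rf = {
      fit <- randomForest::randomForest(x_train, y_train,
                                        ntree = params$ntree,
                                        mtry = params$mtry)
      predict(fit, x_test)
    },
    xgb = {
      nclass <- nlevels(y_train)
      dtrain <- xgboost::xgb.DMatrix(x_train,
                                     label = as.integer(y_train) - 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softmax", num_class = nclass,
                      max_depth = params$max_depth, eta = params$eta,
                      tree_method = "exact", nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
      pred <- predict(fit, xgboost::xgb.DMatrix(x_test))
      factor(levels(y_train)[pred + 1L], levels = levels(y_train))
    },
    stop("unknown model '", model, "'", call. = FALSE)
  )
}

#' Weighted F1-score
#'
#' Per-class F1 (harmonic mean of precision and recall, 0 when undefined)
#' weighted by true-class support; classes absent from the truth are
#' ignored.
#'
#' @param truth,pred Factors with identical levels.
#' @return Weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  lv <- union(levels(factor(truth)), levels(factor(pred)))
  truth <- factor(truth, levels = lv); pred <- factor(pred, levels = lv)
  f1 <- vapply(lv, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- as.numeric(table(truth))
  sum(f1 * support) / sum(support)
}

#' Train the classifier bank and evaluate on the held-out test cycles
#'
#' Features are standardized with statistics fitted on the training
#' partition only. Each model is tuned by grid search with `cv_folds`-fold
#' stratified cross-validation over the pooled train+validation windows,
#' refitted on all of them with the best parameters, and scored on the test
#' partition. No test window influences scaling, tuning or fitting.
#'
#' @param windows A feature table with `partition` (from
#'   [split_by_cycles()]), `label`, and the 11 feature columns.
#' @param models Character vector of models to run; any of `"knn"`,
#'   `"logistic"`, `"svm"`, `"tree"`, `"rf"`, `"xgb"`.
#' @param grids Hyperparameter grids as from [default_grids()].
#' @param cv_folds Number of cross-validation folds (default 4).
#' @param seed Integer seed controlling fold assignment and stochastic
#'   learners.
#' @return A data.frame with one row per model: `model`, `accuracy`,
#'   `weighted_f1`, `best_params`; attributes `confusion` (list of
#'   confusion matrices) and `tuning` (per-model CV accuracies).
#' @export
train_and_evaluate <- function(windows, models = names(default_grids()),
                               grids = default_grids(), cv_folds = 4,
                               seed = 1) {
  stopifnot("partition" %in% names(windows), "label" %in% names(windows))
  y_all <- factor(windows$label)
  if (nlevels(y_all) < 2) stop("need at least 2 classes", call. = FALSE)
  trainval <- windows$partition %in% c("train", "validation")
  test <- windows$partition == "test"
  if (!any(trainval) || !any(test)) {
    stop("both train+validation and test partitions must be non-empty",
         call. = FALSE)
  }
  scaler <- feature_scaler(windows[windows$partition == "train", ])
  scaled <- scale_features(scaler, windows)
  x <- as.matrix(scaled[, .feature_names])
  x_tv <- x[trainval, , drop = FALSE]
  y_tv <- droplevels(y_all[trainval])
  x_te <- x[test, , drop = FALSE]
  y_te <- factor(windows$label[test], levels = levels(y_tv))

  # stratified fold assignment
  set.seed(seed)
  folds <- integer(length(y_tv))
  for (cl in levels(y_tv)) {
    idx <- which(y_tv == cl)
    folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }

  results <- list(); confusion <- list(); tuning <- list()
  for (model in models) {
    grid <- grids[[model]]
    if (is.null(grid)) stop("no grid for model '", model, "'", call. = FALSE)
    cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
      params <- grid[g, , drop = FALSE]
      accs <- vapply(seq_len(cv_folds), function(fold) {
        tr <- folds != fold; va <- folds == fold
        pred <- .fit_predict(model, params, x_tv[tr, , drop = FALSE],
                             droplevels(y_tv[tr]), x_tv[va, , drop = FALSE],
                             seed = seed + fold)
        mean(as.character(pred) == as.character(y_tv[va]))
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- which.max(cv_acc)
    params <- grid[best, , drop = FALSE]
    pred <- .fit_predict(model, params, x_tv, y_tv, x_te, seed = seed)
    acc <- mean(as.character(pred) == as.character(y_te))
    f1 <- weighted_f1(y_te, factor(pred, levels = levels(y_te)))
    results[[model]] <- data.frame(
      model = model, accuracy = acc, weighted_f1 = f1,
      best_params = paste(names(grid), unlist(params), sep = "=",
                          collapse = ","),
      stringsAsFactors = FALSE)
    confusion[[model]] <- table(truth = y_te,
                                pred = factor(pred, levels = levels(y_te)))
    tuning[[model]] <- cbind(grid, cv_accuracy = cv_acc)
  }
  out <- do.call(rbind, c(results, make.row.names = FALSE))
  attr(out, "confusion") <- confusion
  attr(out, "tuning") <- tuning
  out
}
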