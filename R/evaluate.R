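# Repeated stratified splitting, grid-search cross-validated model
# comparison (KNN / RF / SVM / LR), and ROC-AUC.

#' ROC curve and area under the curve
#'
#' Sweeps the decision threshold over the unique scores, records the ROC
#' curve from (0, 0) to (1, 1) and integrates it by the trapezoid rule;
#' tied scores contribute half, so the AUC equals the Mann-Whitney U
#' statistic divided by \eqn{n_1 n_0}.
#'
#' @param scores Predicted probability (or any monotone score) of class 1.
#' @param y 0/1 labels; both classes must be present.
#' @return List `auc` and `roc` (data frame `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc
#' @export
roc_auc <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Stratified train/test split
#'
#' Randomly assigns the requested fraction of each class to the training
#' set, preserving the class ratio within rounding.
#'
#' @param y Label vector.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed; every random draw in the split flows from it.
#' @return List `train`, `test` (row indices, disjoint and covering).
#' @export
stratified_split <- function(y, train_frac = 0.8, seed = 0) {
  stopifnot(train_frac > 0, train_frac < 1)
  train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, size = round(length(idx) * train_frac))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

.stratified_folds <- function(y, k, seed) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Default hyperparameter grids
#'
#' @return Named list of data frames, one grid per algorithm: `knn`
#'   (neighbours k), `rf` (`ntree`, `maxnodes` as a tree-depth proxy, NA =
#'   unrestricted), `svm` (RBF `cost`, `gamma`; NA gamma = the 1/(d *
#'   var) heuristic), `lr` (ridge `lambda`; 0 = plain MLE).
#' @export
default_grids <- function() {
  list(
    knn = data.frame(k = seq(3, 15, by = 2)),
    rf = expand.grid(ntree = c(100, 300), maxnodes = c(NA, 32, 1024)),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.1)),
    lr = data.frame(lambda = c(0, 0.1, 1, 10))
  )
}

# Train one configured learner and return a score function over matrices.
.fit_learner <- function(algorithm, params, X, y) {
  switch(algorithm,
    knn = {
      k <- params$k
      function(Xt) {
        pr <- class::knn(train = X, test = Xt, cl = factor(y), k = k,
                         prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == "1", p_win, 1 - p_win)
      }
    },
    rf = {
      args <- list(x = X, y = factor(y), ntree = params$ntree)
      if (!is.na(params$maxnodes)) args$maxnodes <- params$maxnodes
      fit <- do.call(randomForest::randomForest, args)
      function(Xt) unname(predict(fit, Xt, type = "prob")[, "1"])
    },
    svm = {
      gamma <- if (is.na(params$gamma)) 1 / (ncol(X) * mean(apply(X, 2, var)))
               else params$gamma
      fit <- e1071::svm(x = X, y = factor(y), kernel = "radial",
                        cost = params$cost, gamma = gamma,
                        probability = TRUE)
      function(Xt) {
        pr <- attr(predict(fit, Xt, probability = TRUE), "probabilities")
        unname(pr[, "1"])
      }
    },
    lr = {
      fit <- fit_logistic_mle(X, y, lambda = params$lambda)
      function(Xt) predict_logistic(fit, Xt)
    },
    stop("unknown algorithm: ", algorithm)
  )
}

.cv_accuracy <- function(algorithm, params, X, y, folds) {
  acc <- numeric(max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    scorer <- tryCatch(.fit_learner(algorithm, params,
                                    X[tr, , drop = FALSE], y[tr]),
                       error = function(e) NULL)
    if (is.null(scorer)) return(NA_real_)
    p <- scorer(X[!tr, , drop = FALSE])
    acc[f] <- mean((p >= 0.5) == (y[!tr] == 1))
  }
  mean(acc)
}

#' Compare classification algorithms with repeated stratified splits
#'
#' For each repeat the data are split 80/20 stratified by label (seeded),
#' the scaler is fitted on the training portion, each algorithm's
#' hyperparameters are tuned by stratified k-fold grid-search
#' cross-validation on the training portion (selection by CV accuracy),
#' the winning configuration is refitted on the full training set, and
#' accuracy plus ROC-AUC are scored on the held-out test set.
#'
#' @param table Numeric descriptor data frame (unscaled; scaling is
#'   fitted per training split).
#' @param labels 0/1 vector.
#' @param algorithms Subset of `c("knn", "rf", "svm", "lr")`.
#' @param n_repeats Number of random splits (default 5).
#' @param cv_folds Cross-validation folds (default 5).
#' @param grids Hyperparameter grids, see [default_grids()].
#' @param seeds Integer seed per repeat (default `0:(n_repeats-1)`).
#' @param train_frac Training fraction.
#' @param scale Standardize with train-fitted parameters (default TRUE).
#' @return A `ModelEvaluation` list: `per_repeat` (data frame of
#'   algorithm, repeat, seed, accuracy, auc, chosen hyperparameters),
#'   `summary` (mean and SD per algorithm), `roc` (ROC points from the
#'   first repeat), `fits` (the per-repeat unpenalized logistic fits when
#'   `"lr"` is included, for downstream [wald_report()]).
#' @examples
#' tab <- make_feature_table(hac_benchmark_spec(n_per_class = 100, seed = 1))
#' ev <- compare_models(tab[, attr(tab, "descriptors")], tab$label,
#'                      algorithms = "lr", n_repeats = 2)
#' ev$summary
#' @export
compare_models <- function(table, labels, algorithms = c("knn", "rf", "svm", "lr"),
                           n_repeats = 5, cv_folds = 5,
                           grids = default_grids(),
                           seeds = seq_len(n_repeats) - 1L,
                           train_frac = 0.8, scale = TRUE) {
  X_all <- as.matrix(as.data.frame(table))
  y <- as.numeric(labels)
  stopifnot(length(seeds) == n_repeats, all(y %in% c(0, 1)))
  algorithms <- match.arg(algorithms, c("knn", "rf", "svm", "lr"),
                          several.ok = TRUE)
  for (a in algorithms)
    if (is.null(grids[[a]]) || nrow(grids[[a]]) == 0)
      stop("empty hyperparameter grid for ", a)
  if (min(table(y)) * train_frac < cv_folds)
    stop("need at least cv_folds training samples per class")

  rows <- list(); roc_first <- list(); lr_fits <- list()
  for (r in seq_len(n_repeats)) {
    seed <- as.integer(seeds[r])
    sp <- stratified_split(y, train_frac, seed = seed)
    Xtr <- X_all[sp$train, , drop = FALSE]
    Xte <- X_all[sp$test, , drop = FALSE]
    if (scale) {
      ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, stats::sd)
      if (any(scl == 0)) stop("constant column in training split")
      Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
      Xte <- sweep(sweep(Xte, 2, ctr), 2, scl, "/")
    }
    ytr <- y[sp$train]; yte <- y[sp$test]
    folds <- .stratified_folds(ytr, cv_folds, seed)
    for (a in algorithms) {
      grid <- grids[[a]]
      cv <- withr::with_seed(seed, {
        vapply(seq_len(nrow(grid)), function(g)
          .cv_accuracy(a, grid[g, , drop = FALSE], Xtr, ytr, folds),
          numeric(1))
      })
      if (all(is.na(cv))) {
        warning("all grid cells failed for ", a, " (repeat ", r, ")")
        next
      }
      if (anyNA(cv)) warning("non-convergent grid cell(s) skipped for ", a)
      scorer <- NULL
      while (is.null(scorer) && any(!is.na(cv))) { # fall back on refit failure
        gi <- which.max(cv)
        best <- grid[gi, , drop = FALSE]
        scorer <- withr::with_seed(seed, tryCatch(
          .fit_learner(a, best, Xtr, ytr), error = function(e) NULL))
        if (is.null(scorer)) cv[gi] <- NA
      }
      if (is.null(scorer)) {
        warning("no grid cell could be refitted for ", a, " (repeat ", r, ")")
        next
      }
      p <- scorer(Xte)
      ra <- roc_auc(p, yte)
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = a, repeat_ = r, seed = seed,
        accuracy = mean((p >= 0.5) == (yte == 1)), auc = ra$auc,
        params = paste(names(best), unlist(best), sep = "=", collapse = ";"),
        stringsAsFactors = FALSE
      )
      if (r == 1) roc_first[[a]] <- ra$roc
      if (a == "lr") {
        uf <- tryCatch(fit_logistic_mle(Xtr, ytr, lambda = 0),
                       error = function(e) NULL) # e.g. separable training set
        if (!is.null(uf)) lr_fits[[length(lr_fits) + 1]] <- uf
      }
    }
  }
  per_repeat <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_repeat, per_repeat$algorithm),
    function(d) data.frame(
      algorithm = d$algorithm[1],
      mean_accuracy = mean(d$accuracy), sd_accuracy = stats::sd(d$accuracy),
      mean_auc = mean(d$auc), sd_auc = stats::sd(d$auc),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(
    list(per_repeat = per_repeat, summary = agg, roc = roc_first,
         fits = lr_fits),
    class = "ModelEvaluation"
  )
}

#' @export
print.ModelEvaluation <- function(x, ...) {
  cat("ModelEvaluation over", length(unique(x$per_repeat$repeat_)),
      "stratified splits\n")
  print(x$summary, digits = 4)
  invisible(x)
}
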