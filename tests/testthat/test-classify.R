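# Logistic MLE, Wald inference, ROC-AUC and model comparison.

test_that("the IRLS fit matches glm(binomial) coefficients and SEs", {
  tab <- make_feature_table(hac_benchmark_spec(n_per_class = 200, seed = 4))
  X <- as.matrix(tab[, attr(tab, "descriptors")]); y <- tab$label
  fit <- fit_logistic_mle(X, y)
  g <- stats::glm(y ~ X, family = stats::binomial)
  expect_equal(unname(c(fit$beta0, fit$betas)), unname(stats::coef(g)),
               tolerance = 1e-6)
  expect_equal(unname(c(fit$se0, fit$ses)),
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("fitted probabilities satisfy the logit identity exactly", {
  tab <- make_feature_table(hac_benchmark_spec(n_per_class = 80, seed = 8))
  X <- as.matrix(tab[, attr(tab, "descriptors")]); y <- tab$label
  fit <- fit_logistic_mle(X, y)
  eta <- fit$beta0 + drop(X %*% fit$betas)
  expect_equal(log(fit$fitted / (1 - fit$fitted)), eta, tolerance = 1e-8)
})

test_that("zero coefficients give probability one half everywhere", {
  fit <- structure(list(beta0 = 0, betas = c(a = 0, b = 0)),
                   class = "LogisticFit")
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_logistic(fit, X), rep(0.5, 10))
})

test_that("a known 1-D coefficient is recovered within 3 SE", {
  x <- withr::with_seed(10, rnorm(50000))
  y <- withr::with_seed(11, rbinom(50000, 1, stats::plogis(1.5 * x)))
  fit <- fit_logistic_mle(matrix(x, dimnames = list(NULL, "x")), y)
  expect_lt(abs(fit$betas[["x"]] - 1.5), 3 * fit$ses[["x"]])
})

test_that("complete separation raises a diagnostic error", {
  x <- matrix(c(-(5:1), 1:5), dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = 5)
  expect_error(fit_logistic_mle(x, y), "separat")
})

test_that("Wald arithmetic reproduces odds ratios and CIs", {
  out <- wald_table(c(-0.807, 0.622, 0), c(0.045, 0.047, 1))
  expect_equal(out$odds_ratio, c(exp(-0.807), exp(0.622), 1),
               tolerance = 1e-12)
  expect_equal(out$odds_ratio[1], 0.446, tolerance = 1e-3)
  expect_equal(out$odds_ratio[2], 1.862, tolerance = 1e-3)
  expect_equal(out$ci_lower[3], exp(-1.96), tolerance = 1e-12)
  expect_equal(out$ci_upper[3], exp(1.96), tolerance = 1e-12)
  expect_true(all(out$ci_lower < out$odds_ratio + 1e-12 &
                  out$odds_ratio < out$ci_upper + 1e-12))
  expect_equal(out$z, out$beta / out$se)
})

test_that("wald_report averages coefficients and SEs across splits", {
  fits <- lapply(1:3, function(s) {
    tab <- make_feature_table(hac_benchmark_spec(n_per_class = 150, seed = s))
    fit_logistic_mle(as.matrix(tab[, attr(tab, "descriptors")]), tab$label)
  })
  rep_ <- wald_report(fits)
  betas <- rowMeans(sapply(fits, `[[`, "betas"))
  expect_equal(rep_$beta, unname(betas), tolerance = 1e-12)
  expect_equal(rep_$odds_ratio, exp(unname(betas)), tolerance = 1e-12)
  expect_true(all(rep_$beta_sd_across_splits > 0))
})

test_that("AUC equals the pair-counting oracle, with tie handling", {
  y <- withr::with_seed(20, rbinom(20, 1, 0.5))
  y[1] <- 0; y[2] <- 1
  scores <- withr::with_seed(21, round(runif(20), 1)) # forces ties
  expect_equal(roc_auc(scores, y)$auc, pair_auc(scores, y),
               tolerance = 1e-12)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_auc(c(1:5, 6:10), rep(c(0, 1), each = 5))$auc, 1.0)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC agrees with pROC and is monotone-transform invariant", {
  skip_if_not_installed("pROC")
  y <- withr::with_seed(30, rbinom(60, 1, 0.5))
  s <- withr::with_seed(31, rnorm(60) + y)
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(roc_auc(stats::plogis(3 * s - 1), y)$auc, ours,
               tolerance = 1e-12)
})

test_that("the ROC curve runs from (0,0) to (1,1) monotonically", {
  y <- withr::with_seed(40, rbinom(50, 1, 0.4))
  s <- withr::with_seed(41, rnorm(50))
  roc <- roc_auc(s, y)$roc
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("stratified splits preserve the class ratio and partition", {
  y <- rep(c(0, 1), c(60, 40))
  sp <- stratified_split(y, 0.8, seed = 3)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sum(y[sp$train] == 1) / length(sp$train), 0.4,
               tolerance = 0.01)
  expect_identical(stratified_split(y, 0.8, seed = 3)$train, sp$train)
})

test_that("a separable table is classified perfectly by all algorithms", {
  x <- data.frame(x1 = withr::with_seed(70, c(rnorm(40, -4), rnorm(40, 4))))
  y <- rep(c(0, 1), each = 40)
  small_grids <- list(knn = data.frame(k = 3),
                      rf = data.frame(ntree = 50, maxnodes = NA),
                      svm = data.frame(cost = 1, gamma = NA),
                      lr = data.frame(lambda = c(0, 0.1)))
  ev <- suppressWarnings(compare_models(x, y, n_repeats = 2, cv_folds = 3,
                                        grids = small_grids))
  expect_equal(ev$summary$mean_accuracy, rep(1, 4))
  expect_equal(ev$summary$mean_auc, rep(1, 4))
})

test_that("permuted labels yield chance-level accuracy", {
  tab <- make_feature_table(hac_benchmark_spec(n_per_class = 100, seed = 12))
  yperm <- withr::with_seed(99, sample(tab$label))
  ev <- suppressWarnings(compare_models(
    tab[, attr(tab, "descriptors")], yperm, algorithms = "lr",
    n_repeats = 3, cv_folds = 3, grids = list(lr = data.frame(lambda = 0.1))))
  # 3 SD of a binomial on the 40-sample test set
  expect_lt(abs(ev$summary$mean_accuracy - 0.5),
            3 * sqrt(0.25 / 40) / sqrt(3) + 0.05)
})

test_that("repeat bookkeeping follows n_repeats and records seeds", {
  tab <- make_feature_table(hac_benchmark_spec(n_per_class = 60, seed = 13))
  g <- list(lr = data.frame(lambda = 0))
  ev1 <- compare_models(tab[, attr(tab, "descriptors")], tab$label,
                        algorithms = "lr", n_repeats = 1, cv_folds = 3,
                        grids = g)
  ev5 <- compare_models(tab[, attr(tab, "descriptors")], tab$label,
                        algorithms = "lr", n_repeats = 5, cv_folds = 3,
                        grids = g)
  expect_equal(nrow(ev1$per_repeat), 1)
  expect_equal(nrow(ev5$per_repeat), 5)
  expect_equal(ev5$per_repeat$seed, 0:4)
  expect_error(compare_models(tab[, attr(tab, "descriptors")], tab$label,
                              algorithms = "lr", grids = list(lr = data.frame()),
                              n_repeats = 1), "empty")
})
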