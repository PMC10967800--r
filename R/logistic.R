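# Logistic regression by maximum likelihood (IRLS) with Wald inference.

#' Fit a logistic regression by maximum likelihood
#'
#' The probability of the positive class (HAC = 1) given descriptors
#' \eqn{x} is modelled as
#' \deqn{P(y = 1 \mid x) = \frac{e^{\beta_0 + \sum_i \beta_i x_i}}
#'   {1 + e^{\beta_0 + \sum_i \beta_i x_i}},}
#' equivalently \eqn{\ln[P/(1-P)] = \beta_0 + \sum_i \beta_i x_i}.
#' Coefficients are estimated by iteratively reweighted least squares to
#' log-likelihood convergence; standard errors come from the inverse
#' observed Fisher information, Wald z = beta/SE, two-sided normal
#' p-values.  An optional ridge penalty `lambda` is available for the
#' model-comparison learner; inference (SEs, odds ratios) is only
#' reported for the unpenalized fit.
#'
#' @param X Numeric matrix or data frame of predictors (no intercept
#'   column).
#' @param y 0/1 response vector.
#' @param lambda Ridge penalty on the non-intercept coefficients
#'   (0 = plain MLE).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum IRLS iterations.
#' @return A `LogisticFit`: `beta0`, `betas`, `ses`, `z`, `p`, `or_`
#'   (exp(beta)), `ci95` (exp(beta -/+ 1.96 SE)), `fitted`, `vcov`,
#'   `loglik`, `converged`, `lambda`.
#' @examples
#' tab <- make_feature_table(hac_benchmark_spec(n_per_class = 150, seed = 1))
#' fit <- fit_logistic_mle(tab[, attr(tab, "descriptors")], tab$label)
#' sign(fit$betas)
#' @export
fit_logistic_mle <- function(X, y, lambda = 0, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- c(0, rep(lambda, p - 1))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    H <- XtW %*% Xd + diag(pen, p)
    beta_new <- tryCatch(solve(H, XtW %*% z),
                         error = function(e)
                           stop("singular information matrix: ",
                                "predictors may be exactly collinear"))
    beta <- drop(beta_new)
    if (any(!is.finite(beta)) || sqrt(sum(beta^2)) > 1e4)
      stop("coefficients diverge: data are (quasi-)completely separated")
    eta <- drop(Xd %*% beta)
    log1pe <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))) # stable
    ll <- sum(y * eta - log1pe) - sum(pen * beta^2) / 2
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  mu <- stats::plogis(drop(Xd %*% beta))
  if (all(abs(mu - y) < 1e-6) && sqrt(sum(beta^2)) > 10)
    stop("coefficients diverge: data are completely separated")
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(Xd * w) %*% Xd + diag(pen, p)
  vcov <- solve(info)
  ses <- sqrt(diag(vcov))
  betas <- beta[-1]
  se_b <- ses[-1]
  structure(
    list(
      beta0 = beta[1], betas = stats::setNames(betas, colnames(X)),
      se0 = ses[1], ses = stats::setNames(se_b, colnames(X)),
      z = betas / se_b,
      p = 2 * stats::pnorm(-abs(betas / se_b)),
      or_ = exp(betas),
      ci95 = cbind(lower = exp(betas - 1.96 * se_b),
                   upper = exp(betas + 1.96 * se_b)),
      fitted = mu, vcov = vcov, loglik = sum(y * log(pmax(mu, 1e-300)) +
                                             (1 - y) * log(pmax(1 - mu, 1e-300))),
      converged = converged, lambda = lambda
    ),
    class = "LogisticFit"
  )
}

#' Predicted class-1 probabilities from a logistic fit
#'
#' @param fit A `LogisticFit`.
#' @param X New predictor matrix with the same columns the model was
#'   fitted on.
#' @return Probabilities in (0, 1).
#' @export
predict_logistic <- function(fit, X) {
  X <- as.matrix(X)
  unname(stats::plogis(drop(fit$beta0 + X %*% fit$betas)))
}

#' Wald inference table (odds ratios with 95% confidence intervals)
#'
#' `wald_table()` performs the arithmetic on given coefficients: odds
#' ratio exp(beta), CI bounds exp(beta -/+ 1.96 SE), z = beta/SE,
#' two-sided p.  `wald_report()` applies it to one `LogisticFit`, or
#' averages coefficients and standard errors across a list of fits from
#' repeated training splits before exponentiating (both the mean Wald SE
#' and the across-split SD of the coefficients are reported).
#'
#' @param beta,se Numeric vectors of coefficients and standard errors.
#' @param names Optional descriptor names.
#' @return Data frame `descriptor`, `beta`, `se`, `z`, `p`, `odds_ratio`,
#'   `ci_lower`, `ci_upper` (plus `beta_sd_across_splits` from
#'   `wald_report` on multiple fits).
#' @examples
#' ref <- reference_model_coefficients()
#' wald_table(ref$beta, ref$se, ref$descriptor)
#' @export
wald_table <- function(beta, se, names = NULL) {
  stopifnot(length(beta) == length(se), all(se > 0))
  if (is.null(names)) names <- paste0("x", seq_along(beta))
  data.frame(
    descriptor = names,
    beta = beta, se = se, z = beta / se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    odds_ratio = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    stringsAsFactors = FALSE
  )
}

#' @rdname wald_table
#' @param fit A `LogisticFit`, or a list of them (one per training split).
#' @export
wald_report <- function(fit) {
  if (inherits(fit, "LogisticFit")) fit <- list(fit)
  stopifnot(length(fit) >= 1, all(vapply(fit, inherits, logical(1),
                                         "LogisticFit")))
  if (any(!vapply(fit, `[[`, logical(1), "converged")))
    warning("some fits did not converge; inference may be unreliable")
  betas <- do.call(rbind, lapply(fit, `[[`, "betas"))
  ses <- do.call(rbind, lapply(fit, `[[`, "ses"))
  out <- wald_table(colMeans(betas), colMeans(ses), colnames(betas))
  out$beta_sd_across_splits <- apply(betas, 2, stats::sd)
  out
}
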