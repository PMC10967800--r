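# Pearson screening, category-aware collinearity elimination,
# Cook's-distance outlier removal and standardization.

#' Default descriptor categories
#'
#' Groups the ten descriptors by the physical property they measure;
#' collinearity elimination operates within these groups.
#'
#' @return Named character vector, descriptor -> category.
#' @export
descriptor_categories <- function() {
  c(s_phobic_avg = "hydrophobicity",
    s_pos_area = "charge", s_neg_area = "charge", s_charge_avg = "charge",
    s_ah = "structure", s_bs = "structure", s_do = "structure",
    s_sf = "structure",
    norm_s_b = "flexibility",
    fd = "geometry")
}

#' Pearson screening with category-aware collinearity elimination
#'
#' Two passes over the descriptor table.  (1) Significance against the
#' class label: the point-biserial correlation (Pearson r with the 0/1
#' label, t-test on n - 2 df) must reach `alpha`, otherwise the
#' descriptor is dropped as `nonsignificant_vs_target`.  (2) Within each
#' descriptor category, while any pair of surviving descriptors has
#' `|r| >=` `collinearity_threshold`, the descriptor with the largest
#' mean absolute within-category correlation is dropped as
#' `collinear_in_category` (ties broken by name order).  Constant columns
#' have undefined r and are dropped with a warning.
#'
#' @param table Data frame of descriptor columns (numeric).
#' @param labels 0/1 vector, one per row.
#' @param alpha Significance level for the label screen.
#' @param collinearity_threshold Absolute within-category correlation cut.
#' @param categories Descriptor -> category map; descriptors missing from
#'   it form their own singleton categories.
#' @return List with `report` (a `CorrelationReport`: `r_matrix`,
#'   `p_matrix`, `r_with_label`, `p_with_label`) and `result` (a
#'   `PreprocessResult`: `kept`, `dropped` data frame with reasons).
#' @export
pearson_screen <- function(table, labels, alpha = 0.05,
                           collinearity_threshold = 0.8,
                           categories = descriptor_categories()) {
  x <- as.data.frame(table)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  stopifnot(nrow(x) >= 3, ncol(x) >= 2, length(labels) == nrow(x))
  y <- as.numeric(labels)

  dropped <- data.frame(descriptor = character(0), reason = character(0))
  constant <- vapply(x, function(col) stats::sd(col) == 0, logical(1))
  if (any(constant)) {
    warning("constant descriptor column(s) dropped: ",
            paste(names(x)[constant], collapse = ", "))
    dropped <- rbind(dropped, data.frame(
      descriptor = names(x)[constant], reason = "nonsignificant_vs_target"))
    x <- x[, !constant, drop = FALSE]
  }

  r_with_label <- vapply(x, function(col) stats::cor(col, y), numeric(1))
  p_with_label <- vapply(x, function(col)
    stats::cor.test(col, y)$p.value, numeric(1))
  r_matrix <- stats::cor(x)
  n <- nrow(x)
  tstat <- r_matrix * sqrt((n - 2) / pmax(1 - r_matrix^2, 1e-300))
  p_matrix <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p_matrix) <- 0

  nonsig <- names(x)[p_with_label >= alpha]
  if (length(nonsig) > 0)
    dropped <- rbind(dropped, data.frame(descriptor = nonsig,
                                         reason = "nonsignificant_vs_target"))
  kept <- setdiff(names(x), nonsig)

  cat_of <- function(d) {
    ifelse(d %in% names(categories), unname(categories[d]), d)
  }
  repeat {
    cats <- cat_of(kept)
    worst <- NULL; worst_mean <- -Inf
    for (ct in unique(cats)) {
      members <- sort(kept[cats == ct])
      if (length(members) < 2) next
      sub <- abs(r_matrix[members, members, drop = FALSE])
      diag(sub) <- NA
      if (max(sub, na.rm = TRUE) < collinearity_threshold) next
      means <- rowMeans(sub, na.rm = TRUE)
      cand <- members[which.max(means)] # name order breaks exact ties
      if (means[[cand]] > worst_mean) { worst <- cand; worst_mean <- means[[cand]] }
    }
    if (is.null(worst)) break
    dropped <- rbind(dropped, data.frame(descriptor = worst,
                                         reason = "collinear_in_category"))
    kept <- setdiff(kept, worst)
  }

  list(
    report = structure(
      list(r_matrix = r_matrix, p_matrix = p_matrix,
           r_with_label = r_with_label, p_with_label = p_with_label),
      class = "CorrelationReport"),
    result = structure(
      list(kept = kept, dropped = dropped),
      class = "PreprocessResult")
  )
}

#' Cook's-distance removal of influential outliers
#'
#' Fits the unpenalized logistic model on the full table, computes
#' leverages from the weighted hat matrix, Pearson residuals, and Cook's
#' distances \eqn{D_j = r_j^2 h_j / (p (1 - h_j)^2)}, and removes the
#' observations that are simultaneously highly influential
#' (\eqn{D_j >} `cooks_threshold`, default 4/n) and outlying
#' (standardized Pearson residual \eqn{|r_j / \sqrt{1-h_j}| >}
#' `resid_threshold`).  Runs once, without iterative re-removal.
#'
#' @param table Numeric descriptor data frame.
#' @param labels 0/1 vector.
#' @param cooks_threshold Influence cut; `NULL` uses 4/n.
#' @param resid_threshold Standardized-residual cut.
#' @return List `removed` (row indices), `ids` (rownames if any),
#'   `cooks`, `leverage`, `std_resid`, `threshold`.
#' @export
cooks_outlier_removal <- function(table, labels, cooks_threshold = NULL,
                                  resid_threshold = 2.0) {
  x <- as.matrix(as.data.frame(table))
  y <- as.numeric(labels)
  n <- nrow(x)
  if (is.null(cooks_threshold)) cooks_threshold <- 4 / n
  fit <- tryCatch(fit_logistic_mle(x, y),
                  error = function(e)
                    stop("logistic fit failed (", conditionMessage(e),
                         "); consider standardizing the table first"))
  X <- cbind(1, x)
  p_hat <- fit$fitted
  w <- pmax(p_hat * (1 - p_hat), 1e-10)
  XtWX_inv <- fit$vcov # (X'WX)^{-1}
  # leverage h_j = w_j x_j' (X'WX)^{-1} x_j
  h <- rowSums((X %*% XtWX_inv) * X) * w
  pr <- (y - p_hat) / sqrt(w)            # Pearson residuals
  std <- pr / sqrt(pmax(1 - h, 1e-12))   # standardized
  p_par <- ncol(X)
  cooks <- pr^2 * h / (p_par * (1 - h)^2)
  removed <- which(cooks > cooks_threshold & abs(std) > resid_threshold)
  list(removed = removed, ids = rownames(x)[removed], cooks = cooks,
       leverage = h, std_resid = std, threshold = cooks_threshold)
}

#' Standardize descriptors with train-set parameters
#'
#' z = (x - mean) / sd, with mean and sd estimated on the fitting rows
#' only and applied to every row (the test partition is scaled with the
#' training parameters).
#'
#' @param table Numeric data frame.
#' @param fit_rows Row indices used to estimate the scaler (default: all).
#' @return List `scaled` (data frame), `center`, `scale`.
#' @export
standardize <- function(table, fit_rows = seq_len(nrow(table))) {
  x <- as.data.frame(table)
  stopifnot(length(fit_rows) > 0)
  ctr <- vapply(x[fit_rows, , drop = FALSE], mean, numeric(1))
  scl <- vapply(x[fit_rows, , drop = FALSE], stats::sd, numeric(1))
  if (any(scl == 0))
    stop("zero standard deviation on the fitting rows for: ",
         paste(names(x)[scl == 0], collapse = ", "))
  scaled <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                                 x, ctr, scl, SIMPLIFY = FALSE))
  rownames(scaled) <- rownames(x)
  list(scaled = scaled, center = ctr, scale = scl)
}

#' @rdname standardize
#' @param scaler A list with `center` and `scale` (as returned above).
#' @export
unstandardize <- function(table, scaler) {
  x <- as.data.frame(table)
  as.data.frame(mapply(function(col, m, s) col * s + m,
                       x, scaler$center[names(x)], scaler$scale[names(x)],
                       SIMPLIFY = FALSE))
}
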