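# ROC analysis with DeLong inference.
#
# Direction convention: `direction = "low"` means low predictor values
# indicate the positive class (a lesion is called positive when its score
# is <= threshold); `direction = "high"` means the opposite (called
# positive when score > threshold). The orientation is always explicit and
# never auto-flipped: an AUC below 0.5 is reported as such.
#
# With midranks, the placement value of positive subject i is
#   V10_i = P_hat(X_neg < x_i) + 0.5 P_hat(X_neg = x_i)
# (direction "high"), computable as (R_i - R10_i)/n_neg from the combined
# and within-group midranks. The AUC is the mean placement, identical to
# the tie-corrected Mann-Whitney statistic divided by n_pos * n_neg, and
# the DeLong variance is var(V10)/n_pos + var(V01)/n_neg.

check_roc_input <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop("predictor and labels must have the same length", call. = FALSE)
  }
  labels <- as.logical(labels)
  if (any(is.na(values)) || any(is.na(labels))) {
    stop("predictor values and labels must be non-missing", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("predictor values must be finite", call. = FALSE)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present in 'labels'", call. = FALSE)
  }
  labels
}

# Placement values for one predictor; list(auc, v10, v01).
delong_placements <- function(values, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- check_roc_input(values, labels)
  m <- sum(labels)
  n <- sum(!labels)
  r_all <- rank(values, ties.method = "average")
  r_pos <- rank(values[labels], ties.method = "average")
  r_neg <- rank(values[!labels], ties.method = "average")
  v10 <- (r_all[labels] - r_pos) / n      # P(neg < pos_i) + ties/2
  v01 <- 1 - (r_all[!labels] - r_neg) / m # P(pos > neg_j) + ties/2
  if (direction == "low") {
    v10 <- 1 - v10
    v01 <- 1 - v01
  }
  list(auc = mean(v10), v10 = v10, v01 = v01, n_pos = m, n_neg = n)
}

#' Empirical ROC curve
#'
#' One curve point per achievable threshold (ties grouped), including the
#' degenerate endpoints where everything or nothing is called positive.
#'
#' @param values Numeric predictor (e.g. a complexity score).
#' @param labels Logical (or 0/1) indicator of the positive class.
#' @param direction `"low"` if low values predict the positive class
#'   (positivity criterion `value <= threshold`), `"high"` otherwise
#'   (criterion `value > threshold`).
#' @return A data frame of class `cto_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, and attributes `direction`, `n_pos`,
#'   `n_neg`.
#' @examples
#' roc_curve(c(0, 1, 1, 2, 2, 3), c(1, 1, 1, 0, 0, 0), direction = "low")
#' @export
roc_curve <- function(values, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- check_roc_input(values, labels)
  pos <- values[labels]
  neg <- values[!labels]
  thr <- c(-Inf, sort(unique(values)))
  if (direction == "low") {
    sens <- vapply(thr, function(t) mean(pos <= t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg > t), numeric(1))
  } else {
    sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
    spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  }
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  structure(out, class = c("cto_roc", "data.frame"),
            direction = direction, n_pos = length(pos), n_neg = length(neg),
            values = values, labels = labels)
}

#' AUC with DeLong variance, confidence interval and test against 0.5
#'
#' The AUC is the tie-corrected Mann-Whitney statistic scaled to `[0, 1]`;
#' its variance comes from the DeLong placement-value decomposition. The
#' 95% interval is a normal interval on the logit scale (back-transformed,
#' hence always inside `[0, 1]`); the test of AUC = 0.5 is a two-sided z
#' test with the DeLong standard error.
#'
#' @param x Either a `cto_roc` object or a numeric predictor vector.
#' @param labels,direction Used when `x` is a numeric vector; see
#'   [roc_curve()].
#' @param conf_level Confidence level for the interval. Default 0.95.
#' @return List of class `cto_auc`: `auc`, `variance`, `se`, `ci_low`,
#'   `ci_high`, `p_vs_half`, `n_pos`, `n_neg`, `direction`.
#' @examples
#' roc_auc(c(1, 2, 2, 3), c(1, 1, 0, 0), direction = "low")
#' @export
roc_auc <- function(x, labels = NULL, direction = c("low", "high"),
                    conf_level = 0.95) {
  if (inherits(x, "cto_roc")) {
    values <- attr(x, "values")
    labels <- attr(x, "labels")
    direction <- attr(x, "direction")
  } else {
    values <- x
    direction <- match.arg(direction)
  }
  pl <- delong_placements(values, labels, direction)
  m <- pl$n_pos
  n <- pl$n_neg
  v <- if (m > 1) stats::var(pl$v10) / m else 0
  v <- v + if (n > 1) stats::var(pl$v01) / n else 0
  se <- sqrt(v)
  auc <- pl$auc
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (se == 0 || auc <= 0 || auc >= 1) {
    ci <- c(auc, auc)
  } else {
    lse <- se / (auc * (1 - auc))
    ci <- stats::plogis(stats::qlogis(auc) + c(-1, 1) * z * lse)
  }
  p_half <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(auc - 0.5) / se)
  }
  structure(list(auc = auc, variance = v, se = se,
                 ci_low = ci[1], ci_high = ci[2], p_vs_half = p_half,
                 conf_level = conf_level,
                 n_pos = m, n_neg = n, direction = direction),
            class = "cto_auc")
}

#' @export
print.cto_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), p vs 0.5 = %.3g [direction: %s]\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_vs_half,
              x$direction))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Both predictors must be measured on the same subjects in the same order.
#' The covariance of the two AUC estimates is computed from the paired
#' placement values, giving z = (AUC_a - AUC_b)/se(difference) and a
#' two-sided normal p-value. When the difference and its variance are both
#' zero (e.g. identical predictors) the p-value is 1 by convention.
#'
#' @param predictor_a,predictor_b Numeric predictors on the same subjects.
#' @param labels Positive-class indicator shared by both.
#' @param direction Orientation shared by both predictors; see [roc_curve()].
#' @return List of class `cto_delong`: `auc_a`, `auc_b`, `difference`,
#'   `variance_of_difference`, `z`, `p_two_sided`.
#' @export
delong_paired_test <- function(predictor_a, predictor_b, labels,
                               direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (length(predictor_a) != length(predictor_b)) {
    stop("paired predictors must have the same length", call. = FALSE)
  }
  pa <- delong_placements(predictor_a, labels, direction)
  pb <- delong_placements(predictor_b, labels, direction)
  m <- pa$n_pos
  n <- pa$n_neg
  s10 <- if (m > 1) stats::cov(cbind(pa$v10, pb$v10)) else matrix(0, 2, 2)
  s01 <- if (n > 1) stats::cov(cbind(pa$v01, pb$v01)) else matrix(0, 2, 2)
  vcov_auc <- s10 / m + s01 / n
  diff <- pa$auc - pb$auc
  vdiff <- max(0, vcov_auc[1, 1] + vcov_auc[2, 2] - 2 * vcov_auc[1, 2])
  if (vdiff == 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    z <- diff / sqrt(vdiff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
                 variance_of_difference = vdiff, z = z, p_two_sided = p,
                 n_pos = m, n_neg = n, direction = direction),
            class = "cto_delong")
}

#' @export
print.cto_delong <- function(x, ...) {
  cat(sprintf("Paired DeLong: AUC %.3f vs %.3f, diff %.3f, z = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$difference, x$z, x$p_two_sided))
  invisible(x)
}

#' Youden-index optimal cutpoint
#'
#' Maximises J = sensitivity + specificity - 1 over the achievable
#' thresholds of a ROC curve. Ties in J are broken toward the point with
#' higher sensitivity (screening use); any remaining tie goes to the
#' threshold closest to the middle of the threshold list (the less extreme
#' criterion), then to the lower threshold, so the result is deterministic.
#'
#' @param roc A `cto_roc` from [roc_curve()].
#' @return List of class `cto_cutoff`: `criterion` (e.g. `"<=3"` when low
#'   values predict positive, `">3"` otherwise), `threshold`, `sensitivity`
#'   and `specificity` (percentages), `youden_j`, `direction`.
#' @examples
#' youden_cutoff(roc_curve(c(0, 1, 1, 2, 2, 3), c(1, 1, 1, 0, 0, 0), "low"))
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "cto_roc"))
  direction <- attr(roc, "direction")
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-9) # float-tolerant tie detection
  if (length(best) > 1) {
    best <- best[roc$sensitivity[best] >= max(roc$sensitivity[best]) - 1e-9]
  }
  if (length(best) > 1) {
    centre <- (1 + nrow(roc)) / 2
    d <- abs(best - centre)
    best <- best[d == min(d)]
    best <- best[1]
  }
  thr <- roc$threshold[best]
  fmt <- function(t) format(t, trim = TRUE, digits = 6)
  criterion <- if (!is.finite(thr)) {
    if (direction == "low") "none positive" else "all positive"
  } else if (direction == "low") {
    paste0("<=", fmt(thr))
  } else {
    paste0(">", fmt(thr))
  }
  structure(list(criterion = criterion, threshold = thr,
                 sensitivity = 100 * roc$sensitivity[best],
                 specificity = 100 * roc$specificity[best],
                 youden_j = j[best], direction = direction),
            class = "cto_cutoff")
}

#' @export
print.cto_cutoff <- function(x, ...) {
  cat(sprintf("Best cutpoint %s: sensitivity %.1f%%, specificity %.1f%% (J = %.3f)\n",
              x$criterion, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}
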