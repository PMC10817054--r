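# Two-group univariate tests and agreement statistics.
#
# Fisher's exact test, the large-sample Mann-Whitney branch and Student's t
# delegate to the base R implementations (which use exactly the conventions
# adopted here: probability-mass two-sided Fisher p, tie-corrected normal
# approximation with continuity correction, pooled variance). The exact
# small-sample Mann-Whitney branch is enumerated directly because it must
# handle ties.

#' Cohen's kappa
#'
#' Chance-corrected agreement between two categorical raters:
#' kappa = (p_o - p_e) / (1 - p_e), with expected agreement p_e from the
#' product of the marginal distributions. Perfect agreement on a single
#' category (p_o = p_e = 1) returns 1 by convention.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors.
#' @return Kappa, a single number (at most 1; can be negative).
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)) # 0.5
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) == 0 || length(ratings_b) == 0) {
    stop("cohens_kappa: empty ratings", call. = FALSE)
  }
  if (length(ratings_a) != length(ratings_b)) {
    stop("cohens_kappa: ratings must have equal length", call. = FALSE)
  }
  keep <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- as.character(ratings_a[keep])
  b <- as.character(ratings_b[keep])
  if (!length(a)) stop("cohens_kappa: no complete pairs", call. = FALSE)
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, lev), factor(b, lev))
  p <- tab / sum(tab)
  p_o <- sum(diag(p))
  p_e <- sum(rowSums(p) * colSums(p))
  if (p_e == 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table. A table with
#' an empty margin carries no information and returns p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(6, 53, 17, 34)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_exact_2x2: cells must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney U test
#'
#' Two-sided test for a location difference between two independent
#' samples. For combined sample size up to `exact_limit` the p-value is
#' computed by exhaustive enumeration of all group assignments (valid in
#' the presence of ties); beyond that, the tie-corrected normal
#' approximation with continuity correction is used. U counts, over all
#' cross-pairs, the times an `x` exceeds a `y` (ties count one half).
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest combined size for the exact branch. Default 12.
#' @return List with `u`, `p_two_sided`, `method`.
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
mann_whitney_test <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y)) {
    stop("mann_whitney_test: both samples must be non-empty", call. = FALSE)
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  n1 <- length(x)
  n2 <- length(y)
  u_of <- function(xx, yy) {
    r <- rank(c(xx, yy), ties.method = "average")
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  u <- u_of(x, y)
  if (n1 + n2 <= exact_limit) {
    pool <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    centre <- n1 * n2 / 2
    us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
    p <- mean(abs(us - centre) >= abs(u - centre) - 1e-9)
    return(list(u = u, p_two_sided = p, method = "exact enumeration"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  list(u = u, p_two_sided = wt$p.value,
       method = "normal approximation, tie-corrected, continuity-corrected")
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with n1 + n2 - 2 degrees of freedom. Degenerate inputs with
#' zero pooled variance are flagged: equal means give t = 0, p = 1;
#' unequal means give an infinite t with p = 0 and `degenerate = TRUE`.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @return List with `t`, `df`, `p_two_sided`, `degenerate`.
#' @export
students_t_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("students_t_test: need at least 2 observations per group", call. = FALSE)
  }
  df <- length(x) + length(y) - 2
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = df, p_two_sided = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df,
                p_two_sided = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, degenerate = FALSE)
}
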