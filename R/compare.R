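# Cohort-level reporting: two-group univariate comparisons and the
# score-by-endpoint diagnostic accuracy table with pairwise DeLong
# comparisons.

#' Two-group univariate comparison table
#'
#' One row per variable, split by a binary grouping flag. Continuous
#' variables are summarised as median (IQR) and compared with the
#' Mann-Whitney U test (or mean +/- SD and Student's t when
#' `continuous_test = "t"`); categorical (binary) variables as n (%) with
#' Fisher's exact test. No multiplicity adjustment is applied; p-values are
#' reported raw.
#'
#' @param data Data frame.
#' @param group Name of a logical/0-1 column splitting the cohort.
#' @param variables Named character vector: names are column names, values
#'   are `"continuous"` or `"categorical"`.
#' @param continuous_test `"mann_whitney"` (default) or `"t"`.
#' @param digits Decimals for the printed summaries. Default 1.
#' @return Data frame with columns `variable`, `type`, `group1`, `group2`
#'   (formatted summaries, group1 = `group` TRUE), `p_value`, `test`.
#' @export
compare_groups <- function(data, group, variables,
                           continuous_test = c("mann_whitney", "t"),
                           digits = 1) {
  continuous_test <- match.arg(continuous_test)
  stopifnot(is.data.frame(data), group %in% names(data))
  g <- as_flag(data[[group]], group)
  if (any(is.na(g))) stop("grouping column must be non-missing", call. = FALSE)
  bad <- !variables %in% c("continuous", "categorical")
  if (any(bad)) {
    stop("unknown variable type(s): ",
         paste(unique(variables[bad]), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(names(variables), names(data))
  if (length(miss)) {
    stop("variable(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(names(variables), function(v) {
    type <- variables[[v]]
    x1 <- data[[v]][g]
    x2 <- data[[v]][!g]
    if (type == "continuous") {
      x1 <- as.numeric(x1); x2 <- as.numeric(x2)
      if (continuous_test == "mann_whitney") {
        p <- mann_whitney_test(x1, x2)$p_two_sided
        test <- "Mann-Whitney U"
        fmt <- function(x) {
          q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
          sprintf("%.*f (%.*f-%.*f)", digits, q[2], digits, q[1], digits, q[3])
        }
      } else {
        p <- students_t_test(x1, x2)$p_two_sided
        test <- "Student's t"
        fmt <- function(x) sprintf("%.*f +/- %.*f", digits, mean(x),
                                   digits, stats::sd(x))
      }
      data.frame(variable = v, type = type,
                 group1 = fmt(x1), group2 = fmt(x2),
                 p_value = p, test = test, stringsAsFactors = FALSE)
    } else {
      f1 <- as_flag(x1, v); f2 <- as_flag(x2, v)
      a <- sum(f1, na.rm = TRUE); b <- sum(!f1, na.rm = TRUE)
      cc <- sum(f2, na.rm = TRUE); d <- sum(!f2, na.rm = TRUE)
      fmt <- function(k, n) sprintf("%d (%.*f%%)", k, digits,
                                    if (n > 0) 100 * k / n else 0)
      data.frame(variable = v, type = type,
                 group1 = fmt(a, a + b), group2 = fmt(cc, cc + d),
                 p_value = fisher_exact_2x2(a, b, cc, d),
                 test = "Fisher exact", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Direction conventions for the study endpoints
#'
#' For time-efficient crossing and final procedural success the positive
#' class is success, which low complexity scores predict (criteria render
#' as `<=k`); for the need of any non-AW strategy the positive class is
#' that need, which high scores predict (`>k`).
#'
#' @return Named character vector mapping endpoint column name to
#'   `"low"`/`"high"`.
#' @export
endpoint_directions <- function() {
  c(time_efficient_crossing = "low",
    final_procedural_success = "low",
    any_non_aw = "high")
}

#' Diagnostic accuracy table (scores x endpoints)
#'
#' For every score column and endpoint column: AUC with DeLong 95% CI and
#' p-value against 0.5, plus the Youden-index best cutpoint with its
#' sensitivity and specificity. Endpoints with a single observed class are
#' marked uncomputable rather than dropped.
#'
#' @param scores Data frame of score totals (e.g. from [score_table()]).
#' @param endpoints Data frame of endpoint flags (from [derive_endpoints()]);
#'   rows must align with `scores`.
#' @param score_cols Score columns to evaluate. Defaults to the five systems.
#' @param endpoint_cols Endpoint columns. Defaults to the three study
#'   endpoints.
#' @param directions Named `"low"`/`"high"` per endpoint; defaults to
#'   [endpoint_directions()].
#' @return Data frame, one row per score x endpoint, with columns `score`,
#'   `endpoint`, `direction`, `auc`, `ci_low`, `ci_high`, `criterion`,
#'   `sensitivity`, `specificity`, `youden_j`, `p_vs_half`, `note`.
#' @export
accuracy_table <- function(scores, endpoints,
                           score_cols = c("jcto_ca", "ct_rector", "kcct",
                                          "jcto_ccta", "recharge_ccta"),
                           endpoint_cols = names(endpoint_directions()),
                           directions = endpoint_directions()) {
  stopifnot(nrow(scores) == nrow(endpoints))
  rows <- list()
  for (ep in endpoint_cols) {
    lab <- as.logical(endpoints[[ep]])
    dir <- directions[[ep]] %||% "low"
    for (sc in score_cols) {
      val <- scores[[sc]]
      keep <- !is.na(val) & !is.na(lab)
      row <- data.frame(score = sc, endpoint = ep, direction = dir,
                        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        criterion = NA_character_, sensitivity = NA_real_,
                        specificity = NA_real_, youden_j = NA_real_,
                        p_vs_half = NA_real_, note = "",
                        stringsAsFactors = FALSE)
      if (!any(lab[keep]) || all(lab[keep])) {
        row$note <- "uncomputable: single-class endpoint"
      } else {
        a <- roc_auc(val[keep], lab[keep], dir)
        cut <- youden_cutoff(roc_curve(val[keep], lab[keep], dir))
        row$auc <- a$auc
        row$ci_low <- a$ci_low
        row$ci_high <- a$ci_high
        row$p_vs_half <- a$p_vs_half
        row$criterion <- cut$criterion
        row$sensitivity <- cut$sensitivity
        row$specificity <- cut$specificity
        row$youden_j <- cut$youden_j
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' All pairwise DeLong comparisons for one endpoint
#'
#' @inheritParams accuracy_table
#' @param endpoint Single endpoint column name.
#' @return Data frame with one row per unordered score pair: AUCs,
#'   difference, z and raw two-sided p (no multiplicity adjustment; the
#'   number of comparisons is in attribute `n_comparisons`).
#' @export
delong_pairwise <- function(scores, endpoints, endpoint,
                            score_cols = c("jcto_ca", "ct_rector", "kcct",
                                           "jcto_ccta", "recharge_ccta"),
                            directions = endpoint_directions()) {
  lab <- as.logical(endpoints[[endpoint]])
  dir <- directions[[endpoint]] %||% "low"
  keep <- Reduce(`&`, lapply(score_cols, function(sc) !is.na(scores[[sc]])))
  keep <- keep & !is.na(lab)
  pairs <- utils::combn(score_cols, 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- delong_paired_test(scores[[pr[1]]][keep], scores[[pr[2]]][keep],
                            lab[keep], dir)
    data.frame(endpoint = endpoint, score_a = pr[1], score_b = pr[2],
               auc_a = d$auc_a, auc_b = d$auc_b, difference = d$difference,
               z = d$z, p_two_sided = d$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_comparisons") <- ncol(pairs)
  out
}
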