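# CSV interchange, validation, interobserver agreement, and the top-level
# pipeline tying scoring -> endpoints -> diagnostics -> report tables.
#
# CSV is the sole interchange format (RFC-4180, UTF-8, "." decimal);
# booleans are encoded 0/1, lengths in mm, angles in degrees. Report files
# carry a provenance header as comment lines starting with "#".

#' Lesion CSV schema
#'
#' Column names and types of the per-lesion table: identifier, the CCTA
#' feature block, the clinical block, and the angiographic block.
#' @return Named character vector column -> type
#'   (`"id"`, `"flag"`, `"numeric"`, `"arc"`).
#' @export
lesion_schema <- function() {
  c(lesion_id = "id",
    blunt_cap_proximal = "flag",
    blunt_cap_entry_or_exit = "flag",
    proximal_side_branch = "flag",
    occlusion_length_mm = "numeric",
    max_bend_deg = "numeric",
    any_calcification = "flag",
    calc_area_frac_ge_50 = "flag",
    calc_arc_max_deg = "arc",
    calc_area_frac_100 = "flag",
    multiple_occlusions = "flag",
    diseased_distal_landing_zone = "flag",
    duration_gt_12mo_or_unknown = "flag",
    reattempt = "flag",
    prior_cabg_to_cto_vessel = "flag",
    angio_blunt_stump = "flag",
    angio_any_calcification = "flag",
    angio_max_bend_deg = "numeric",
    angio_occlusion_length_mm = "numeric")
}

#' Procedure CSV schema
#' @return Named character vector column -> type.
#' @export
procedure_schema <- function() {
  c(lesion_id = "id",
    gw_crossing_time_min = "numeric",
    used_aw = "flag",
    used_adr = "flag",
    used_rw = "flag",
    used_rdr = "flag",
    final_strategy = "strategy",
    residual_stenosis_pct = "numeric",
    timi_flow = "numeric",
    switch_time_min = "numeric")
}

validate_against_schema <- function(df, schema, what) {
  unknown <- setdiff(names(df), names(schema))
  if (length(unknown)) {
    stop(sprintf("%s table: unknown column(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop(sprintf("%s table: missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "flag") df[[col]] <- as_flag(df[[col]], col)
    if (type == "numeric") df[[col]] <- as.numeric(df[[col]])
    if (type == "arc") check_arc(as.character(df[[col]]))
  }
  df
}

#' Read a cohort bundle from CSV files
#'
#' Reads, types and validates the lesion and procedure tables (and an
#' optional second-reader lesion table for interobserver agreement).
#' Validation failures name the offending rows.
#'
#' @param lesions_path,procedures_path CSV paths. `procedures_path` may be
#'   `NULL` for a scores-only bundle.
#' @param second_reader_path Optional CSV with a second reader's lesion
#'   features on a subset of lesions.
#' @return List of class `cto_bundle` with `lesions`, `procedures`
#'   (possibly `NULL`), `second_reader` (possibly `NULL`).
#' @export
read_cohort <- function(lesions_path, procedures_path = NULL,
                        second_reader_path = NULL) {
  lesions <- utils::read.csv(lesions_path, stringsAsFactors = FALSE,
                             comment.char = "#")
  lesions <- validate_against_schema(lesions, lesion_schema(), "lesion")
  procedures <- NULL
  if (!is.null(procedures_path)) {
    procedures <- utils::read.csv(procedures_path, stringsAsFactors = FALSE,
                                  comment.char = "#")
    procedures <- validate_against_schema(procedures, procedure_schema(),
                                          "procedure")
    procedures$final_strategy <- as.character(procedures$final_strategy)
    procedures <- validate_procedures(procedures)
    if (!identical(sort(lesions$lesion_id), sort(procedures$lesion_id))) {
      stop("lesion and procedure tables must join 1:1 on lesion_id",
           call. = FALSE)
    }
  }
  second <- NULL
  if (!is.null(second_reader_path)) {
    second <- utils::read.csv(second_reader_path, stringsAsFactors = FALSE,
                              comment.char = "#")
    second <- validate_against_schema(second, lesion_schema(), "second-reader")
    if (!any(second$lesion_id %in% lesions$lesion_id)) {
      stop("second-reader table shares no lesion_id with the lesion table",
           call. = FALSE)
    }
  }
  structure(list(lesions = lesions, procedures = procedures,
                 second_reader = second),
            class = "cto_bundle")
}

#' Write a cohort to CSV files
#'
#' @param cohort A `cto_cohort` or `cto_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`lesions.csv`, `procedures.csv`,
#'   and `truth.csv` when a latent difficulty is present).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_flags <- function(df) {
    for (col in names(df)) if (is.logical(df[[col]])) {
      df[[col]] <- as.integer(df[[col]])
    }
    df
  }
  paths <- file.path(dir, "lesions.csv")
  utils::write.csv(write_flags(cohort$lesions), paths[1], row.names = FALSE,
                   quote = FALSE, na = "")
  if (!is.null(cohort$procedures)) {
    p <- file.path(dir, "procedures.csv")
    utils::write.csv(write_flags(cohort$procedures), p, row.names = FALSE,
                     quote = FALSE, na = "")
    paths <- c(paths, p)
  }
  if (!is.null(cohort$difficulty)) {
    p <- file.path(dir, "truth.csv")
    utils::write.csv(data.frame(lesion_id = cohort$lesions$lesion_id,
                                difficulty = cohort$difficulty),
                     p, row.names = FALSE, quote = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Interobserver agreement report
#'
#' Cohen's kappa per categorical parameter scored by both readers on the
#' shared lesions, with the mean and IQR of the kappas across parameters.
#' Only parameters present in both tables are compared; nothing is imputed.
#'
#' @param reader_a,reader_b Lesion tables in the [lesion_schema()] layout
#'   (reader_b may cover a subset of lesions).
#' @param parameters Categorical columns to compare. Defaults to every
#'   shared flag/arc column of the schema.
#' @return Data frame `parameter`, `kappa`, `n`; attributes `mean_kappa`,
#'   `iqr_kappa`.
#' @export
kappa_report <- function(reader_a, reader_b,
                         parameters = NULL) {
  ids <- intersect(reader_a$lesion_id, reader_b$lesion_id)
  if (!length(ids)) stop("no overlapping lesion_id between readers", call. = FALSE)
  sch <- lesion_schema()
  categorical <- names(sch)[sch %in% c("flag", "arc")]
  if (is.null(parameters)) {
    parameters <- intersect(intersect(categorical, names(reader_a)),
                            names(reader_b))
  }
  a <- reader_a[match(ids, reader_a$lesion_id), , drop = FALSE]
  b <- reader_b[match(ids, reader_b$lesion_id), , drop = FALSE]
  rows <- lapply(parameters, function(p) {
    keep <- !is.na(a[[p]]) & !is.na(b[[p]])
    data.frame(parameter = p,
               kappa = if (any(keep)) cohens_kappa(a[[p]][keep], b[[p]][keep])
                       else NA_real_,
               n = sum(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$kappa)
  attr(out, "mean_kappa") <- mean(out$kappa[ok])
  attr(out, "iqr_kappa") <- unname(stats::quantile(out$kappa[ok], c(0.25, 0.75)))
  out
}

#' Analysis configuration
#'
#' Plain list of reporting and testing conventions: positive-class and
#' direction conventions per endpoint, the exact-test size threshold for
#' the Mann-Whitney branch, and report rounding (percentages to 1 decimal,
#' AUC to 3).
#'
#' @param directions See [endpoint_directions()].
#' @param mw_exact_limit Combined-size bound for the exact Mann-Whitney
#'   branch.
#' @param pct_digits,auc_digits Report rounding.
#' @param continuous_test Group-comparison test for continuous variables.
#' @return List of class `cto_config`.
#' @export
analysis_config <- function(directions = endpoint_directions(),
                            mw_exact_limit = 12,
                            pct_digits = 1, auc_digits = 3,
                            continuous_test = "mann_whitney") {
  structure(list(directions = directions, mw_exact_limit = mw_exact_limit,
                 pct_digits = pct_digits, auc_digits = auc_digits,
                 continuous_test = continuous_test),
            class = "cto_config")
}

#' Run the full analysis pipeline
#'
#' Scores every lesion, derives the endpoints, and produces the report
#' tables: endpoint/strategy prevalence, per-feature group comparisons
#' (split by time-efficient crossing), the score-by-endpoint accuracy
#' table, pairwise DeLong comparisons per endpoint, and (when a
#' second-reader table is present) the interobserver kappa table. Without
#' a procedure table the report degrades to scores only.
#'
#' @param bundle A `cto_bundle` or `cto_cohort`.
#' @param config An [analysis_config()].
#' @return List of class `cto_report` with elements `scores`, `endpoints`,
#'   `prevalence`, `group_comparison`, `accuracy`, `delong`, `kappa`
#'   (unavailable stages are `NULL` and listed in `$notes`).
#' @export
run_pipeline <- function(bundle, config = analysis_config()) {
  scores <- score_table(bundle$lesions)
  notes <- character()
  endpoints <- prevalence <- comparison <- accuracy <- delong <- NULL
  if (is.null(bundle$procedures)) {
    notes <- c(notes, "no procedure table: endpoints and accuracy unavailable")
  } else {
    endpoints <- derive_endpoints(bundle$procedures)
    endpoints <- endpoints[match(scores$lesion_id, endpoints$lesion_id), ]
    prevalence <- aggregate_endpoints(bundle$procedures)
    comp_data <- cbind(bundle$lesions,
                       group = endpoints$time_efficient_crossing)
    vars <- c(occlusion_length_mm = "continuous", max_bend_deg = "continuous",
              blunt_cap_proximal = "categorical",
              proximal_side_branch = "categorical",
              any_calcification = "categorical",
              calc_area_frac_ge_50 = "categorical",
              calc_area_frac_100 = "categorical",
              multiple_occlusions = "categorical",
              diseased_distal_landing_zone = "categorical",
              duration_gt_12mo_or_unknown = "categorical",
              reattempt = "categorical",
              prior_cabg_to_cto_vessel = "categorical")
    vars <- vars[names(vars) %in% names(comp_data)]
    comparison <- compare_groups(comp_data, "group", vars,
                                 continuous_test = config$continuous_test)
    accuracy <- accuracy_table(scores, endpoints,
                               directions = config$directions)
    delong <- do.call(rbind, lapply(names(config$directions), function(ep) {
      if (is.null(endpoints[[ep]])) return(NULL)
      lab <- endpoints[[ep]]
      if (!any(lab) || all(lab)) return(NULL)
      delong_pairwise(scores, endpoints, ep, directions = config$directions)
    }))
  }
  kappa <- NULL
  if (!is.null(bundle$second_reader)) {
    kappa <- kappa_report(bundle$lesions, bundle$second_reader)
  }
  structure(list(scores = scores, endpoints = endpoints,
                 prevalence = prevalence, group_comparison = comparison,
                 accuracy = accuracy, delong = delong, kappa = kappa,
                 notes = notes, config = config),
            class = "cto_report")
}

#' Write a report to CSV files
#'
#' One CSV per table, each prefixed with "#" provenance comment lines
#' (package version, row counts, notes). Numeric rounding follows the
#' report config: AUC columns to `auc_digits`, percentage columns to
#' `pct_digits`.
#'
#' @param report A `cto_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  round_cols <- function(df, cols, digits) {
    for (col in intersect(cols, names(df))) {
      df[[col]] <- round(df[[col]], digits)
    }
    df
  }
  tables <- list(
    scores = report$scores,
    endpoints = report$endpoints,
    endpoint_prevalence = report$prevalence,
    group_comparison = report$group_comparison,
    accuracy = round_cols(
      round_cols(report$accuracy, c("auc", "ci_low", "ci_high", "youden_j"),
                 cfg$auc_digits),
      c("sensitivity", "specificity"), cfg$pct_digits),
    delong_pairwise = round_cols(report$delong,
                                 c("auc_a", "auc_b", "difference"),
                                 cfg$auc_digits),
    kappa = report$kappa
  )
  paths <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab)) next
    path <- file.path(dir, paste0(nm, ".csv"))
    header <- c(
      sprintf("# ctohybrid %s report table '%s'",
              as.character(utils::packageVersion("ctohybrid")), nm),
      sprintf("# rows: %d", nrow(tab)),
      if (length(report$notes)) paste("#", report$notes)
    )
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(tab, con, row.names = FALSE, na = "")
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
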