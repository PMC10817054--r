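# Procedural endpoints of hybrid-algorithm CTO PCI.
#
# Three endpoints are derived from each procedure record:
#   * time-efficient guidewire crossing: successful crossing within 30
#     minutes of first wire insertion (boundary inclusive);
#   * final procedural success: crossing at any time with restored flow,
#     i.e. residual stenosis strictly below 50% and TIMI flow grade 3;
#   * need for any non-antegrade-wiring (non-AW) strategy: ADR, RW or RDR
#     was used at any point.

strategy_levels <- function() c("AW", "ADR", "RW", "RDR", "none")

#' Validate a procedure table
#'
#' Checks the internal consistency rules of procedure records: TIMI flow in
#' 0-3, residual stenosis in 0-100, `final_strategy = "none"` exactly when
#' no crossing time is recorded, the final strategy among the used ones,
#' and a recorded TIMI flow whenever crossing occurred (a crossed lesion
#' with unknown flow is rejected, never assumed successful).
#'
#' @param proc Data frame of procedure records (see [procedure_schema()]).
#' @return `proc`, invisibly, with flags coerced to logical.
#' @export
validate_procedures <- function(proc) {
  stopifnot(is.data.frame(proc))
  need <- c("gw_crossing_time_min", "used_aw", "used_adr", "used_rw",
            "used_rdr", "final_strategy", "timi_flow")
  miss <- setdiff(need, names(proc))
  if (length(miss)) {
    stop("procedure table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("used_aw", "used_adr", "used_rw", "used_rdr")) {
    proc[[f]] <- as_flag(proc[[f]], f)
  }
  t_cross <- as.numeric(proc$gw_crossing_time_min)
  fs <- as.character(proc$final_strategy)
  bad_fs <- !fs %in% strategy_levels()
  if (any(bad_fs)) {
    stop("invalid final_strategy in row(s): ",
         paste(which(bad_fs), collapse = ", "), call. = FALSE)
  }
  bad_timi <- !is.na(proc$timi_flow) & !(proc$timi_flow %in% 0:3)
  if (any(bad_timi)) {
    stop("timi_flow outside 0-3 in row(s): ",
         paste(which(bad_timi), collapse = ", "), call. = FALSE)
  }
  if ("residual_stenosis_pct" %in% names(proc)) {
    check_range(as.numeric(proc$residual_stenosis_pct), 0, 100,
                "residual_stenosis_pct")
  }
  crossed <- !is.na(t_cross)
  bad_none <- crossed != (fs != "none")
  if (any(bad_none)) {
    stop("final_strategy must be 'none' exactly when no crossing time is recorded; row(s): ",
         paste(which(bad_none), collapse = ", "), call. = FALSE)
  }
  used <- cbind(AW = proc$used_aw, ADR = proc$used_adr,
                RW = proc$used_rw, RDR = proc$used_rdr)
  idx <- match(fs, colnames(used))
  has_final <- !is.na(idx)
  bad_used <- has_final &
    !used[cbind(seq_along(fs), ifelse(has_final, idx, 1L))]
  bad_used[!has_final] <- FALSE
  if (any(bad_used, na.rm = TRUE)) {
    stop("final_strategy not among the used strategies in row(s): ",
         paste(which(bad_used), collapse = ", "), call. = FALSE)
  }
  bad_flow <- crossed & is.na(proc$timi_flow)
  if (any(bad_flow)) {
    stop("crossing recorded but TIMI flow missing in row(s): ",
         paste(which(bad_flow), collapse = ", "), call. = FALSE)
  }
  invisible(proc)
}

#' Derive the study endpoints from procedure records
#'
#' @param proc Data frame of procedure records, or a single-record list.
#' @param time_limit_min Crossing-time bound, minutes, for the
#'   time-efficiency endpoint; the bound is inclusive. Default 30.
#' @return Data frame with `lesion_id`, `time_efficient_crossing`,
#'   `final_procedural_success`, `any_non_aw` and the helper column
#'   `crossed_any_time`.
#' @examples
#' derive_endpoints(data.frame(
#'   lesion_id = 1, gw_crossing_time_min = 30, used_aw = 1, used_adr = 0,
#'   used_rw = 0, used_rdr = 0, final_strategy = "AW",
#'   residual_stenosis_pct = 20, timi_flow = 3))
#' @export
derive_endpoints <- function(proc, time_limit_min = 30) {
  if (!is.data.frame(proc)) proc <- as.data.frame(proc, stringsAsFactors = FALSE)
  proc <- validate_procedures(proc)
  t_cross <- as.numeric(proc$gw_crossing_time_min)
  crossed <- !is.na(t_cross)
  residual <- if ("residual_stenosis_pct" %in% names(proc)) {
    as.numeric(proc$residual_stenosis_pct)
  } else NA_real_
  success <- crossed & !is.na(proc$timi_flow) & proc$timi_flow == 3 &
    !is.na(residual) & residual < 50
  data.frame(
    lesion_id = if ("lesion_id" %in% names(proc)) proc$lesion_id
                else seq_len(nrow(proc)),
    time_efficient_crossing = crossed & t_cross <= time_limit_min,
    final_procedural_success = success,
    any_non_aw = proc$used_adr | proc$used_rw | proc$used_rdr,
    crossed_any_time = crossed,
    stringsAsFactors = FALSE
  )
}

#' Strategy usage profile
#'
#' Flag algebra over the four hybrid-algorithm crossing strategies:
#' the retrograde approach is RW or RDR; a dissection-and-re-entry
#' technique (DART) is ADR or RDR.
#'
#' @param proc Data frame of procedure records, or a single-record list.
#' @return Data frame with the four usage flags, `n_strategies`,
#'   `retrograde` and `any_dart`.
#' @export
strategy_profile <- function(proc) {
  if (!is.data.frame(proc)) proc <- as.data.frame(proc, stringsAsFactors = FALSE)
  proc <- validate_procedures(proc)
  data.frame(
    lesion_id = if ("lesion_id" %in% names(proc)) proc$lesion_id
                else seq_len(nrow(proc)),
    used_aw = proc$used_aw, used_adr = proc$used_adr,
    used_rw = proc$used_rw, used_rdr = proc$used_rdr,
    n_strategies = as.integer(proc$used_aw) + as.integer(proc$used_adr) +
      as.integer(proc$used_rw) + as.integer(proc$used_rdr),
    retrograde = proc$used_rw | proc$used_rdr,
    any_dart = proc$used_adr | proc$used_rdr,
    stringsAsFactors = FALSE
  )
}

#' Cohort-level endpoint and strategy prevalence
#'
#' Counts and percentages (to one decimal) for the three endpoints, crossing
#' at any time, and each strategy-usage flag over a cohort of procedures.
#'
#' @inheritParams derive_endpoints
#' @return Data frame with columns `measure`, `count`, `pct`.
#' @export
aggregate_endpoints <- function(proc, time_limit_min = 30) {
  if (!is.data.frame(proc) || nrow(proc) == 0) {
    stop("aggregate_endpoints: non-empty procedure data frame required",
         call. = FALSE)
  }
  ep <- derive_endpoints(proc, time_limit_min)
  sp <- strategy_profile(proc)
  n <- nrow(proc)
  flags <- list(
    time_efficient_crossing = ep$time_efficient_crossing,
    final_procedural_success = ep$final_procedural_success,
    any_non_aw = ep$any_non_aw,
    crossed_any_time = ep$crossed_any_time,
    any_aw = sp$used_aw,
    any_adr = sp$used_adr,
    any_rw = sp$used_rw,
    any_rdr = sp$used_rdr,
    any_dart = sp$any_dart,
    retrograde = sp$retrograde
  )
  counts <- vapply(flags, sum, integer(1))
  data.frame(
    measure = names(flags),
    count = unname(counts),
    pct = unname(round(100 * counts / n, 1)),
    n = n,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
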