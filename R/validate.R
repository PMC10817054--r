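# Internal validation helpers shared by the scoring, endpoint and IO layers.

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Coerce a user-supplied flag (logical, 0/1 numeric, "0"/"1") to logical.
# NA passes through; anything else errors with the field name.
as_flag <- function(x, field) {
  if (is.null(x)) return(NA)
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) stop(sprintf("field '%s' must be 0/1 or logical", field), call. = FALSE)
    return(as.logical(x))
  }
  if (is.character(x)) {
    out <- rep(NA, length(x))
    out[x %in% c("1", "TRUE", "true")] <- TRUE
    out[x %in% c("0", "FALSE", "false")] <- FALSE
    bad <- is.na(out) & !is.na(x) & x != ""
    if (any(bad)) stop(sprintf("field '%s' must be 0/1 or logical", field), call. = FALSE)
    return(out)
  }
  stop(sprintf("field '%s' must be 0/1 or logical", field), call. = FALSE)
}

# Require scalar fields to be present (non-NULL, non-NA); errors name the
# offending fields so a missing flag is never silently scored as absent.
require_fields <- function(values, fields, score) {
  missing <- fields[vapply(
    fields,
    function(f) is.null(values[[f]]) || any(is.na(values[[f]])),
    logical(1)
  )]
  if (length(missing)) {
    stop(sprintf(
      "%s: missing required field(s): %s",
      score, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

check_range <- function(x, lo, hi, field) {
  bad <- !is.na(x) & (x < lo | x > hi | !is.finite(x))
  if (any(bad)) {
    stop(sprintf("field '%s' must be finite and in [%s, %s]", field, lo, hi),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Calcium arc categories
#'
#' Allowed values for the maximal arc of calcium encircling the vessel wall
#' within the occluded segment: under half the circumference (`"<180"`),
#' at least half (`">=180"`), or fully circumferential (`"360"`).
#' @export
calc_arc_levels <- function() c("<180", ">=180", "360")

check_arc <- function(arc) {
  bad <- !is.na(arc) & !(arc %in% calc_arc_levels())
  if (any(bad)) {
    stop(sprintf(
      "calc_arc_max_deg must be one of %s",
      paste(sQuote(calc_arc_levels()), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}
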