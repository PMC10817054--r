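# The five additive CTO complexity scores.
#
# Shared conventions (as printed in the source score definitions):
#   * length thresholds ">= 15 mm" / ">= 20 mm" are inclusive;
#   * the bend threshold "> 45 degrees" is strict;
#   * "severe calcification" for CT-RECTOR / J-CTO(CCTA) / RECHARGE(CCTA)
#     means calcified area >= 50% of the vessel cross-sectional area,
#     with no arc requirement;
#   * KCCT grades calcium on an exclusive ladder: severe peripheral = 1
#     point, central = 2 points (never 1 + 2).

score_result <- function(system, components) {
  structure(
    list(system = system, total = sum(components), components = components),
    class = "cto_score"
  )
}

#' @export
print.cto_score <- function(x, ...) {
  cat(sprintf("%s score: %d point%s\n", x$system, x$total,
              if (x$total == 1) "" else "s"))
  comp <- x$components[x$components > 0]
  if (length(comp)) {
    cat(paste0("  ", names(comp), ": ", comp, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Maximum attainable points per scoring system
#' @return Named integer vector.
#' @export
score_max_points <- function() {
  c(ct_rector = 6L, kcct = 8L, jcto_ccta = 5L, recharge_ccta = 6L, jcto_ca = 5L)
}

#' CT-RECTOR score
#'
#' One point for each of: multiple occlusions, blunt cap at the entry or
#' exit of the occlusion, severe calcification (calcified area >= 50% of
#' CSA), bending over 45 degrees, occlusion duration over 12 months or
#' unknown, and reattempt procedure. Range 0-6.
#'
#' @param ct A [ct_lesion_features()] object.
#' @param clin A [clinical_context()] object.
#' @return A `cto_score` with `total` and per-component points.
#' @examples
#' compute_ct_rector(
#'   ct_lesion_features(blunt_cap_entry_or_exit = FALSE, max_bend_deg = 60,
#'                      any_calcification = TRUE, calc_area_frac_ge_50 = TRUE,
#'                      calc_arc_max_deg = ">=180", calc_area_frac_100 = FALSE,
#'                      multiple_occlusions = FALSE),
#'   clinical_context(duration_gt_12mo_or_unknown = TRUE, reattempt = FALSE))
#' @export
compute_ct_rector <- function(ct, clin) {
  require_fields(ct, c("multiple_occlusions", "blunt_cap_entry_or_exit",
                       "calc_area_frac_ge_50", "max_bend_deg"), "CT-RECTOR")
  require_fields(clin, c("duration_gt_12mo_or_unknown", "reattempt"), "CT-RECTOR")
  score_result("CT-RECTOR", c(
    multiple_occlusions = as.integer(ct$multiple_occlusions),
    blunt_cap_entry_or_exit = as.integer(ct$blunt_cap_entry_or_exit),
    severe_calcification = as.integer(ct$calc_area_frac_ge_50),
    bending_gt_45 = as.integer(ct$max_bend_deg > 45),
    duration_gt_12mo_or_unknown = as.integer(clin$duration_gt_12mo_or_unknown),
    reattempt = as.integer(clin$reattempt)
  ))
}

#' KCCT score
#'
#' One point for each of: proximal blunt cap, proximal adjacent side branch,
#' occlusion length of at least 15 mm, bending over 45 degrees, duration
#' over 12 months or unknown, and reattempt; calcification adds 1 point when
#' severe peripheral and 2 points when central (exclusive grades, see
#' [grade_calcification()]). Range 0-8.
#'
#' @inheritParams compute_ct_rector
#' @return A `cto_score`.
#' @export
compute_kcct <- function(ct, clin) {
  require_fields(ct, c("blunt_cap_proximal", "proximal_side_branch",
                       "occlusion_length_mm", "max_bend_deg"), "KCCT")
  require_fields(clin, c("duration_gt_12mo_or_unknown", "reattempt"), "KCCT")
  grade <- grade_calcification(ct)
  if (is.na(grade)) {
    stop("KCCT: missing required field(s): calcification grade fields",
         call. = FALSE)
  }
  score_result("KCCT", c(
    blunt_cap_proximal = as.integer(ct$blunt_cap_proximal),
    proximal_side_branch = as.integer(ct$proximal_side_branch),
    length_ge_15 = as.integer(ct$occlusion_length_mm >= 15),
    bending_gt_45 = as.integer(ct$max_bend_deg > 45),
    duration_gt_12mo_or_unknown = as.integer(clin$duration_gt_12mo_or_unknown),
    reattempt = as.integer(clin$reattempt),
    calcification = calc_points_kcct(grade)
  ))
}

calc_points_kcct <- function(grade) {
  ifelse(grade == "central", 2L,
         ifelse(grade == "severe_peripheral", 1L, 0L))
}

#' CCTA-based J-CTO score
#'
#' One point for each of: proximal blunt cap, occlusion length of at least
#' 20 mm, severe calcification (>= 50% CSA), bending over 45 degrees, and
#' reattempt. Range 0-5.
#'
#' @inheritParams compute_ct_rector
#' @return A `cto_score`.
#' @export
compute_jcto_ccta <- function(ct, clin) {
  require_fields(ct, c("blunt_cap_proximal", "occlusion_length_mm",
                       "calc_area_frac_ge_50", "max_bend_deg"), "J-CTO(CCTA)")
  require_fields(clin, "reattempt", "J-CTO(CCTA)")
  score_result("J-CTO(CCTA)", c(
    blunt_cap_proximal = as.integer(ct$blunt_cap_proximal),
    length_ge_20 = as.integer(ct$occlusion_length_mm >= 20),
    severe_calcification = as.integer(ct$calc_area_frac_ge_50),
    bending_gt_45 = as.integer(ct$max_bend_deg > 45),
    reattempt = as.integer(clin$reattempt)
  ))
}

#' CCTA-based RECHARGE score
#'
#' One point for each of: proximal blunt cap, occlusion length of at least
#' 20 mm, severe calcification (>= 50% CSA), bending over 45 degrees,
#' diseased distal landing zone, and previous bypass grafting to the CTO
#' vessel. Range 0-6.
#'
#' @inheritParams compute_ct_rector
#' @return A `cto_score`.
#' @export
compute_recharge_ccta <- function(ct, clin) {
  require_fields(ct, c("blunt_cap_proximal", "occlusion_length_mm",
                       "calc_area_frac_ge_50", "max_bend_deg",
                       "diseased_distal_landing_zone"), "RECHARGE(CCTA)")
  require_fields(clin, "prior_cabg_to_cto_vessel", "RECHARGE(CCTA)")
  score_result("RECHARGE(CCTA)", c(
    blunt_cap_proximal = as.integer(ct$blunt_cap_proximal),
    length_ge_20 = as.integer(ct$occlusion_length_mm >= 20),
    severe_calcification = as.integer(ct$calc_area_frac_ge_50),
    bending_gt_45 = as.integer(ct$max_bend_deg > 45),
    diseased_distal_landing_zone = as.integer(ct$diseased_distal_landing_zone),
    prior_cabg_to_cto_vessel = as.integer(clin$prior_cabg_to_cto_vessel)
  ))
}

#' Angiographic J-CTO score
#'
#' The standard five-component J-CTO score read from invasive angiography:
#' blunt stump, any calcification, bending over 45 degrees, occlusion length
#' of at least 20 mm, and reattempt. Range 0-5.
#'
#' @param angio An [angio_lesion_features()] object.
#' @param clin A [clinical_context()] object.
#' @return A `cto_score`.
#' @export
compute_jcto_angio <- function(angio, clin) {
  require_fields(angio, c("blunt_stump", "any_calcification",
                          "max_bend_deg", "occlusion_length_mm"), "J-CTO(CA)")
  require_fields(clin, "reattempt", "J-CTO(CA)")
  score_result("J-CTO(CA)", c(
    blunt_stump = as.integer(angio$blunt_stump),
    any_calcification = as.integer(angio$any_calcification),
    bending_gt_45 = as.integer(angio$max_bend_deg > 45),
    length_ge_20 = as.integer(angio$occlusion_length_mm >= 20),
    reattempt = as.integer(clin$reattempt)
  ))
}

#' Score a lesion with every applicable system
#'
#' Computes all five scores for one lesion. A score whose required inputs
#' are missing is returned as an uncomputable placeholder carrying the
#' reason, never silently imputed.
#'
#' @param ct [ct_lesion_features()], or `NULL` if no CCTA reading exists.
#' @param angio [angio_lesion_features()], or `NULL`.
#' @param clin [clinical_context()].
#' @param lesion_id Identifier carried into the panel.
#' @return A `cto_score_panel`: list with `lesion_id` and `scores`, one
#'   entry per system, each either a `cto_score` or a
#'   `cto_score_uncomputable` with a `reason`.
#' @export
score_all <- function(ct = NULL, angio = NULL, clin = clinical_context(),
                      lesion_id = NA) {
  if (is.null(ct) && is.null(angio)) {
    stop("score_all: at least one of 'ct' or 'angio' must be supplied",
         call. = FALSE)
  }
  wrap <- function(fun, ..., system) {
    tryCatch(fun(...), error = function(e) {
      structure(list(system = system, total = NA_integer_,
                     reason = conditionMessage(e)),
                class = "cto_score_uncomputable")
    })
  }
  absent <- function(system, block) {
    structure(list(system = system, total = NA_integer_,
                   reason = sprintf("%s features not provided", block)),
              class = "cto_score_uncomputable")
  }
  scores <- list(
    ct_rector = if (is.null(ct)) absent("CT-RECTOR", "CCTA") else
      wrap(compute_ct_rector, ct, clin, system = "CT-RECTOR"),
    kcct = if (is.null(ct)) absent("KCCT", "CCTA") else
      wrap(compute_kcct, ct, clin, system = "KCCT"),
    jcto_ccta = if (is.null(ct)) absent("J-CTO(CCTA)", "CCTA") else
      wrap(compute_jcto_ccta, ct, clin, system = "J-CTO(CCTA)"),
    recharge_ccta = if (is.null(ct)) absent("RECHARGE(CCTA)", "CCTA") else
      wrap(compute_recharge_ccta, ct, clin, system = "RECHARGE(CCTA)"),
    jcto_ca = if (is.null(angio)) absent("J-CTO(CA)", "angiographic") else
      wrap(compute_jcto_angio, angio, clin, system = "J-CTO(CA)")
  )
  structure(list(lesion_id = lesion_id, scores = scores),
            class = "cto_score_panel")
}

#' @export
print.cto_score_panel <- function(x, ...) {
  cat(sprintf("Score panel for lesion %s\n", format(x$lesion_id)))
  for (s in x$scores) {
    if (inherits(s, "cto_score_uncomputable")) {
      cat(sprintf("  %s: uncomputable (%s)\n", s$system, s$reason))
    } else {
      cat(sprintf("  %s: %d\n", s$system, s$total))
    }
  }
  invisible(x)
}

#' Score a cohort table
#'
#' Vectorised scoring of a lesion table in the package's CSV schema (see
#' [lesion_schema()]). Rows with missing required inputs get `NA` for the
#' affected score.
#'
#' @param lesions Data frame, one row per lesion.
#' @return Data frame with `lesion_id`, the five score totals
#'   (`ct_rector`, `kcct`, `jcto_ccta`, `recharge_ccta`, `jcto_ca`) and the
#'   derived tortuosity/length component flags.
#' @export
score_table <- function(lesions) {
  stopifnot(is.data.frame(lesions))
  g <- function(col) if (col %in% names(lesions)) lesions[[col]] else NA
  flag <- function(col) as_flag(g(col), col)
  blunt_prox <- flag("blunt_cap_proximal")
  blunt_ee <- flag("blunt_cap_entry_or_exit")
  sb <- flag("proximal_side_branch")
  len <- as.numeric(g("occlusion_length_mm"))
  bend <- as.numeric(g("max_bend_deg"))
  anyc <- flag("any_calcification")
  a50 <- flag("calc_area_frac_ge_50")
  arc <- as.character(g("calc_arc_max_deg"))
  a100 <- flag("calc_area_frac_100")
  mocc <- flag("multiple_occlusions")
  dlz <- flag("diseased_distal_landing_zone")
  dur <- flag("duration_gt_12mo_or_unknown")
  rea <- flag("reattempt")
  cabg <- flag("prior_cabg_to_cto_vessel")
  a_blunt <- flag("angio_blunt_stump")
  a_calc <- flag("angio_any_calcification")
  a_bend <- as.numeric(g("angio_max_bend_deg"))
  a_len <- as.numeric(g("angio_occlusion_length_mm"))
  check_arc(arc)

  grade <- grade_calc_vec(anyc, a50, arc, a100)
  bend45 <- bend > 45
  data.frame(
    lesion_id = if ("lesion_id" %in% names(lesions)) lesions$lesion_id
                else seq_len(nrow(lesions)),
    ct_rector = as.integer(mocc) + as.integer(blunt_ee) + as.integer(a50) +
      as.integer(bend45) + as.integer(dur) + as.integer(rea),
    kcct = as.integer(blunt_prox) + as.integer(sb) + as.integer(len >= 15) +
      as.integer(bend45) + as.integer(dur) + as.integer(rea) +
      calc_points_kcct(grade),
    jcto_ccta = as.integer(blunt_prox) + as.integer(len >= 20) +
      as.integer(a50) + as.integer(bend45) + as.integer(rea),
    recharge_ccta = as.integer(blunt_prox) + as.integer(len >= 20) +
      as.integer(a50) + as.integer(bend45) + as.integer(dlz) +
      as.integer(cabg),
    jcto_ca = as.integer(a_blunt) + as.integer(a_calc) +
      as.integer(a_bend > 45) + as.integer(a_len >= 20) + as.integer(rea),
    calc_grade = as.character(grade),
    tortuosity_gt_45 = bend45,
    length_ge_15 = len >= 15,
    length_ge_20 = len >= 20,
    stringsAsFactors = FALSE
  )
}
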