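#' CCTA lesion features
#'
#' Bundle the per-lesion CCTA morphology used by the four CT-derived
#' complexity scores. All flags default to `NA` (unknown); scores that need
#' an unknown flag refuse to compute rather than impute.
#'
#' @param blunt_cap_proximal Blunt (non-tapered) proximal cap.
#' @param blunt_cap_entry_or_exit Blunt cap at either the entry or the exit
#'   of the occlusion (the CT-RECTOR definition, distinct from the
#'   proximal-only cap used by the other scores).
#' @param proximal_side_branch Side branch adjacent to the proximal cap.
#' @param occlusion_length_mm Occluded-segment length, millimetres, `>= 0`.
#' @param max_bend_deg Maximal bend within the occluded segment, degrees,
#'   in `[0, 180]`. Tortuosity flags (`> 45` degrees) are derived from this,
#'   never stored.
#' @param any_calcification Any calcium within the occluded segment.
#' @param calc_area_frac_ge_50 Calcified area at least 50% of the vessel
#'   cross-sectional area (CSA) anywhere in the segment.
#' @param calc_arc_max_deg Maximal calcium arc category, one of
#'   `"<180"`, `">=180"`, `"360"` (see [calc_arc_levels()]).
#' @param calc_area_frac_100 Calcified area equal to 100% of the CSA.
#' @param multiple_occlusions Two or more complete interruptions of contrast
#'   opacification separated by an enhanced segment of at least 5 mm.
#' @param diseased_distal_landing_zone Lumen stenosis above 50% distal to
#'   the occlusion, or distal lumen diameter under 2 mm.
#'
#' @return A list of class `cto_ct_features`.
#' @examples
#' ct_lesion_features(occlusion_length_mm = 22, max_bend_deg = 50,
#'                    calc_area_frac_ge_50 = TRUE, calc_arc_max_deg = ">=180",
#'                    any_calcification = TRUE)
#' @export
ct_lesion_features <- function(blunt_cap_proximal = NA,
                               blunt_cap_entry_or_exit = NA,
                               proximal_side_branch = NA,
                               occlusion_length_mm = NA_real_,
                               max_bend_deg = NA_real_,
                               any_calcification = NA,
                               calc_area_frac_ge_50 = NA,
                               calc_arc_max_deg = NA_character_,
                               calc_area_frac_100 = NA,
                               multiple_occlusions = NA,
                               diseased_distal_landing_zone = NA) {
  out <- list(
    blunt_cap_proximal = as_flag(blunt_cap_proximal, "blunt_cap_proximal"),
    blunt_cap_entry_or_exit = as_flag(blunt_cap_entry_or_exit, "blunt_cap_entry_or_exit"),
    proximal_side_branch = as_flag(proximal_side_branch, "proximal_side_branch"),
    occlusion_length_mm = as.numeric(occlusion_length_mm),
    max_bend_deg = as.numeric(max_bend_deg),
    any_calcification = as_flag(any_calcification, "any_calcification"),
    calc_area_frac_ge_50 = as_flag(calc_area_frac_ge_50, "calc_area_frac_ge_50"),
    calc_arc_max_deg = as.character(calc_arc_max_deg),
    calc_area_frac_100 = as_flag(calc_area_frac_100, "calc_area_frac_100"),
    multiple_occlusions = as_flag(multiple_occlusions, "multiple_occlusions"),
    diseased_distal_landing_zone = as_flag(diseased_distal_landing_zone,
                                           "diseased_distal_landing_zone")
  )
  check_range(out$occlusion_length_mm, 0, Inf, "occlusion_length_mm")
  check_range(out$max_bend_deg, 0, 180, "max_bend_deg")
  check_arc(out$calc_arc_max_deg)
  validate_calc_fields(out)
  structure(out, class = "cto_ct_features")
}

# Cross-field consistency of the calcification block. 100% CSA calcium is by
# definition circumferential and >=50% CSA; any graded calcium implies
# any_calcification.
validate_calc_fields <- function(ct) {
  a100 <- ct$calc_area_frac_100
  a50 <- ct$calc_area_frac_ge_50
  arc <- ct$calc_arc_max_deg
  any <- ct$any_calcification
  bad100 <- !is.na(a100) & a100 &
    ((!is.na(arc) & arc != "360") | (!is.na(a50) & !a50))
  if (any(bad100)) {
    stop("inconsistent calcification: calc_area_frac_100 requires arc '360' and calc_area_frac_ge_50",
         call. = FALSE)
  }
  badany <- !is.na(any) & !any &
    ((!is.na(a50) & a50) | (!is.na(a100) & a100) |
       (!is.na(arc) & arc %in% c(">=180", "360")))
  if (any(badany)) {
    stop("inconsistent calcification: graded calcium present but any_calcification is FALSE",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Angiographic lesion features
#'
#' The invasive-angiography reading of the lesion, used by the angiographic
#' J-CTO score.
#'
#' @param blunt_stump Blunt proximal stump on angiography.
#' @param any_calcification Any visible calcification on angiography.
#' @param max_bend_deg Maximal bend, degrees, in `[0, 180]`.
#' @param occlusion_length_mm Occlusion length on angiography, mm, `>= 0`.
#' @return A list of class `cto_angio_features`.
#' @export
angio_lesion_features <- function(blunt_stump = NA,
                                  any_calcification = NA,
                                  max_bend_deg = NA_real_,
                                  occlusion_length_mm = NA_real_) {
  out <- list(
    blunt_stump = as_flag(blunt_stump, "blunt_stump"),
    any_calcification = as_flag(any_calcification, "any_calcification"),
    max_bend_deg = as.numeric(max_bend_deg),
    occlusion_length_mm = as.numeric(occlusion_length_mm)
  )
  check_range(out$max_bend_deg, 0, 180, "max_bend_deg")
  check_range(out$occlusion_length_mm, 0, Inf, "occlusion_length_mm")
  structure(out, class = "cto_angio_features")
}

#' Clinical context for scoring
#'
#' @param duration_gt_12mo_or_unknown Estimated occlusion duration over 12
#'   months, or unknown.
#' @param reattempt Reattempt after a previously failed recanalisation.
#' @param prior_cabg_to_cto_vessel Previous bypass graft to the occluded vessel.
#' @return A list of class `cto_clinical`.
#' @export
clinical_context <- function(duration_gt_12mo_or_unknown = NA,
                             reattempt = NA,
                             prior_cabg_to_cto_vessel = NA) {
  structure(list(
    duration_gt_12mo_or_unknown = as_flag(duration_gt_12mo_or_unknown,
                                          "duration_gt_12mo_or_unknown"),
    reattempt = as_flag(reattempt, "reattempt"),
    prior_cabg_to_cto_vessel = as_flag(prior_cabg_to_cto_vessel,
                                       "prior_cabg_to_cto_vessel")
  ), class = "cto_clinical")
}

#' Grade calcification for the KCCT score
#'
#' Orders the calcification of the occluded segment on the ladder
#' none < present_nonsevere < severe_peripheral < central. Central calcium
#' is fully circumferential (arc 360 degrees) occupying the whole vessel
#' cross-section; severe peripheral calcium encircles at least half the
#' circumference with at least half the cross-sectional area calcified.
#'
#' @param ct A [ct_lesion_features()] object (or any list with the
#'   calcification fields).
#' @return A length-1 ordered factor with levels
#'   `none < present_nonsevere < severe_peripheral < central`.
#' @examples
#' grade_calcification(ct_lesion_features(
#'   any_calcification = TRUE, calc_area_frac_ge_50 = TRUE,
#'   calc_arc_max_deg = ">=180", calc_area_frac_100 = FALSE))
#' @export
grade_calcification <- function(ct) {
  validate_calc_fields(ct)
  grade_calc_vec(
    any_calc = ct$any_calcification,
    a50 = ct$calc_area_frac_ge_50,
    arc = ct$calc_arc_max_deg,
    a100 = ct$calc_area_frac_100
  )
}

#' Calcification grade levels
#' @return Character vector of the four ordered grade labels.
#' @export
calc_grade_levels <- function() {
  c("none", "present_nonsevere", "severe_peripheral", "central")
}

# Vectorised grading core; NA in a deciding field propagates to NA grade.
grade_calc_vec <- function(any_calc, a50, arc, a100) {
  n <- max(length(any_calc), length(a50), length(arc), length(a100))
  any_calc <- rep_len(any_calc, n)
  a50 <- rep_len(a50, n)
  arc <- rep_len(arc, n)
  a100 <- rep_len(a100, n)
  central <- !is.na(a100) & a100 & !is.na(arc) & arc == "360"
  severe <- !central & !is.na(a50) & a50 & !is.na(arc) & arc %in% c(">=180", "360")
  nonsev <- !central & !severe & !is.na(any_calc) & any_calc
  none <- !central & !severe & !is.na(any_calc) & !any_calc
  out <- rep(NA_character_, n)
  out[central] <- "central"
  out[severe] <- "severe_peripheral"
  out[nonsev] <- "present_nonsevere"
  out[none] <- "none"
  factor(out, levels = calc_grade_levels(), ordered = TRUE)
}
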