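# Shared test fixtures: fully specified feature/clinical objects with every
# risk factor absent, plus brute-force oracles independent of the package's
# scoring and ROC code paths.

blank_ct <- function(...) {
  args <- list(
    blunt_cap_proximal = FALSE, blunt_cap_entry_or_exit = FALSE,
    proximal_side_branch = FALSE, occlusion_length_mm = 5,
    max_bend_deg = 10, any_calcification = FALSE,
    calc_area_frac_ge_50 = FALSE, calc_arc_max_deg = "<180",
    calc_area_frac_100 = FALSE, multiple_occlusions = FALSE,
    diseased_distal_landing_zone = FALSE
  )
  args[names(list(...))] <- list(...)
  do.call(ct_lesion_features, args)
}

blank_angio <- function(...) {
  args <- list(blunt_stump = FALSE, any_calcification = FALSE,
               max_bend_deg = 10, occlusion_length_mm = 5)
  args[names(list(...))] <- list(...)
  do.call(angio_lesion_features, args)
}

blank_clin <- function(...) {
  args <- list(duration_gt_12mo_or_unknown = FALSE, reattempt = FALSE,
               prior_cabg_to_cto_vessel = FALSE)
  args[names(list(...))] <- list(...)
  do.call(clinical_context, args)
}

# All 2^8 combinations of the binary risk factors, with continuous fields
# set just past (or short of) their thresholds, as one lesion table row per
# combination. Calcification combinations are restricted to the consistent
# ladder states.
factor_grid <- function() {
  g <- expand.grid(
    blunt = c(FALSE, TRUE), sb = c(FALSE, TRUE), mocc = c(FALSE, TRUE),
    dlz = c(FALSE, TRUE), dur = c(FALSE, TRUE), rea = c(FALSE, TRUE),
    cabg = c(FALSE, TRUE),
    calc = c("none", "present_nonsevere", "severe_peripheral", "central"),
    long = c(FALSE, TRUE), bent = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  data.frame(
    lesion_id = seq_len(nrow(g)),
    blunt_cap_proximal = g$blunt,
    blunt_cap_entry_or_exit = g$blunt,
    proximal_side_branch = g$sb,
    occlusion_length_mm = ifelse(g$long, 22, 9),
    max_bend_deg = ifelse(g$bent, 60, 20),
    any_calcification = g$calc != "none",
    calc_area_frac_ge_50 = g$calc %in% c("severe_peripheral", "central"),
    calc_arc_max_deg = c(none = "<180", present_nonsevere = "<180",
                         severe_peripheral = ">=180", central = "360")[g$calc],
    calc_area_frac_100 = g$calc == "central",
    multiple_occlusions = g$mocc,
    diseased_distal_landing_zone = g$dlz,
    duration_gt_12mo_or_unknown = g$dur,
    reattempt = g$rea,
    prior_cabg_to_cto_vessel = g$cabg,
    angio_blunt_stump = g$blunt,
    angio_any_calcification = g$calc != "none",
    angio_max_bend_deg = ifelse(g$bent, 60, 20),
    angio_occlusion_length_mm = ifelse(g$long, 22, 9),
    stringsAsFactors = FALSE
  )
}

# Independent point-sum oracle: literal transcription of each score's
# published component list, one indicator at a time.
oracle_scores <- function(row) {
  bend45 <- row$max_bend_deg > 45
  severe <- row$calc_area_frac_ge_50
  central <- row$calc_area_frac_100 && row$calc_arc_max_deg == "360"
  sev_per <- !central && severe && row$calc_arc_max_deg %in% c(">=180", "360")
  c(
    ct_rector = row$multiple_occlusions + row$blunt_cap_entry_or_exit +
      severe + bend45 + row$duration_gt_12mo_or_unknown + row$reattempt,
    kcct = row$blunt_cap_proximal + row$proximal_side_branch +
      (row$occlusion_length_mm >= 15) + bend45 +
      row$duration_gt_12mo_or_unknown + row$reattempt +
      2 * central + 1 * sev_per,
    jcto_ccta = row$blunt_cap_proximal + (row$occlusion_length_mm >= 20) +
      severe + bend45 + row$reattempt,
    recharge_ccta = row$blunt_cap_proximal + (row$occlusion_length_mm >= 20) +
      severe + bend45 + row$diseased_distal_landing_zone +
      row$prior_cabg_to_cto_vessel,
    jcto_ca = row$angio_blunt_stump + row$angio_any_calcification +
      (row$angio_max_bend_deg > 45) + (row$angio_occlusion_length_mm >= 20) +
      row$reattempt
  )
}

# Pair-enumeration AUC oracle: loops over every (positive, negative) pair.
oracle_auc <- function(values, labels, direction = "low") {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    win <- if (direction == "low") (p < q) else (p > q)
    total <- total + win + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Leave-one-out jackknife variance of the AUC.
jackknife_auc_var <- function(values, labels, direction = "low") {
  n <- length(values)
  full <- sapply(seq_len(n), function(i) {
    pl <- ctohybrid:::delong_placements(values[-i], labels[-i], direction)
    pl$auc
  })
  (n - 1) / n * sum((full - mean(full))^2)
}

# A small procedure record with consistent defaults.
proc_record <- function(...) {
  args <- list(lesion_id = 1, gw_crossing_time_min = 10, used_aw = TRUE,
               used_adr = FALSE, used_rw = FALSE, used_rdr = FALSE,
               final_strategy = "AW", residual_stenosis_pct = 20,
               timi_flow = 3, switch_time_min = NA_real_)
  args[names(list(...))] <- list(...)
  as.data.frame(args, stringsAsFactors = FALSE)
}
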