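# Scoring systems: calcification grading, component sums, thresholds,
# monotonicity, and the vectorised/per-lesion equivalence.

test_that("calcification grading follows the ordinal ladder", {
  expect_equal(as.character(grade_calcification(blank_ct(
    any_calcification = TRUE, calc_area_frac_ge_50 = TRUE,
    calc_arc_max_deg = "360", calc_area_frac_100 = TRUE))), "central")
  expect_equal(as.character(grade_calcification(blank_ct(
    any_calcification = TRUE, calc_area_frac_ge_50 = TRUE,
    calc_arc_max_deg = ">=180", calc_area_frac_100 = FALSE))),
    "severe_peripheral")
  # circumferential arc without full-area calcium is still only peripheral
  expect_equal(as.character(grade_calcification(blank_ct(
    any_calcification = TRUE, calc_area_frac_ge_50 = TRUE,
    calc_arc_max_deg = "360", calc_area_frac_100 = FALSE))),
    "severe_peripheral")
  expect_equal(as.character(grade_calcification(blank_ct())), "none")
  expect_equal(as.character(grade_calcification(blank_ct(
    any_calcification = TRUE))), "present_nonsevere")
  # inconsistent field combination is rejected at construction
  expect_error(blank_ct(calc_area_frac_100 = TRUE, calc_arc_max_deg = "<180"),
               "inconsistent calcification")
  expect_error(blank_ct(any_calcification = FALSE, calc_area_frac_ge_50 = TRUE,
                        calc_arc_max_deg = ">=180"),
               "inconsistent calcification")
})

test_that("score component sums match their published point lists", {
  all_ct <- blank_ct(blunt_cap_proximal = TRUE, blunt_cap_entry_or_exit = TRUE,
                     proximal_side_branch = TRUE, occlusion_length_mm = 30,
                     max_bend_deg = 90, any_calcification = TRUE,
                     calc_area_frac_ge_50 = TRUE, calc_arc_max_deg = "360",
                     calc_area_frac_100 = TRUE, multiple_occlusions = TRUE,
                     diseased_distal_landing_zone = TRUE)
  all_clin <- blank_clin(duration_gt_12mo_or_unknown = TRUE, reattempt = TRUE,
                         prior_cabg_to_cto_vessel = TRUE)
  expect_equal(compute_ct_rector(all_ct, all_clin)$total, 6)
  expect_equal(compute_kcct(all_ct, all_clin)$total, 8)
  expect_equal(compute_jcto_ccta(all_ct, all_clin)$total, 5)
  expect_equal(compute_recharge_ccta(all_ct, all_clin)$total, 6)
  expect_equal(compute_jcto_angio(blank_angio(
    blunt_stump = TRUE, any_calcification = TRUE, max_bend_deg = 90,
    occlusion_length_mm = 30), all_clin)$total, 5)

  none <- blank_ct()
  clin0 <- blank_clin()
  expect_equal(compute_ct_rector(none, clin0)$total, 0)
  expect_equal(compute_kcct(none, clin0)$total, 0)
  expect_equal(compute_jcto_ccta(none, clin0)$total, 0)
  expect_equal(compute_recharge_ccta(none, clin0)$total, 0)
  expect_equal(compute_jcto_angio(blank_angio(), clin0)$total, 0)

  r <- compute_ct_rector(blank_ct(multiple_occlusions = TRUE),
                         blank_clin(reattempt = TRUE))
  expect_equal(r$total, 2)
  expect_equal(r$components[["multiple_occlusions"]], 1L)
  expect_equal(r$components[["reattempt"]], 1L)
  expect_equal(compute_jcto_ccta(
    blank_ct(blunt_cap_proximal = TRUE, any_calcification = TRUE,
             calc_area_frac_ge_50 = TRUE, calc_arc_max_deg = ">=180"),
    blank_clin())$total, 2)
  expect_equal(compute_recharge_ccta(
    blank_ct(diseased_distal_landing_zone = TRUE),
    blank_clin(prior_cabg_to_cto_vessel = TRUE))$total, 2)
  expect_equal(compute_jcto_angio(blank_angio(blunt_stump = TRUE),
                                  blank_clin(reattempt = TRUE))$total, 2)
  # central calcification alone contributes exactly 2 KCCT points
  expect_equal(compute_kcct(
    blank_ct(any_calcification = TRUE, calc_area_frac_ge_50 = TRUE,
             calc_arc_max_deg = "360", calc_area_frac_100 = TRUE),
    blank_clin())$total, 2)
})

test_that("length and bend thresholds are bit-exact", {
  clin0 <- blank_clin()
  expect_equal(compute_kcct(blank_ct(occlusion_length_mm = 15.0), clin0)$total, 1)
  expect_equal(compute_kcct(blank_ct(occlusion_length_mm = 14.999), clin0)$total, 0)
  expect_equal(compute_jcto_ccta(blank_ct(occlusion_length_mm = 20.0), clin0)$total, 1)
  expect_equal(compute_jcto_ccta(blank_ct(occlusion_length_mm = 19.9), clin0)$total, 0)
  expect_equal(compute_ct_rector(blank_ct(max_bend_deg = 45.0), clin0)$total, 0)
  expect_equal(compute_ct_rector(blank_ct(max_bend_deg = 45.01), clin0)$total, 1)
})

test_that("exhaustive factor enumeration matches the point-sum oracle", {
  grid <- factor_grid()
  got <- score_table(grid)
  for (i in seq_len(nrow(grid))) {
    expected <- oracle_scores(grid[i, ])
    expect_equal(unlist(got[i, names(expected)]), expected,
                 ignore_attr = TRUE)
  }
  maxes <- score_max_points()
  for (s in names(maxes)) {
    expect_true(all(got[[s]] >= 0 & got[[s]] <= maxes[[s]]))
    expect_true(all(got[[s]] == round(got[[s]])))
  }
})

test_that("flipping any factor to present never decreases a score", {
  grid <- factor_grid()
  base <- score_table(grid)
  systems <- names(score_max_points())
  flips <- list(
    function(g) { g$blunt_cap_proximal <- TRUE
                  g$blunt_cap_entry_or_exit <- TRUE; g },
    function(g) { g$proximal_side_branch <- TRUE; g },
    function(g) { g$multiple_occlusions <- TRUE; g },
    function(g) { g$diseased_distal_landing_zone <- TRUE; g },
    function(g) { g$duration_gt_12mo_or_unknown <- TRUE; g },
    function(g) { g$reattempt <- TRUE; g },
    function(g) { g$prior_cabg_to_cto_vessel <- TRUE; g },
    function(g) { g$occlusion_length_mm <- 25; g },
    function(g) { g$max_bend_deg <- 60; g$angio_max_bend_deg <- 60; g },
    function(g) { # promote calcification one grade up the ladder
      g$any_calcification <- TRUE
      g$calc_area_frac_ge_50 <- TRUE
      g$calc_arc_max_deg <- ifelse(g$calc_arc_max_deg == "<180", ">=180",
                                   g$calc_arc_max_deg)
      g
    }
  )
  for (flip in flips) {
    flipped <- score_table(flip(grid))
    for (s in systems) {
      expect_true(all(flipped[[s]] >= base[[s]]))
    }
  }
})

test_that("missing required fields make scores uncomputable, never imputed", {
  ct_na <- blank_ct(multiple_occlusions = NA)
  expect_error(compute_ct_rector(ct_na, blank_clin()), "multiple_occlusions")
  expect_error(compute_kcct(blank_ct(occlusion_length_mm = NA), blank_clin()),
               "occlusion_length_mm")
  panel <- score_all(ct = ct_na, angio = blank_angio(), clin = blank_clin(),
                     lesion_id = "L1")
  expect_s3_class(panel$scores$ct_rector, "cto_score_uncomputable")
  expect_match(panel$scores$ct_rector$reason, "multiple_occlusions")
  expect_equal(panel$scores$jcto_ca$total, 0)
})

test_that("score_all degrades gracefully without a feature block", {
  panel <- score_all(ct = blank_ct(), clin = blank_clin(), lesion_id = 7)
  expect_equal(panel$scores$kcct$total, 0)
  expect_s3_class(panel$scores$jcto_ca, "cto_score_uncomputable")
  expect_match(panel$scores$jcto_ca$reason, "angiographic")
  expect_error(score_all(clin = blank_clin()), "at least one")
})

test_that("a long, calcified, bent lesion scores at or above the success cutoffs", {
  # the archetypal hard lesion: long, severely calcified, tortuous
  hard_ct <- blank_ct(blunt_cap_proximal = TRUE, blunt_cap_entry_or_exit = TRUE,
                      occlusion_length_mm = 35, max_bend_deg = 70,
                      any_calcification = TRUE, calc_area_frac_ge_50 = TRUE,
                      calc_arc_max_deg = "360", calc_area_frac_100 = TRUE)
  hard_angio <- blank_angio(blunt_stump = TRUE, any_calcification = TRUE,
                            max_bend_deg = 70, occlusion_length_mm = 35)
  panel <- score_all(hard_ct, hard_angio, blank_clin())
  # above the success criteria (<= cutoff predicts time-efficient crossing)
  cutoffs <- c(jcto_ca = 1, ct_rector = 2, kcct = 3, jcto_ccta = 1,
               recharge_ccta = 2)
  for (s in names(cutoffs)) {
    expect_gt(panel$scores[[s]]$total, cutoffs[[s]])
  }
})

test_that("score_table and per-lesion score_all agree on random lesions", {
  set.seed(404)
  cohort <- generate_cohort(cohort_config(n_lesions = 40, seed = 404))
  tab <- score_table(cohort$lesions)
  for (i in seq_len(10)) {
    row <- cohort$lesions[i, ]
    ct <- do.call(ct_lesion_features,
                  row[intersect(names(row), names(formals(ct_lesion_features)))])
    angio <- angio_lesion_features(
      blunt_stump = row$angio_blunt_stump,
      any_calcification = row$angio_any_calcification,
      max_bend_deg = row$angio_max_bend_deg,
      occlusion_length_mm = row$angio_occlusion_length_mm)
    clin <- clinical_context(row$duration_gt_12mo_or_unknown, row$reattempt,
                             row$prior_cabg_to_cto_vessel)
    panel <- score_all(ct, angio, clin, lesion_id = row$lesion_id)
    expect_equal(panel$scores$ct_rector$total, tab$ct_rector[i])
    expect_equal(panel$scores$kcct$total, tab$kcct[i])
    expect_equal(panel$scores$jcto_ccta$total, tab$jcto_ccta[i])
    expect_equal(panel$scores$recharge_ccta$total, tab$recharge_ccta[i])
    expect_equal(panel$scores$jcto_ca$total, tab$jcto_ca[i])
  }
})
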