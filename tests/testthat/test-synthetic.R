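# Synthetic cohort generator: determinism, marginal fidelity, latent
# structure, escalation consistency, calibration.

test_that("generation is deterministic given config and seed", {
  cfg <- cohort_config(n_lesions = 1, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_lesions = 50, seed = 123)
  a <- generate_cohort(cfg2)
  b <- generate_cohort(cfg2)
  expect_identical(a$lesions, b$lesions)
  expect_identical(a$procedures, b$procedures)
  c3 <- generate_cohort(cohort_config(n_lesions = 50, seed = 124))
  expect_false(identical(a$lesions, c3$lesions))
})

test_that("generated records satisfy the domain invariants", {
  co <- generate_cohort(cohort_config(n_lesions = 500, seed = 77))
  expect_silent(validate_procedures(co$procedures))
  L <- co$lesions
  expect_true(all(L$occlusion_length_mm > 0))
  expect_true(all(L$max_bend_deg >= 0 & L$max_bend_deg <= 180))
  # calcium ladder nesting
  expect_true(all(!L$calc_area_frac_100 | L$calc_area_frac_ge_50))
  expect_true(all(!L$calc_area_frac_ge_50 | L$any_calcification))
  expect_true(all(L$calc_arc_max_deg[L$calc_area_frac_100] == "360"))
  # entry-or-exit blunt cap contains the proximal blunt cap
  expect_true(all(!L$blunt_cap_proximal | L$blunt_cap_entry_or_exit))
  # scoring the cohort raises no validation error
  sc <- score_table(L)
  expect_false(any(is.na(sc$kcct)))
})

test_that("marginal prevalences and medians track the configuration", {
  cfg <- cohort_config(n_lesions = 10000, seed = 4242)
  co <- generate_cohort(cfg)
  L <- co$lesions
  n <- nrow(L)
  check_prev <- function(x, p) {
    expect_lt(abs(mean(x) - p), 3 * sqrt(p * (1 - p) / n))
  }
  fp <- cfg$feature_prevalences
  cp <- cfg$clinical_prevalences
  check_prev(L$blunt_cap_proximal, fp$blunt_cap_proximal)
  check_prev(L$proximal_side_branch, fp$proximal_side_branch)
  check_prev(L$multiple_occlusions, fp$multiple_occlusions)
  check_prev(L$diseased_distal_landing_zone, fp$diseased_distal_landing_zone)
  check_prev(L$any_calcification, fp$any_calcification)
  check_prev(L$calc_area_frac_ge_50, fp$calc_ge_50)
  check_prev(L$calc_area_frac_100, fp$calc_100)
  check_prev(L$duration_gt_12mo_or_unknown, cp$duration_gt_12mo_or_unknown)
  check_prev(L$reattempt, cp$reattempt)
  check_prev(L$prior_cabg_to_cto_vessel, cp$prior_cabg_to_cto_vessel)
  expect_lt(abs(median(L$occlusion_length_mm) - 15.6) / 15.6, 0.05)
  expect_lt(abs(median(L$max_bend_deg) - 27) / 27, 0.05)
})

test_that("zero loadings decouple features from the outcome", {
  cfg <- cohort_config(n_lesions = 10000, seed = 5)
  cfg0 <- ctohybrid:::scale_config(cfg, 0)
  co <- generate_cohort(cfg0)
  sc <- score_table(co$lesions)
  ep <- derive_endpoints(co$procedures)
  a <- roc_auc(sc$kcct, ep$time_efficient_crossing, "low")
  expect_lt(abs(a$auc - 0.5), 0.02)
  # marginal prevalences still hold with zero loadings
  expect_lt(abs(mean(co$lesions$blunt_cap_proximal) -
                  cfg$feature_prevalences$blunt_cap_proximal), 0.02)
})

test_that("stronger difficulty effects reduce time-efficient crossing", {
  # common random numbers: same seed across the gamma grid; the crossing
  # time's residual spread is wide, so the rate moves slowly in gamma and
  # the check needs a large cohort per grid point
  rates <- vapply(c(0.4, 1.0, 1.6, 2.2), function(g) {
    cfg <- cohort_config(n_lesions = 50000, seed = 31)
    cfg$outcome_params$gamma <- g
    mean(derive_endpoints(generate_cohort(cfg)$procedures)$time_efficient_crossing)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("unreachable configurations raise named errors", {
  expect_error(
    generate_cohort(cohort_config(
      n_lesions = 10,
      feature_prevalences = utils::modifyList(
        cohort_config()$feature_prevalences, list(blunt_cap_proximal = 1.2)))),
    "blunt_cap_proximal")
  expect_error(
    cohort_config(length_distribution = list(median = 15.6, sdlog_total = 0.7,
                                             loading = 0.8)),
    "length_distribution")
  expect_error(cohort_config(n_lesions = 0), "n_lesions")
})

test_that("calibration hits the target and handles the limits", {
  cfg <- cohort_config(n_lesions = 110, seed = 18)
  # no-signal limit
  cal0 <- calibrate_discrimination(cfg, target_auc = 0.5)
  expect_equal(attr(cal0, "scale_factor"), 0)
  expect_true(all(unlist(cal0$difficulty_loadings) == 0))
  # near-separation target is unreachable for a bounded integer score
  expect_error(
    calibrate_discrimination(cfg, target_auc = 0.999, n_sim = 4000),
    "unreachable")
  # a published-scale target is reachable and self-consistent
  cal <- calibrate_discrimination(cfg, "kcct", "time_efficient_crossing",
                                  target_auc = 0.84, n_sim = 20000,
                                  tol = 0.01)
  expect_lt(abs(attr(cal, "achieved_auc") - 0.84), 0.01)
  cal$n_lesions <- 4000L
  cal$seed <- 777L
  co <- generate_cohort(cal)
  a <- roc_auc(score_table(co$lesions)$kcct,
               derive_endpoints(co$procedures)$time_efficient_crossing, "low")
  expect_lt(abs(a$auc - 0.84), 0.04)
  expect_error(calibrate_discrimination(cfg, target_auc = 0.4), "target_auc")
})
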