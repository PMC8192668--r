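# Synthetic cohort generator: determinism, invariants, calibration.

test_that("generation is deterministic per seed and leaves the RNG alone", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  co1 <- generate_cohort(cohort_config(seed = 5))
  co2 <- generate_cohort(cohort_config(seed = 5))
  after <- runif(1)
  expect_identical(co1, co2)
  expect_identical(before, after)  # with_seed restores the caller's stream
  co3 <- generate_cohort(cohort_config(seed = 6))
  expect_false(identical(co1, co3))
})

test_that("default cohorts satisfy the emulated structure", {
  co <- default_test_cohort(seed = 1)
  df <- cohort_lesions(co)
  n_patients <- length(unique(df$patient_id))
  expect_equal(n_patients, 35)
  expect_gte(length(co), 35)
  expect_lte(length(co), 45)
  expect_gte(nrow(df), 95)   # 120 +/- 25 lesions
  expect_lte(nrow(df), 145)
  les_per_patient <- table(df$patient_id[!duplicated(df$lesion_id)])
  expect_true(all(les_per_patient >= 1 & les_per_patient <= 9))
  expect_true(all(df$lesion_volume_ml > 2 & df$lesion_volume_ml <= 871))
  nl_vol <- vapply(co, function(t) t$normal_liver_mass * 1000 / 1.03,
                   numeric(1))
  expect_true(all(nl_vol >= 837 & nl_vol <= 5049))
  expect_true(all(df$injected_activity_gbq >= 0.5 &
                    df$injected_activity_gbq <= 12.6))
  # every generated object already passed the constructors; spot-check a few
  expect_true(all(vapply(co, function(t) {
    abs(t$tumor_mass_total -
          sum(vapply(t$lesions, `[[`, numeric(1), "mass"))) < 1e-12
  }, logical(1))))
})

test_that("volume-stratified concordance ordering emerges from the noise model", {
  co <- default_test_cohort(seed = 1)
  cc <- volume_stratified_concordance(co)
  r2 <- setNames(cc$r_squared, cc$stratum)
  expect_gt(r2[["normal liver"]], r2[["lesions > 100 ml"]])
  expect_gt(r2[["lesions > 100 ml"]], r2[["lesions > 2 ml"]])
})

test_that("zero noise makes planning equal delivered", {
  cfg <- cohort_config(seed = 3, noise_scale = 0,
                       tnr_discordance_sdlog = 0)
  co <- generate_cohort(cfg)
  df <- cohort_lesions(co)
  expect_equal(df$lesion_dpa_planning, df$lesion_dpa_delivered,
               tolerance = 1e-12)
  cc <- volume_stratified_concordance(co)
  expect_true(all(cc$r_squared > 1 - 1e-10))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), ">= 1")
  expect_error(cohort_config(lesion_volume_range = c(10, 5)), "increasing")
  expect_error(cohort_config(lsf_max = 1), "\\[0, 1\\)")
  expect_error(cohort_config(noise_scale = -1), ">= 0")
  expect_error(cohort_config(lesion_count_range = c(0, 9)), "min >= 1")
})

test_that("partial-volume emulation is undone exactly by RC correction", {
  curves <- list(pet = rc_curve("pet_y90", 0.95, 15, 1.1),
                 spect = rc_curve("spect_tc99m", 0.9, 30, 1.0))
  cfg <- cohort_config(seed = 9, n_patients = 8)
  clean <- generate_cohort(cfg)
  degraded <- generate_cohort(cfg, rc_curves = curves)
  df_c <- cohort_lesions(clean)
  df_d <- cohort_lesions(degraded)
  # degradation shrinks every observation
  expect_true(all(df_d$lesion_dpa_delivered < df_c$lesion_dpa_delivered))
  restored <- correct_cohort_rc(degraded, curves, rc_floor = 1e-6)
  df_r <- cohort_lesions(restored)
  expect_equal(df_r$lesion_dpa_delivered, df_c$lesion_dpa_delivered,
               tolerance = 1e-12)
  expect_equal(df_r$lesion_dpa_planning, df_c$lesion_dpa_planning,
               tolerance = 1e-12)
  expect_equal(df_r$normal_liver_dpa_delivered,
               df_c$normal_liver_dpa_delivered, tolerance = 1e-12)
})

test_that("simulated TCP outcomes are calibrated Bernoulli draws", {
  m <- tcp_model(150, 30)
  o1 <- generate_tcp_outcomes(rep(150, 4000), m, seed = 21)
  o2 <- generate_tcp_outcomes(rep(150, 4000), m, seed = 21)
  expect_identical(o1, o2)
  expect_lt(abs(mean(o1) - 0.5), 0.03)
  high <- generate_tcp_outcomes(rep(600, 500), m, seed = 2)
  expect_gt(mean(high), 0.98)
})

test_that("phantom generator samples the true curve exactly when noiseless", {
  cv <- rc_curve("pet_y90", 0.93, 22, 1.2)
  meas <- generate_phantom_rc(cv, noise_sd = 0, seed = 1)
  expect_equal(nrow(meas), 6)
  expect_equal(meas$rc, rc_value(meas$volume_ml, cv))
  m1 <- generate_phantom_rc(cv, noise_sd = 0.05, seed = 4)
  m2 <- generate_phantom_rc(cv, noise_sd = 0.05, seed = 4)
  expect_identical(m1, m2)
  expect_true(all(m1$rc <= 1))
})
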