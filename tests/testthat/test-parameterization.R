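# The SM-vs-PM TCP-change parameterization machinery.

test_that("per-lesion TCP change is exactly zero at matched activities", {
  tr <- make_matched_treatment(rate = 25)
  co <- sirt_cohort(list(tr))
  for (d in c(80, 100, 120, 150)) {
    expect_identical(per_lesion_delta_tcp(tr, d, d, tcp_model()), 0)
  }
  ch <- build_chart(co, sm_axis = c(100, 120), pm_axis = c(100, 120))
  expect_identical(ch$mean_delta_tcp[ch$sm_dose == ch$pm_dose], c(0, 0))
})

test_that("per-lesion TCP change matches a full hand-evaluated chain", {
  m <- tcp_model(midpoint_dose = 200, slope = 50)
  tr <- make_treatment(lobe = 2, nl = 1.5, lsf = 0.05, tnr = 3,
                       lesion_mass = 0.2, rate = 30)
  # A_SM = 100 * 2 / 50 = 4 GBq; A_PM = 75 * (1.5 + 0.6) / (50 * 0.95)
  a_sm <- 4
  a_pm <- 75 * 2.1 / 47.5
  manual <- 100 * (plogis((30 * a_pm - 200) / 50) -
                     plogis((30 * a_sm - 200) / 50))
  expect_equal(per_lesion_delta_tcp(tr, 100, 75, m), manual, tolerance = 1e-12)
  # relative-change switch
  rel <- per_lesion_delta_tcp(tr, 100, 75, m, relative = TRUE)
  expect_equal(rel, 100 * (plogis((30 * a_pm - 200) / 50) /
                             plogis((30 * a_sm - 200) / 50) - 1),
               tolerance = 1e-12)
})

test_that("TCP change is monotone in both prescription doses", {
  tr <- make_treatment()
  d1 <- per_lesion_delta_tcp(tr, 100, 60, tcp_model())
  d2 <- per_lesion_delta_tcp(tr, 100, 80, tcp_model())
  d3 <- per_lesion_delta_tcp(tr, 120, 60, tcp_model())
  expect_true(all(d2 >= d1))  # raising PM dose raises the change
  expect_true(all(d3 <= d1))  # raising SM dose lowers it
})

test_that("chart aggregates pooled lesions with complete cells", {
  co <- default_test_cohort(seed = 1)
  n_lesions <- nrow(cohort_lesions(co))
  ch <- build_chart(co, sm_axis = seq(80, 150, 10), pm_axis = seq(40, 150, 10),
                    tcp_model = tcp_model())
  expect_s3_class(ch, "sirt_chart")
  expect_equal(nrow(ch), 8 * 12)
  expect_true(all(ch$n_lesions == n_lesions))
  expect_true(all(ch$min_delta_tcp <= ch$mean_delta_tcp + 1e-12))
  expect_true(all(ch$mean_delta_tcp <= ch$max_delta_tcp + 1e-12))
  expect_true(all(ch$sd_delta_tcp >= 0))
  # inherited monotonicity of the mean along both axes
  for (sm in unique(ch$sm_dose)) {
    col <- ch$mean_delta_tcp[ch$sm_dose == sm][order(ch$pm_dose[ch$sm_dose == sm])]
    expect_true(all(diff(col) > 0))
  }
  for (pm in unique(ch$pm_dose)) {
    row <- ch$mean_delta_tcp[ch$pm_dose == pm][order(ch$sm_dose[ch$pm_dose == pm])]
    expect_true(all(diff(row) < 0))
  }
})

test_that("single-lesion cohorts collapse the cell statistics", {
  co <- sirt_cohort(list(make_treatment()))
  ch <- build_chart(co, sm_axis = c(100, 140), pm_axis = c(50, 100))
  expect_equal(ch$mean_delta_tcp, ch$min_delta_tcp)
  expect_equal(ch$mean_delta_tcp, ch$max_delta_tcp)
  expect_true(all(ch$sd_delta_tcp == 0))
  expect_true(all(ch$n_lesions == 1))
})

test_that("default PM axis always includes the named clinical doses", {
  expect_true(all(c(40, 45, 47, 50, 55, 60, 75) %in% default_pm_axis()))
  expect_true(!is.unsorted(default_pm_axis(), strictly = TRUE))
  expect_error(build_chart(sirt_cohort(list(make_treatment())),
                           sm_axis = c(100, 90), pm_axis = c(40, 50)),
               "strictly increasing")
})

test_that("equivalence line matches the closed-form single-treatment oracle", {
  tr <- make_treatment(lobe = 2.2, nl = 1.6, lsf = 0.07, tnr = 2.5,
                       lesion_mass = 0.3, rate = 40)
  co <- sirt_cohort(list(tr))
  sm_axis <- seq(80, 150, by = 10)
  eq <- equivalence_line(co, sm_axis, tcp_model())
  oracle <- equivalent_pm_dose(tr, sm_axis)
  expect_true(all(eq$converged))
  expect_true(all(abs(eq$pm_dose - oracle) <= 0.1))
  # the line through matched activities is linear through the origin
  expect_equal(oracle / sm_axis, rep(oracle[1] / sm_axis[1], length(sm_axis)))
  # perturbing above the line gives positive mean change
  expect_gt(mean(per_lesion_delta_tcp(tr, 100, oracle[3] + 10, tcp_model())), 0)
})

test_that("equivalence line flags an unbracketed crossing instead of extrapolating", {
  tr <- make_treatment()
  co <- sirt_cohort(list(tr))
  eq <- equivalence_line(co, sm_axis = 100, tcp_model(), pm_range = c(400, 500))
  expect_false(eq$converged)
  expect_true(is.na(eq$pm_dose))
})

test_that("histogram conserves mass and reports consistent statistics", {
  co <- default_test_cohort(seed = 1)
  h <- delta_tcp_histogram(co, 120, 75, tcp_model(), bin_width = 5)
  expect_equal(sum(h$counts), nrow(cohort_lesions(co)))
  expect_equal(h$sd, sd(h$values))
  expect_equal(h$mean, mean(h$values))
  expect_equal(h$min, min(h$values))
  expect_equal(h$max, max(h$values))
  # degenerate cohort: identical lesions end in one bin
  co1 <- sirt_cohort(list(make_matched_treatment("A"),
                          make_matched_treatment("B")))
  h1 <- delta_tcp_histogram(co1, 120, 120, tcp_model(), bin_width = 5)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(h1$sd, 0)
})

test_that("concordance is exact for perfect agreement and near zero for noise", {
  # planning == delivered -> R^2 = 1 everywhere
  mk <- function(id, rate) {
    make_treatment(id, rate = rate, planning = rate,
                   lesion_mass = 0.11 + 0.01 * rate,
                   nl_del = rate / 2, nl_plan = rate / 2)
  }
  co <- sirt_cohort(lapply(1:6, function(i) mk(paste0("T", i), 10 + 5 * i)))
  cc <- volume_stratified_concordance(co, large_lesion_min = 100)
  expect_true(all(abs(cc$r_squared - 1) < 1e-12))
  expect_true(all(abs(cc$slope - 1) < 1e-9))

  # independent planning values -> R^2 near zero at large n
  set.seed(5)
  co2 <- sirt_cohort(lapply(1:200, function(i) {
    make_treatment(paste0("T", i), rate = runif(1, 10, 60),
                   planning = runif(1, 10, 60), lesion_mass = 0.15,
                   nl_del = runif(1, 5, 30), nl_plan = runif(1, 5, 30),
                   activity = 1)
  }))
  cc2 <- volume_stratified_concordance(co2)
  expect_lt(cc2$r_squared[cc2$stratum == "lesions > 2 ml"], 0.05)

  # small strata are dropped with a warning
  expect_warning(cc3 <- volume_stratified_concordance(co[1:6],
                                                      large_lesion_min = 1e5),
                 "omitted")
  expect_false(sprintf("lesions > %g ml", 1e5) %in% cc3$stratum)
})
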