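# Dose-response models: logit TCP and the Walrand NTCP / WLTD model.

test_that("logit TCP has midpoint, symmetry and monotonicity identities", {
  m <- tcp_model(midpoint_dose = 180, slope = 40)
  expect_equal(tcp(180, m), 0.5)
  expect_lt(tcp(0, m), tcp(500, m))
  for (s in c(5, 40, 133)) {
    expect_equal(tcp(180 + s, m) + tcp(180 - s, m), 1)
  }
  d <- seq(0, 600, by = 25)
  expect_true(all(diff(tcp(d, m)) > 0))
  expect_true(all(tcp(d, m) > 0 & tcp(d, m) < 1))
  expect_error(tcp(-1, m), ">= 0")
  expect_error(tcp_model(slope = -3), "positive")
})

test_that("fit_tcp recovers generating parameters from simulated outcomes", {
  true <- tcp_model(midpoint_dose = 150, slope = 30)
  set.seed(202)
  doses <- runif(500, 0, 400)
  outcomes <- generate_tcp_outcomes(doses, true, seed = 42)
  fit <- fit_tcp(doses, outcomes)
  expect_lt(abs(fit$midpoint_dose - 150), 15)
  expect_gt(fit$slope, 0)
})

test_that("fit_tcp rejects degenerate and inverted data", {
  expect_error(fit_tcp(1:20, rep(0, 20)), "both outcome classes")
  expect_error(fit_tcp(1:5, c(0, 1, 0, 1, 0)), "at least 10")
  # responses decreasing with dose -> negative slope -> rejected
  set.seed(7)
  doses <- runif(200, 0, 400)
  flipped <- 1 - generate_tcp_outcomes(doses, tcp_model(150, 30), seed = 8)
  expect_error(fit_tcp(doses, flipped), "increase with dose")
  # perfectly separated data
  expect_error(fit_tcp(c(1:10, 101:110), rep(c(0, 1), each = 10)),
               "separation")
})

test_that("killed fraction matches printed constants and limits", {
  expect_identical(killed_fraction(0.5), 0.4)
  # direct arithmetic, frozen: 0.4 * (0.15/0.85)^(1/8.29)
  expect_equal(killed_fraction(0.15), 0.324480152696, tolerance = 1e-10)
  expect_lt(killed_fraction(1e-30), 1e-3)  # slow power-law decay to 0
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(killed_fraction(p)) > 0))
  expect_error(killed_fraction(0), "\\(0, 1\\)")
  expect_error(killed_fraction(1), "\\(0, 1\\)")
})

test_that("msa factor is bounded, monotone, and matches direct evaluation", {
  expect_identical(msa_factor(0), 0)
  expect_equal(msa_factor(0.0471), 1 - exp(-1))
  expect_equal(msa_factor(2.5), 0.976672927562, tolerance = 1e-10)
  msa <- seq(0, 5, by = 0.1)
  f <- msa_factor(msa)
  expect_true(all(f >= 0 & f < 1))
  expect_true(all(diff(f) > 0))
  expect_error(msa_factor(-0.1), ">= 0")
})

test_that("wltd matches an independent arithmetic chain and is monotone in p", {
  # high msa pushes F -> 1; compare against a literal transcription
  p <- 0.15; vf <- 1
  f <- 1 - exp(-(1e6 / 0.0471)^(1 / 3))  # numerically 1
  kf <- 0.4 * (p / (1 - p))^(1 / 8.29)
  manual <- 47.1 * (1 + 0.457 * p) * f / (vf - kf)^(0.869 * f) * vf
  expect_equal(wltd(p, vf, 1e6), manual, tolerance = 1e-12)
  expect_equal(wltd(p, vf, 1e6), 70.7717989655, tolerance = 1e-9)

  # monotonicity scan over the feasible range at fixed vf, msa
  for (vf in c(0.5, 0.75, 1)) {
    pmax <- max_feasible_ntcp(vf)
    grid <- seq(0.005, pmax * 0.98, length.out = 40)
    w <- vapply(grid, wltd, numeric(1), vf = vf, msa = 1.5)
    expect_true(all(diff(w) > 0))
  }
})

test_that("wltd guards the infeasible region explicitly", {
  # Kf(0.5) = 0.4 so vf <= 0.4 cannot reach p = 0.5
  expect_error(wltd(0.5, 0.4, 1.5), "infeasible")
  expect_error(wltd(0.5, 0.35, 1.5), "unreachable")
  # pole: enormous dose just inside feasibility
  expect_gt(wltd(0.5, 0.4 + 1e-9, 1.5), 1e4)
  expect_error(wltd(0.15, 1.2, 1), "\\(0, 1\\]")
})

test_that("ntcp_from_dose inverts wltd to 1e-9 across the feasible grid", {
  for (p in c(0.01, 0.15, 0.5)) {
    for (vf in c(0.45, 0.6, 0.75, 0.9, 1)) {
      for (msa in c(0.05, 0.5, 2.5)) {
        if (killed_fraction(p) >= vf) next
        d <- wltd(p, vf, msa)
        inv <- ntcp_from_dose(d, vf, msa)
        expect_identical(inv$status, "ok")
        expect_equal(inv$p, p, tolerance = 1e-9)
      }
    }
  }
})

test_that("ntcp_from_dose is monotone and flags out-of-range doses", {
  d1 <- ntcp_from_dose(60, 0.8, 1.5)
  d2 <- ntcp_from_dose(80, 0.8, 1.5)
  expect_true(d1$status == "ok" && d2$status == "ok")
  expect_lt(d1$p, d2$p)
  low <- ntcp_from_dose(1e-6, 0.8, 1.5)
  expect_identical(low$status, "below_range")
  expect_true(is.na(low$p))
  expect_error(ntcp_from_dose(-5, 0.8, 1.5), "positive")
})
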