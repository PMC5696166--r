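# Mono-exponential fitting and cumulated-activity integration.

test_that("fit recovers exact generative parameters on noiseless data", {
  crv <- monoexp_tac(a0 = 10, lambda_bio = 0.1,
                     times = c(1, 5, 10, 20, 40))
  fit <- fit_monoexp(crv)
  expect_equal(fit$a0, 10, tolerance = 1e-9)
  expect_equal(fit$lambda_bio, 0.1, tolerance = 1e-9)
  expect_equal(fit$lambda_eff, 0.1 + log(2) / 159.528, tolerance = 1e-9)
  # nonlinear refinement agrees on noiseless data
  fit_nls <- fit_monoexp(crv, method = "nls")
  expect_equal(fit_nls$lambda_bio, 0.1, tolerance = 1e-6)
})

test_that("two-point fit solves the closed form", {
  crv <- tac(c(1, 3), c(8, 2), nuclide = lu177)
  fit <- fit_monoexp(crv)
  expect_equal(fit$lambda_bio, log(4) / 2, tolerance = 1e-12)
  expect_equal(fit$a0, 16, tolerance = 1e-12)
})

test_that("flat and accumulating curves clamp the biological rate at zero", {
  flat <- tac(c(2, 24, 72), c(5, 5, 5), nuclide = lu177)
  expect_equal(fit_monoexp(flat)$lambda_bio, 0)
  rising <- tac(c(2, 24, 72), c(2, 8, 15), nuclide = lu177)
  fit <- fit_monoexp(rising)
  expect_true(fit$lambda_bio_raw < 0)
  expect_equal(fit$lambda_bio, 0)
  expect_equal(fit$lambda_eff, lu177$lambda_phys)
})

test_that("non-positive points are excluded with a warning; <2 points errors", {
  crv <- tac(c(1, 5, 9), c(10, 0, 5), nuclide = lu177)
  expect_warning(fit <- fit_monoexp(crv), "excluded")
  expect_equal(fit$lambda_bio, log(10 / 5) / 8, tolerance = 1e-12)
  zero <- tac(c(1, 5), c(0, 0), nuclide = lu177)
  expect_error(suppressWarnings(fit_monoexp(zero)),
               class = "mirdose_fit_error")
})

test_that("closed-form cumulated activity has the physical-decay limits", {
  # 100 %ID held with no biological clearance: residence = T1/2 / ln 2
  crv <- tac(c(2, 100, 300), rep(100, 3), nuclide = lu177, units = "pid")
  ca <- cumulated_activity_monoexp(fit_monoexp(crv), injected = 1)
  expect_equal(ca$residence_time_h, lu177$half_life_h / log(2),
               tolerance = 1e-9)
  # a0 = 50 %ID with lambda_eff = 0.2: residence 2.5 h
  nuc <- nuclide_spec("toy", half_life_h = log(2) / 0.15, mean_np_kev = 100)
  crv2 <- tac(c(1, 4, 9), 50 * exp(-0.05 * c(1, 4, 9)), nuclide = nuc,
              units = "pid")
  ca2 <- cumulated_activity_monoexp(fit_monoexp(crv2), injected = 1)
  expect_equal(ca2$residence_time_h, 2.5, tolerance = 1e-9)
  # doubling injected doubles the cumulated activity, not the residence time
  ca_2x <- cumulated_activity_monoexp(fit_monoexp(crv2), injected = 2)
  expect_equal(ca_2x$value, 2 * ca2$value)
  expect_equal(ca_2x$residence_time_h, ca2$residence_time_h)
})

test_that("closed form matches fine-grid numerical integration", {
  for (lb in c(0, 0.005, 0.05)) {
    fit <- fit_monoexp(monoexp_tac(a0 = 20, lambda_bio = lb,
                                   times = c(2, 24, 72, 168)))
    ca <- cumulated_activity_monoexp(fit, injected = 3.7)
    f <- function(t) fit$a0 / 100 * 3.7 * exp(-fit$lambda_eff * t)
    num <- stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(ca$value, num, tolerance = 1e-3)
    expect_lt(abs(ca$value - num) / num, 1e-3) # < 0.1%
  }
})

test_that("hybrid integration agrees with the closed form on 1-compartment curves", {
  # sampled from t = 0 over ~3 effective half-lives at 8 points
  lam_bio <- 0.05
  lam_eff <- lam_bio + lu177$lambda_phys
  t3 <- 3 * log(2) / lam_eff
  tt <- seq(0, t3, length.out = 8)
  crv <- tac(tt, 10 * exp(-lam_bio * tt), nuclide = lu177)
  ca_h <- cumulated_activity_hybrid(crv, injected = 1, tail = "fitted")
  ca_m <- cumulated_activity_monoexp(fit_monoexp(crv), injected = 1)
  expect_lt(abs(ca_h$value - ca_m$value) / ca_m$value, 0.02)
})

test_that("the physical tail equals the analytic remainder for a decaying curve", {
  # curve whose decay-corrected value is constant: activity falls at the
  # physical rate only, so trapezoid + physical tail is exact
  tt <- seq(0, 400, by = 4)
  crv <- tac(tt, rep(40, length(tt)), nuclide = lu177)
  ca <- cumulated_activity_hybrid(crv, injected = 1, tail = "physical")
  exact <- 0.4 / lu177$lambda_phys
  expect_lt(abs(ca$value - exact) / exact, 2e-3)
  # and the tail piece itself is analytic: area beyond t_last
  tail_exact <- 0.4 * exp(-lu177$lambda_phys * 400) / lu177$lambda_phys
  grid_part <- pracma::trapz(tt, 0.4 * exp(-lu177$lambda_phys * tt))
  expect_equal(ca$value, grid_part + tail_exact, tolerance = 1e-12)
})

test_that("all-zero curves integrate to zero; unknown tail label errors", {
  crv <- tac(c(2, 24), c(0, 0), nuclide = lu177)
  expect_equal(cumulated_activity_hybrid(crv, 1)$value, 0)
  expect_error(cumulated_activity_hybrid(crv, 1, tail = "bogus"),
               class = "mirdose_config_error")
})

test_that("blood-style back-extrapolation reproduces the t=0 intercept", {
  tt <- seq(2, 60, by = 2)
  crv <- tac(tt, 30 * exp(-0.04 * tt), nuclide = lu177)
  ca_z <- cumulated_activity_hybrid(crv, 1, tail = "fitted", t0 = "zero")
  ca_e <- cumulated_activity_hybrid(crv, 1, tail = "fitted",
                                    t0 = "extrapolate")
  # extrapolation recovers more of the early area and is closer to truth
  truth <- 0.30 / (0.04 + lu177$lambda_phys)
  expect_lt(abs(ca_e$value - truth) / truth, 0.01)
  expect_gt(ca_e$value, ca_z$value)
})

test_that("fit_study integrates each organ with the scheme its fit calls for", {
  cfg <- preset_config("lu177-paperlike", cv = 0)
  st <- generate_study(cfg)
  rep <- fit_study(st)
  expect_setequal(rep$organ, sort(names(cfg$organs)))
  # tumor accumulates -> hybrid; blood clears -> monoexp closed form
  expect_equal(rep$scheme[rep$organ == "tumor"], "hybrid")
  expect_equal(rep$scheme[rep$organ == "blood"], "monoexp")
  expect_true(all(rep$residence_time_h >= 0))
  # no source can beat the all-decays-in-place bound at <= 100 %ID/g
  expect_true(all(rep$residence_time_h <= lu177$half_life_h / log(2)))
})
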