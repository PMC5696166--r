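# Synthetic study generator and its ground truth.

test_that("kinetic constructors evaluate their closed forms", {
  mono <- kinetic_monoexp(10, 0.1)
  expect_equal(kinetic_value(mono, c(0, 10)), c(10, 10 * exp(-1)))
  up <- kinetic_uptake(15, lambda_in = 0.1, lambda_out = 0.003)
  expect_equal(kinetic_value(up, 0), 0)
  tpk <- log(0.1 / 0.003) / (0.1 - 0.003)
  expect_gt(kinetic_value(up, tpk), kinetic_value(up, tpk / 3))
  expect_gt(kinetic_value(up, tpk), kinetic_value(up, 3 * tpk))
  expect_error(kinetic_uptake(15, 0.003, 0.1), class = "mirdose_config_error")
  expect_error(kinetic_biexp(c(1), c(0.1, 0.2)),
               class = "mirdose_config_error")
})

test_that("zero CV reproduces the mean curve exactly for every animal", {
  cfg <- preset_config("lu177-paperlike", cv = 0)
  st <- generate_study(cfg)
  sm <- summarize_study(st, ratio_pairs = list())
  for (o in names(cfg$organs)) {
    mu <- kinetic_value(cfg$organs[[o]], cfg$timepoints_h)
    got <- sm$uptake$mean[sm$uptake$organ == o][order(
      sm$uptake$time_h[sm$uptake$organ == o])]
    expect_equal(got, mu, tolerance = 1e-12)
  }
  expect_true(all(sm$uptake$sd == 0))
  expect_true(all(sm$uptake$n == 4))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- preset_config("lu177-paperlike", seed = 99L)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$samples, b$samples)
  cfg2 <- preset_config("lu177-paperlike", seed = 100L)
  expect_false(identical(generate_study(cfg2)$samples$pidg,
                         a$samples$pidg))
})

test_that("the blocking arm scales only the target organ", {
  cfg <- preset_config("lu177-paperlike", cv = 0)
  base <- summarize_study(generate_study(cfg, "baseline"),
                          ratio_pairs = list())$uptake
  blk <- summarize_study(generate_study(cfg, "blocking"),
                         ratio_pairs = list())$uptake
  t_base <- base[base$organ == "tumor", ]
  t_blk <- blk[blk$organ == "tumor", ]
  expect_equal(t_blk$mean / t_base$mean,
               rep(cfg$blocking_multiplier, nrow(t_base)), tolerance = 1e-12)
  b_base <- base[base$organ == "blood", ]
  b_blk <- blk[blk$organ == "blood", ]
  expect_equal(b_blk$mean, b_base$mean, tolerance = 1e-12)
  # estimated blocking fraction converges to the multiplier as CV -> 0
  expect_equal(blocking_fraction(t_base$mean[5], t_blk$mean[5]),
               cfg$blocking_multiplier * 100, tolerance = 1e-9)
})

test_that("log-normal noise is unbiased: group means approach the curve", {
  cfg <- preset_config("lu177-paperlike", cv = 0.15, seed = 7L,
                       n_per_timepoint = 400L)
  st <- generate_study(cfg)
  sm <- summarize_study(st, ratio_pairs = list())
  mu <- kinetic_value(cfg$organs$tumor, cfg$timepoints_h)
  got <- sm$uptake$mean[sm$uptake$organ == "tumor"]
  expect_equal(got, mu, tolerance = 0.05)
})

test_that("truth record matches hand-computed closed-form integrals", {
  cfg <- synthetic_config(
    nuclide = "lu177",
    organs = list(blood = kinetic_monoexp(30, 0.01),
                  tumor = kinetic_uptake(20, 0.05, 0.002)),
    timepoints_h = c(2, 24, 72), cv = 0, injected_mbq = 2, seed = 1L)
  tr <- truth_record(cfg, tumor_mass_g = 0.15)
  lp <- lu177$lambda_phys
  expect_equal(tr$organ$residence_time_per_g_h[tr$organ$organ == "blood"],
               0.30 / (0.01 + lp), tolerance = 1e-12)
  tau_tumor <- (20 / (0.002 + lp) - 20 / (0.05 + lp)) / 100
  expect_equal(tr$organ$residence_time_per_g_h[tr$organ$organ == "tumor"],
               tau_tumor, tolerance = 1e-12)
  expect_equal(tr$tumor_dose_gy,
               tau_tumor * 2 * 0.15 * self_dose_factor(lu177, 0.15) / 1e3,
               tolerance = 1e-12)
  # truth is a pure function of the config
  expect_equal(truth_record(cfg, tumor_mass_g = 0.15)$tumor_dose_gy,
               tr$tumor_dose_gy)
})

test_that("simulated cell binding recovers the specific fraction", {
  exact <- generate_cell_binding(1000, 0.746, 0.02, cv = 0, seed = 1)
  expect_equal(exact$bound_percent, rep(74.6, 3), tolerance = 1e-12)
  expect_equal(generate_cell_binding(1000, 0, 0.02, cv = 0,
                                     seed = 1)$bound_percent,
               rep(0, 3), tolerance = 1e-12)
  # Monte Carlo: mean over many noisy tubes within 1% of truth
  mc <- generate_cell_binding(1000, 0.746, 0.02, cv = 0.05, seed = 11,
                              n = 1500)
  expect_equal(mean(mc$bound_percent), 74.6, tolerance = 0.01)
  expect_error(generate_cell_binding(1000, 0.9, 0.2, cv = 0),
               class = "mirdose_config_error")
})

test_that("config validation rejects malformed kinetics and parameters", {
  expect_error(synthetic_config("lu177", list(a = 1), c(1, 2)),
               class = "mirdose_config_error")
  expect_error(synthetic_config("lu177",
                                list(a = kinetic_monoexp(1, 0.1)),
                                c(2, 1)),
               class = "mirdose_config_error")
  expect_error(synthetic_config("lu177",
                                list(a = kinetic_monoexp(1, 0.1)),
                                c(1, 2), blocking_multiplier = 1.5),
               class = "mirdose_config_error")
})
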