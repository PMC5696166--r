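# Mouse-to-human residence-time extrapolation.

test_that("percent-kg/g scaling is the stated arithmetic and is homogeneous", {
  expect_equal(human_percent_id(10, 0.02, 1000, 70), 10 * 0.02 * 1000 / 70)
  base <- human_percent_id(5, 0.02, 300, 70)
  expect_equal(human_percent_id(10, 0.02, 300, 70), 2 * base)
  expect_equal(human_percent_id(5, 0.04, 300, 70), 2 * base)
  expect_equal(human_percent_id(5, 0.02, 600, 70), 2 * base)
  expect_equal(human_percent_id(5, 0.02, 300, 35), 2 * base)
  # degenerate self-consistency: same body mass both sides, 1-g organ
  expect_equal(human_percent_id(7, 0.02, 1, 0.02), 7)
  expect_error(human_percent_id(5, 0, 300, 70),
               class = "mirdose_invalid_input")
})

test_that("the packaged phantom loads with positive masses under 70 kg", {
  ph <- human_phantom()
  expect_s3_class(ph, "human_phantom")
  expect_equal(ph$body_mass_kg, 70)
  expect_true(all(ph$organ_masses > 0))
  expect_true("liver" %in% names(ph$organ_masses))
  expect_lt(sum(ph$organ_masses), 70 * 1000)
})

test_that("organ aliases map biodistribution labels onto phantom organs", {
  ph <- human_phantom()
  al <- organ_aliases()
  expect_equal(unname(al["s.i."]), "small_intestine")
  st <- biodist_study(
    data.frame(organ = c("S.I.", "Liver"), animal_id = "a1",
               time_h = c(24, 24), mass_g = 0.5, pidg = c(3, 8)),
    nuclide = lu177)
  expect_setequal(unique(st$samples$organ), c("s.i.", "liver"))
})

test_that("a single organ holding 100 %ID/g-equivalent hits the conservation limit", {
  # one 1-g organ at 100 %ID/g with no clearance, phantom = the mouse itself:
  # residence time is T1/2/ln2 and the remainder is zero
  ph <- structure(list(body_mass_kg = 0.02,
                       organ_masses = c(organ1 = 1), name = "mouse-as-human"),
                  class = "human_phantom")
  s <- data.frame(organ = "organ1", animal_id = "a1",
                  time_h = rep(c(2, 100, 300), 1), mass_g = 1,
                  pidg = 100)
  st <- biodist_study(s, nuclide = lu177, injected_mbq = 1)
  expect_warning(res <- extrapolate_residence_times(st, ph,
                                                    mouse_body_kg = 0.02),
                 "physical-decay bound")
  expect_equal(unname(res$times["organ1"]), lu177$half_life_h / log(2),
               tolerance = 1e-9)
  expect_equal(res$remainder_h, 0, tolerance = 1e-9)
})

test_that("residence times are linear in uptake and match closed forms", {
  ph <- human_phantom()
  mk <- function(scale) {
    tt <- c(2, 24, 72, 168, 336)
    rows <- rbind(
      data.frame(organ = "liver", animal_id = "a1", time_h = tt, mass_g = 1,
                 pidg = scale * 8 * exp(-0.005 * tt)),
      data.frame(organ = "spleen", animal_id = "a1", time_h = tt, mass_g = 0.1,
                 pidg = scale * 12 * exp(-0.002 * tt))
    )
    biodist_study(rows, nuclide = lu177, injected_mbq = 3.7)
  }
  res1 <- suppressWarnings(extrapolate_residence_times(mk(1), ph))
  res2 <- suppressWarnings(extrapolate_residence_times(mk(2), ph))
  expect_equal(unname(res2$times), 2 * unname(res1$times), tolerance = 1e-9)

  # closed form: tau = pidg0 * mb * m_h / Hb / 100 / lambda_eff
  tau_liver <- 8 * 0.020 * ph$organ_masses[["liver"]] / 70 / 100 /
    (0.005 + lu177$lambda_phys)
  tau_spleen <- 12 * 0.020 * ph$organ_masses[["spleen"]] / 70 / 100 /
    (0.002 + lu177$lambda_phys)
  expect_equal(unname(res1$times["liver"]), tau_liver, tolerance = 1e-6)
  expect_equal(unname(res1$times["spleen"]), tau_spleen, tolerance = 1e-6)
})

test_that("extrapolation preserves uptake ordering at equal-or-larger organ mass", {
  ph <- human_phantom()
  tt <- c(2, 24, 72, 168)
  rows <- rbind(
    data.frame(organ = "spleen", animal_id = "a1", time_h = tt, mass_g = 0.1,
               pidg = 14 * exp(-0.004 * tt)),
    data.frame(organ = "lungs", animal_id = "a1", time_h = tt, mass_g = 0.15,
               pidg = 9 * exp(-0.004 * tt))
  )
  st <- biodist_study(rows, nuclide = lu177, injected_mbq = 3.7)
  res <- suppressWarnings(extrapolate_residence_times(st, ph))
  # spleen's per-gram residence exceeds lungs' and lungs' human mass is
  # larger, so the per-organ ordering follows the mass-weighted product
  expect_gt(res$times[["lungs"]] / ph$organ_masses[["lungs"]],
            0) # sanity
  expect_gt(res$times[["spleen"]] / ph$organ_masses[["spleen"]],
            res$times[["lungs"]] / ph$organ_masses[["lungs"]])
})

test_that("unmapped organs are skipped and an empty intersection errors", {
  ph <- human_phantom()
  tt <- c(2, 24)
  st <- biodist_study(
    rbind(data.frame(organ = "tumor", animal_id = "a1", time_h = tt,
                     mass_g = 0.15, pidg = c(5, 10)),
          data.frame(organ = "liver", animal_id = "a1", time_h = tt,
                     mass_g = 1, pidg = c(10, 8))),
    nuclide = lu177, injected_mbq = 3.7)
  res <- suppressWarnings(extrapolate_residence_times(st, ph))
  expect_equal(res$skipped, "tumor")
  only_tumor <- biodist_study(
    data.frame(organ = "tumor", animal_id = "a1", time_h = tt,
               mass_g = 0.15, pidg = c(5, 10)),
    nuclide = lu177, injected_mbq = 3.7)
  expect_error(suppressWarnings(extrapolate_residence_times(only_tumor, ph)),
               class = "mirdose_mapping_error")
})

test_that("a whole-body curve bounds the remainder instead of the physical limit", {
  ph <- human_phantom()
  tt <- c(2, 24, 72, 168)
  rows <- rbind(
    data.frame(organ = "liver", animal_id = "a1", time_h = tt, mass_g = 1,
               pidg = 8 * exp(-0.005 * tt)),
    data.frame(organ = "whole_body", animal_id = "a1", time_h = tt, mass_g = NA,
               pidg = 90 * exp(-0.003 * tt))
  )
  st <- biodist_study(rows, nuclide = lu177, injected_mbq = 3.7)
  expect_no_warning(res <- extrapolate_residence_times(st, ph))
  total_expected <- 0.90 / (0.003 + lu177$lambda_phys)
  expect_equal(res$total_h, total_expected, tolerance = 1e-6)
  expect_equal(res$remainder_h, total_expected - sum(res$times),
               tolerance = 1e-9)
})
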