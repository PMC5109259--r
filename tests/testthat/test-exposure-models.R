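# Hazard-quotient kernels against independent hand arithmetic.

test_that("ingestion HQ matches hand arithmetic and scales as expected", {
  hq <- hq_ingestion(conc = 100, ir = 100, ef = 350, ed = 24, bw = 60,
                     at = 8760, rfd = 3e-4, medium = "soil")
  expect_equal(hq, 100 * 100 * 350 * 24 * 1e-6 / (60 * 8760 * 3e-4),
               tolerance = 1e-12)
  expect_equal(hq, 0.533, tolerance = 1e-3)
  # zero source, inverse proportionality in RfD, linearity in concentration
  expect_identical(hq_ingestion(0, 100, 350, 24, 60, 8760, 3e-4, "soil"), 0)
  expect_equal(hq_ingestion(100, 100, 350, 24, 60, 8760, 6e-4, "soil"),
               hq / 2, tolerance = 1e-12)
  expect_equal(hq_ingestion(200, 100, 350, 24, 60, 8760, 3e-4, "soil"),
               2 * hq, tolerance = 1e-12)
  # water medium switches the unit factor to 1e-3
  expect_equal(hq_ingestion(1, 1, 1, 1, 1, 1, 1, "surface_water") /
                 hq_ingestion(1, 1, 1, 1, 1, 1, 1, "soil"),
               1e3, tolerance = 1e-12)
})

test_that("unit declarations that disagree with the medium error out", {
  expect_error(hq_ingestion(1, 1, 1, 1, 1, 1, 1, "soil", conc_units = "ug/L"),
               "do not match medium")
  expect_error(hq_ingestion(1, 1, 1, 1, 1, 1, 1, "groundwater",
                            conc_units = "mg/kg"),
               "do not match medium")
  expect_silent(hq_ingestion(1, 1, 1, 1, 1, 1, 1, "sediment",
                             conc_units = "mg/kg"))
})

test_that("groundwater leaching matches hand arithmetic and is monotone", {
  expect_equal(conc_groundwater(50, 25, 0.3, 1.5, 20),
               1000 * 50 / ((25 + 0.2) * 20), tolerance = 1e-12)
  expect_equal(conc_groundwater(50, 25, 0.3, 1.5, 20), 99.2, tolerance = 1e-3)
  # pure pore water: df = 1, kd = 0, theta_w / rho_b = 1
  expect_equal(conc_groundwater(2, 0, 1, 1, 1), 2000, tolerance = 1e-12)
  # sorption limit
  expect_lt(conc_groundwater(50, 1e9, 0.3, 1.5, 20), 1e-3)
  # monotonicity
  expect_gt(conc_groundwater(60, 25, 0.3, 1.5, 20),
            conc_groundwater(50, 25, 0.3, 1.5, 20))
  expect_lt(conc_groundwater(50, 30, 0.3, 1.5, 20),
            conc_groundwater(50, 25, 0.3, 1.5, 20))
  expect_lt(conc_groundwater(50, 25, 0.3, 1.5, 40),
            conc_groundwater(50, 25, 0.3, 1.5, 20))
})

test_that("vegetable HQ matches hand arithmetic and validates water content", {
  hq <- hq_vegetable(c_as = 2, puf = 0.1, ir_v = 0.3, theta_v = 0.9,
                     ef = 350, ed = 24, bw = 60, at = 8760, rfd = 1e-3)
  expect_equal(hq, 2 * 0.1 * 0.3 * 0.1 * 350 * 24 / (60 * 8760 * 1e-3),
               tolerance = 1e-12)
  expect_equal(hq, 0.0959, tolerance = 1e-3)
  expect_identical(hq_vegetable(2, 0, 0.3, 0.9, 350, 24, 60, 8760, 1e-3), 0)
  expect_equal(hq_vegetable(4, 0.1, 0.3, 0.9, 350, 24, 60, 8760, 1e-3),
               2 * hq, tolerance = 1e-12)
  expect_error(hq_vegetable(2, 0.1, 0.3, 1.0, 350, 24, 60, 8760, 1e-3),
               "theta_v")
})

test_that("dermal solid-contact HQ matches hand arithmetic in mixed units", {
  hq <- hq_dermal_solid(conc = 100, sa = 0.5, af = 0.2, abs_frac = 0.03,
                        ef = 225, ed = 24, bw = 60, at = 8760,
                        rfd_dermal = 1e-4)
  expect_equal(hq, 100 * 5000 * 0.2 * 0.03 * 225 * 24 * 1e-6 /
                 (60 * 8760 * 1e-4), tolerance = 1e-12)
  expect_equal(hq, 0.308, tolerance = 1e-3)
  expect_identical(hq_dermal_solid(100, 0.5, 0.2, 0, 225, 24, 60, 8760, 1e-4), 0)
  expect_error(hq_dermal_solid(100, 0.5, 0.2, 0.03, 225, 24, 60, 8760,
                               NA_real_, metal = "Pb"),
               "dermal.*Pb")
})

test_that("dermal water-contact HQ carries the ug/L to mg/cm3 chain", {
  # absorbed dose (HQ with RfD = 1): 10 ug/L, Kp 1e-3 cm/h, 1.8 m2, 1 h,
  # 30 events/yr, 24 yr / (60 kg * 8760 d)
  dose <- hq_dermal_water(conc = 10, kp = 1e-3, sa = 1.8, et = 1,
                          ef_events = 30, ed = 24, bw = 60, at = 8760,
                          rfd_dermal = 1)
  expect_equal(dose, 10 * 1e-3 * 18000 * 1 * 30 * 24 * 1e-6 / (60 * 8760),
               tolerance = 1e-12)
  expect_equal(dose, 2.47e-7, tolerance = 1e-2)
  expect_identical(hq_dermal_water(10, 0, 1.8, 1, 30, 24, 60, 8760, 1), 0)
  # linear in contact time
  expect_equal(hq_dermal_water(10, 1e-3, 1.8, 2, 30, 24, 60, 8760, 1),
               2 * dose, tolerance = 1e-12)
  expect_error(hq_dermal_water(10, NA_real_, 1.8, 1, 30, 24, 60, 8760, 1,
                               metal = "Zn"),
               "permeability.*Zn")
})

test_that("inhalation HQ combines dust and vapor pathways additively", {
  base <- list(conc = 0.4, ir_a = 15, ef = 225, ed = 24, bw = 60, at = 8760,
               rfd_inhalation = 8.57e-5, pef = 1.36e9)
  hq_no_vf <- do.call(hq_inhalation, base)
  hq_vf <- do.call(hq_inhalation, c(base, vf = 32376.4))
  # for volatile Hg the vapor term dominates the dust term by > 1e4
  expect_gt((hq_vf - hq_no_vf) / hq_no_vf, 1e4)
  expect_gt(1 - hq_no_vf / hq_vf, 0.9999)
  expect_equal(hq_vf, 0.4 * 15 * 225 * 24 * (1 / 1.36e9 + 1 / 32376.4) /
                 (60 * 8760 * 8.57e-5), tolerance = 1e-12)
  # non-volatile metal at huge PEF -> HQ tends to zero
  expect_lt(do.call(hq_inhalation, modifyList(base, list(pef = 1e15))), 1e-9)
})

test_that("every route is nonnegative and collapses deterministically on vectors", {
  n <- 8
  hq <- hq_ingestion(rep(10, n), rep(50, n), rep(225, n), rep(24, n),
                     rep(60, n), rep(8760, n), 3e-4, "soil")
  expect_length(hq, n)
  expect_true(all(hq == hq[1]))
  expect_true(all(hq >= 0))
})
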