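# Synthetic field-survey generator and its round trip to summary tables.

test_that("the bundled survey summary table is complete and self-consistent", {
  tab <- concentration_summaries()
  expect_equal(nrow(tab), 56)  # 7 strata x 8 metals
  expect_setequal(unique(tab$stratum),
                  c("RVS", "RGS", "PVS", "PGS", "profile_0_100",
                    "sediment", "surface_water"))
  expect_true(all(tab$minimum <= tab$mean & tab$mean <= tab$maximum))
  expect_true(all(tab$sd >= 0))
  expect_true(all(tab$units[tab$stratum == "surface_water"] == "ug/L"))
  expect_true(all(tab$units[tab$stratum != "surface_water"] == "mg/kg"))
  # default site counts of the survey design
  counts <- unique(tab[, c("stratum", "n_sites")])
  expect_equal(
    setNames(counts$n_sites, counts$stratum)[
      c("RVS", "RGS", "PVS", "PGS", "profile_0_100", "surface_water",
        "sediment")],
    c(RVS = 7, RGS = 13, PVS = 11, PGS = 20, profile_0_100 = 6,
      surface_water = 10, sediment = 10)
  )
})

test_that("generated data are reproducible and respect truncation bounds", {
  d1 <- generate_field_data(seed = 5)
  d2 <- generate_field_data(seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1$concentration,
                         generate_field_data(seed = 6)$concentration))
  # every draw inside the declared [min, max]; min/max round-trip exactly
  joined <- dplyr::left_join(d1, concentration_summaries(),
                             by = c("stratum", "metal"))
  expect_true(all(joined$concentration >= joined$minimum &
                    joined$concentration <= joined$maximum))
  # site counts honored
  expect_equal(dplyr::n_distinct(d1$site_id[d1$stratum == "RVS"]), 7)
  expect_equal(dplyr::n_distinct(d1$site_id[d1$stratum == "PGS"]), 20)
})

test_that("large-sample draws match the truncated-lognormal moment oracle", {
  d <- generate_field_data(seed = 31, n_multiplier = 100)
  as_rvs <- d$concentration[d$stratum == "RVS" & d$metal == "As"]
  expect_length(as_rvs, 700)
  # oracle: analytic mean of lognormal(72.3, 26.8) truncated to [34.7, 106.3]
  expected <- oracle_truncated_lnorm_mean(72.3, 26.8, 34.7, 106.3)
  expect_equal(expected, 67.07, tolerance = 1e-3)
  expect_lt(abs(mean(as_rvs) - expected), 1.5)
  expect_true(all(as_rvs >= 34.7 & as_rvs <= 106.3))
})

test_that("co-contaminated metals are rank-correlated within a stratum", {
  d <- generate_field_data(seed = 32, n_multiplier = 100)
  wide <- tidyr::pivot_wider(d[d$stratum == "RVS", ],
                             id_cols = "site_id", names_from = "metal",
                             values_from = "concentration")
  rho <- cor(wide$As, wide$Cd, method = "spearman")
  expect_gt(rho, 0.35)
  expect_lt(rho, 0.65)
  # Hg is not in the co-contamination set: near-independent of As
  expect_lt(abs(cor(wide$As, wide$Hg, method = "spearman")), 0.2)
})

test_that("soil strata carry a pH placeholder; waters do not", {
  d <- generate_field_data(seed = 33)
  expect_true(all(!is.na(d$soil_ph[d$stratum == "RVS"])))
  expect_true(all(d$soil_ph[d$stratum == "PGS"] >= 5.5 &
                    d$soil_ph[d$stratum == "PGS"] <= 7.5))
  expect_true(all(is.na(d$soil_ph[d$stratum == "surface_water"])))
})

test_that("summarize_field_data computes the summary statistics exactly", {
  tiny <- tibble::tibble(site_id = c("a", "b"), stratum = "S", metal = "M",
                         concentration = c(10, 20), units = "mg/kg")
  s <- summarize_field_data(tiny)
  expect_equal(s$mean, 15)
  expect_equal(s$sd, sd(c(10, 20)), tolerance = 1e-12)
  expect_equal(c(s$minimum, s$maximum, s$n_sites), c(10, 20, 2))
  # single-record cells are omitted with a warning
  lonely <- dplyr::bind_rows(tiny, tibble::tibble(
    site_id = "c", stratum = "S", metal = "Lone", concentration = 1,
    units = "mg/kg"))
  expect_warning(s2 <- summarize_field_data(lonely), "fewer than 2")
  expect_false("Lone" %in% s2$metal)
})

test_that("generate -> summarize -> fit round-trips into sampler specs", {
  d <- generate_field_data(seed = 34, n_multiplier = 5)
  s <- summarize_field_data(d)
  expect_true(all(c("stratum", "metal", "mean", "sd", "minimum", "maximum",
                    "units", "n_sites") %in% names(s)))
  specs <- fit_summary_to_spec(s)
  expect_equal(nrow(specs), nrow(s))
  expect_true(all(specs$family == "lognormal"))
  # realized extrema sit inside the declared truncation bounds
  joined <- dplyr::left_join(
    s, concentration_summaries(),
    by = c("stratum", "metal"), suffix = c("_realized", "_declared")
  )
  expect_true(all(joined$minimum_realized >= joined$minimum_declared))
  expect_true(all(joined$maximum_realized <= joined$maximum_declared))
})

test_that("infeasible summaries are rejected", {
  bad <- concentration_summaries()
  bad$maximum[1] <- bad$mean[1] - 1
  expect_error(generate_field_data(bad, seed = 1), "infeasible")
  expect_error(generate_field_data(seed = 1, n_multiplier = 0.5), "n_multiplier")
})
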