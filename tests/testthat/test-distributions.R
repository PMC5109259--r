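# Parameter declaration and Monte Carlo sampling.

test_that("point family returns exact copies of the mean", {
  spec <- parameter_spec("EF_ia", "point", mean = 350)
  expect_identical(sample_parameter(spec, 5, seed = 1), rep(350, 5))
})

test_that("lognormal draws recover the declared arithmetic moments", {
  spec <- parameter_spec("BW", "lognormal", mean = 60, sd = 10)
  x <- sample_parameter(spec, 1e5, seed = 7)
  expect_lt(abs(mean(x) - 60), 0.2)
  expect_lt(abs(sd(x) - 10), 0.3)
  expect_true(all(x > 0))
})

test_that("lognormal with sd = 0 collapses to the mean", {
  spec <- parameter_spec("X", "lognormal", mean = 5, sd = 0)
  expect_identical(sample_parameter(spec, 10, seed = 1), rep(5, 10))
})

test_that("triangular draws match the closed-form mean and respect support", {
  spec <- parameter_spec("T", "triangular", mean = 1, min = 0, max = 2, mode = 1)
  x <- sample_parameter(spec, 1e5, seed = 3)
  expect_lt(abs(mean(x) - 1), 0.01)  # (a + b + c) / 3
  expect_true(all(x >= 0 & x <= 2))
  # asymmetric mode shifts the mean accordingly
  spec2 <- parameter_spec("T2", "triangular", mean = 1, min = 0, max = 3, mode = 0.6)
  x2 <- sample_parameter(spec2, 1e5, seed = 3)
  expect_lt(abs(mean(x2) - (0 + 0.6 + 3) / 3), 0.02)
})

test_that("truncation keeps every draw inside the declared bounds", {
  spec <- parameter_spec("C", "lognormal", mean = 0.10, sd = 0.07,
                         min = 0.03, max = 0.25)
  x <- sample_parameter(spec, 1e5, seed = 11)
  expect_true(all(x >= 0.03 & x <= 0.25))
})

test_that("infeasible truncation errors and names the parameter", {
  spec <- parameter_spec("narrow", "lognormal", mean = 10, sd = 10,
                         min = 9.99, max = 10.0)
  expect_error(sample_parameter(spec, 1000, seed = 1), "narrow")
})

test_that("draws are bit-identical given the same seed and unperturbed by new parameters", {
  specs <- dplyr::bind_rows(
    parameter_spec("A", "lognormal", 10, 3),
    parameter_spec("B", "triangular", 1, min = 0, max = 2)
  )
  d1 <- draw_parameter_matrix(specs, n = 500, seed = 99)
  d2 <- draw_parameter_matrix(specs, n = 500, seed = 99)
  expect_identical(d1, d2)
  # adding a third parameter leaves the existing streams untouched
  d3 <- draw_parameter_matrix(
    dplyr::bind_rows(specs, parameter_spec("C", "lognormal", 5, 1)),
    n = 500, seed = 99
  )
  expect_identical(d3$A, d1$A)
  expect_identical(d3$B, d1$B)
  # a different seed changes the draws
  expect_false(identical(draw_parameter_matrix(specs, n = 500, seed = 100)$A,
                         d1$A))
})

test_that("spec invariants are enforced", {
  expect_error(parameter_spec("X", "lognormal", mean = -1, sd = 1), "positive mean")
  expect_error(parameter_spec("X", "lognormal", mean = 5, sd = -1), "sd")
  expect_error(parameter_spec("X", "lognormal", mean = 5, sd = 1, min = 6, max = 10),
               "min exceeds mean")
  expect_error(parameter_spec("X", "triangular", mean = 1, min = 0, max = 2, mode = 5),
               "min <= mode <= max")
  expect_error(
    validate_parameter_specs(dplyr::bind_rows(
      parameter_spec("X", "point", 1), parameter_spec("X", "point", 2)
    )),
    "duplicated"
  )
})

test_that("summary rows convert to truncated-lognormal specifications", {
  spec <- fit_summary_to_spec(data.frame(
    stratum = "RVS", metal = "As", mean = 72.3, sd = 26.8,
    minimum = 34.7, maximum = 106.3, units = "mg/kg"
  ))
  expect_equal(spec$name, "conc_RVS_As")
  expect_equal(spec$family, "lognormal")
  expect_equal(unlist(spec[, c("mean", "sd", "min", "max")], use.names = FALSE),
               c(72.3, 26.8, 34.7, 106.3))
  # sd = 0 samples to the constant mean
  spec0 <- fit_summary_to_spec(data.frame(
    stratum = "S", metal = "M", mean = 3, sd = 0, minimum = 3, maximum = 3
  ))
  expect_identical(sample_parameter(spec0, 5, seed = 1), rep(3, 5))
  expect_error(
    fit_summary_to_spec(data.frame(stratum = "S", metal = "M", mean = 0,
                                   sd = 1, minimum = 0, maximum = 1)),
    "lognormal undefined"
  )
})

test_that("correlation induction hits targets while preserving marginals", {
  set.seed(42)
  draws <- tibble::tibble(u = runif(10000), v = runif(10000), w = runif(10000))
  out <- induce_correlations(draws, correlation_pairs("u", "v", 0.9), seed = 5)
  rho <- cor(out$u, out$v, method = "spearman")
  expect_gt(rho, 0.85)
  expect_lt(rho, 0.95)
  expect_identical(sort(out$u), sort(draws$u))
  expect_identical(sort(out$v), sort(draws$v))
  expect_identical(out$w, draws$w)  # uninvolved column untouched

  # negative target on uptake/sorption analogue columns
  set.seed(1)
  draws2 <- tibble::tibble(PUF = rlnorm(10000, 0, 0.5), Kd = rlnorm(10000, 3, 0.8))
  out2 <- induce_correlations(draws2, correlation_pairs("PUF", "Kd", -0.5), seed = 5)
  rho2 <- cor(out2$PUF, out2$Kd, method = "spearman")
  expect_gt(rho2, -0.55)
  expect_lt(rho2, -0.45)
  expect_identical(sort(out2$PUF), sort(draws2$PUF))
  expect_identical(sort(out2$Kd), sort(draws2$Kd))
})

test_that("empty correlation spec is the identity", {
  draws <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  expect_identical(induce_correlations(draws, NULL), draws)
  expect_identical(induce_correlations(draws, correlation_pairs(
    character(), character(), numeric())), draws)
})

test_that("unattainable correlation structures are rejected with the pairs named", {
  draws <- tibble::tibble(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  bad <- correlation_pairs(c("a", "a", "b"), c("b", "c", "c"),
                           c(0.9, 0.9, -0.9))
  expect_error(induce_correlations(draws, bad), "positive semi-definite")
  expect_error(induce_correlations(draws, correlation_pairs("a", "z", 0.5)),
               "not among draw columns")
  expect_error(correlation_pairs("a", "b", 1.2), "\\[-1, 1\\]")
})
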