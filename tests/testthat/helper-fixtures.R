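# Shared fixtures: constant draw matrices for deterministic collapse checks
# and small spec tables, all built in code.

# A draw matrix in which every parameter is a known constant, covering all
# columns the default study needs.
constant_draws <- function(n = 4L) {
  metals <- default_metal_properties()
  cols <- c(
    IR_s = 100, IR_sd = 50, IR_w = 2, IR_v = 0.3, IR_a = 15,
    EF_ia = 350, EF_oa = 225, EF_sw = 30, ET_sw = 1,
    ED = 24, BW = 60, SA_o = 0.5, SA_sw = 1.8,
    AF_sa = 0.2, AF_sr = 0.1, AF_sd = 0.3,
    theta_v = 0.9, theta_w = 0.3, rho_b = 1.5, DF = 20, PEF = 1.36e9
  )
  conc <- setNames(
    concentration_summaries()$mean,
    paste("conc", concentration_summaries()$stratum,
          concentration_summaries()$metal, sep = "_")
  )
  kd <- setNames(metals$kd, paste0("Kd_", metals$metal))
  puf <- setNames(metals$puf, paste0("PUF_", metals$metal))
  all <- c(cols, conc, kd, puf)
  tibble::as_tibble(lapply(all, rep, n))
}

# Independent order-statistic oracle for the type-7 percentile convention:
# sort, fractional index h = (n-1) p + 1, linear interpolation.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Analytic mean of a lognormal (arithmetic mean m, sd s) truncated to
# [lo, hi] -- the closed-form oracle for the synthetic-data generator.
oracle_truncated_lnorm_mean <- function(m, s, lo, hi) {
  sdlog2 <- log(1 + s^2 / m^2)
  mu <- log(m) - sdlog2 / 2
  sig <- sqrt(sdlog2)
  a <- (log(lo) - mu) / sig
  b <- (log(hi) - mu) / sig
  m * (pnorm(b - sig) - pnorm(a - sig)) / (pnorm(b) - pnorm(a))
}
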