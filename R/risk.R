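# Risk characterization: reduce per-iteration hazard-quotient samples to
# the reporting statistics used in screening tables (mean, percentiles,
# coefficient of variation, exceedance probability, contribution shares)
# and to cumulative-probability curves.

sum_within_groups <- function(hq_tbl, by) {
  hq_tbl <- tibble::as_tibble(hq_tbl)
  value_col <- if ("thq" %in% names(hq_tbl)) "thq" else "hq"
  lens <- unique(lengths(hq_tbl[[value_col]]))
  if (length(lens) != 1L) {
    abort("hazard-quotient vectors have mismatched iteration counts")
  }
  hq_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      samples = list(purrr::reduce(.data[[value_col]], `+`)),
      .groups = "drop"
    )
}

boot_p95_se <- function(x, n_boot, seed) {
  with_stream(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      quantile(sample(x, replace = TRUE), 0.95, names = FALSE, type = 7)
    }, numeric(1))
    sd(reps)
  })
}

#' Summarize hazard-quotient distributions
#'
#' Sums hazard quotients within each group per iteration (e.g. across metals
#' within a scenario-route cell) and reports the mean, median, 95th
#' percentile (linear interpolation between order statistics), coefficient
#' of variation in percent, and the probability of exceeding the safety
#' threshold. A group with zero mean but nonzero spread has an undefined CV:
#' it is reported as `NA` and flagged with a warning.
#'
#' @param hq_tbl An `rpra_hq` tibble from [compute_study_hq()] (or any tibble
#'   with grouping columns and an `hq`/`thq` list-column).
#' @param by Grouping columns, default `c("scenario", "route")`.
#' @param threshold Safety threshold for the exceedance probability.
#' @param boot_se If `TRUE`, attach a bootstrap standard error of the 95th
#'   percentile (`n_boot` resamples) so Monte Carlo scatter is quantified.
#' @param n_boot,seed Bootstrap replicates and seed (used only when
#'   `boot_se = TRUE`).
#' @return A tibble with one row per group: `mean, sd, p50, p95, cv_pct,
#'   exceed_pct, n_iter` (and `p95_se` when requested).
#' @export
summarize_risk <- function(hq_tbl, by = c("scenario", "route"), threshold = 1,
                           boot_se = FALSE, n_boot = 200L, seed = 1L) {
  if (any(!is.finite(threshold)) || threshold <= 0) {
    abort("threshold must be positive")
  }
  grouped <- sum_within_groups(hq_tbl, by)
  stats <- purrr::map(grouped$samples, function(x) {
    if (length(x) < 2L) abort("need at least 2 samples per group")
    m <- mean(x); s <- sd(x)
    cv <- if (m == 0 && s > 0) NA_real_ else if (m == 0) 0 else 100 * s / m
    row <- tibble::tibble(
      mean = m, sd = s,
      p50 = quantile(x, 0.5, names = FALSE, type = 7),
      p95 = quantile(x, 0.95, names = FALSE, type = 7),
      cv_pct = cv,
      exceed_pct = exceedance_probability(x, threshold),
      n_iter = length(x)
    )
    if (boot_se) row$p95_se <- boot_p95_se(x, n_boot, seed)
    row
  })
  out <- dplyr::bind_cols(grouped[by], dplyr::bind_rows(stats))
  if (any(is.na(out$cv_pct))) {
    warn("coefficient of variation undefined (zero mean, nonzero sd) for some groups")
  }
  out
}

#' Probability of exceeding a risk threshold
#'
#' The fraction of Monte Carlo iterations in which the hazard quotient
#' exceeds the threshold (default 1), in percent.
#'
#' @param samples Numeric vector of per-iteration hazard quotients.
#' @param threshold Positive threshold.
#' @return A percentage in `[0, 100]`.
#' @examples
#' exceedance_probability(c(0.5, 1.5, 2.0, 0.9))  # 50
#' @export
exceedance_probability <- function(samples, threshold = 1) {
  if (!is.numeric(samples) || !length(samples)) {
    abort("samples must be a non-empty numeric vector")
  }
  if (!is.finite(threshold) || threshold <= 0) abort("threshold must be positive")
  100 * sum(samples > threshold) / length(samples)
}

#' Contribution shares within a group
#'
#' Splits the group mean hazard quotient across the levels of `across`
#' (by default, metals within each scenario-route cell):
#' `share = 100 * mean(HQ_level) / sum(mean(HQ_levels))`. Shares are computed
#' on means so they are exactly additive to 100% per group; a group whose
#' levels are all zero has undefined shares, reported `NA` with a warning.
#'
#' @param hq_tbl An `rpra_hq` tibble from [compute_study_hq()].
#' @param within Grouping columns defining each 100% pot.
#' @param across Column whose levels share the pot.
#' @return A tibble with `within` and `across` columns, `mean_hq` and
#'   `share_pct`.
#' @export
contribution_shares <- function(hq_tbl, within = c("scenario", "route"),
                                across = "metal") {
  hq_tbl <- tibble::as_tibble(hq_tbl)
  value_col <- if ("thq" %in% names(hq_tbl)) "thq" else "hq"
  means <- hq_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(within, across)))) |>
    dplyr::summarise(
      mean_hq = mean(purrr::reduce(.data[[value_col]], `+`)),
      .groups = "drop"
    )
  out <- means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(within))) |>
    dplyr::mutate(
      share_pct = if (sum(.data$mean_hq) == 0) NA_real_ else
        100 * .data$mean_hq / sum(.data$mean_hq)
    ) |>
    dplyr::ungroup()
  if (any(is.na(out$share_pct))) {
    warn("contribution shares undefined for group(s) with all-zero hazard quotients")
  }
  out
}

#' Cumulative-probability curve of hazard quotients
#'
#' Empirical cumulative distribution of the per-iteration group totals,
#' suitable for plotting risk curves or exporting as (HQ, cumulative
#' probability) pairs. By construction `1 - cum_prob` at the threshold
#' equals the exceedance probability divided by 100.
#'
#' @inheritParams summarize_risk
#' @param points Maximum number of curve points per group (the full ecdf is
#'   thinned evenly to this size).
#' @return A tibble with the grouping columns, `hq` and `cum_prob`.
#' @export
cumulative_probability <- function(hq_tbl, by = c("scenario", "route"),
                                   points = 512L) {
  grouped <- sum_within_groups(hq_tbl, by)
  curves <- purrr::map(grouped$samples, function(x) {
    n <- length(x)
    idx <- if (n > points) unique(round(seq(1, n, length.out = points))) else seq_len(n)
    tibble::tibble(hq = sort(x)[idx], cum_prob = idx / n)
  })
  grouped$samples <- curves
  tidyr::unnest(dplyr::rename(grouped, curve = "samples"), "curve")
}
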