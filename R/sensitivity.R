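# Sensitivity analysis: rank input parameters by the correlation between
# their Monte Carlo draws and the scenario total hazard quotient.

#' Rank input parameters by correlation with an output
#'
#' Computes the rank (Spearman, default) or product-moment correlation of
#' every draw-matrix column with the per-iteration output, with a two-tailed
#' significance test, and returns the strongest `top_k` inputs ordered by
#' absolute correlation. Rank correlation is invariant to monotone
#' transforms of inputs or output, so it is robust to the lognormal skew of
#' the draws. Constant columns (point parameters) have undefined
#' correlation and are excluded with a warning.
#'
#' @param draws Draw matrix from [draw_parameter_matrix()].
#' @param output Numeric vector of per-iteration output values (e.g. a
#'   scenario THQ from [total_hq()]).
#' @param top_k Number of rows to return (default all).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha Two-tailed significance level for the `significant` flag.
#' @return A tibble of class `rpra_sensitivity` with columns
#'   `rank, parameter, rho, p_value, significant`; the correlation method is
#'   recorded in the `method` attribute.
#' @export
sensitivity_ranking <- function(draws, output, top_k = Inf,
                                method = c("spearman", "pearson"),
                                alpha = 0.01) {
  method <- match.arg(method)
  draws <- tibble::as_tibble(draws)
  if (!is.numeric(output)) abort("output must be a numeric vector")
  if (length(output) != nrow(draws)) {
    abort("draws and output have mismatched iteration counts")
  }
  if (top_k < 1) abort("top_k must be >= 1")
  n <- length(output)
  if (n < 3L) abort("need at least 3 iterations for a correlation test")

  constant <- vapply(draws, function(col) length(unique(col)) == 1L, logical(1))
  if (any(constant)) {
    warn(paste0("constant input column(s) excluded from sensitivity ranking: ",
                paste(names(draws)[constant], collapse = ", ")))
    draws <- draws[!constant]
  }
  if (!ncol(draws)) abort("no varying input columns to rank")

  x <- as.matrix(draws)
  if (method == "spearman") {
    x <- apply(x, 2, rank)
    output <- rank(output)
  }
  rho <- as.vector(cor(x, output))
  # two-tailed t approximation, the standard large-n test for both methods
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)

  out <- tibble::tibble(
    parameter = colnames(x), rho = rho, p_value = p,
    significant = p < alpha
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho))) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    head(n = if (is.finite(top_k)) top_k else nrow(draws))
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  class(out) <- c("rpra_sensitivity", class(out))
  out
}

#' Sensitivity rankings for every scenario of a study
#'
#' Applies [sensitivity_ranking()] to each scenario's total hazard quotient
#' against the shared draw matrix and stacks the results.
#'
#' @param draws Draw matrix from [draw_parameter_matrix()].
#' @param thq_tbl Per-scenario totals from [total_hq()].
#' @inheritParams sensitivity_ranking
#' @return A tibble with a leading `scenario` column.
#' @export
study_sensitivity <- function(draws, thq_tbl, top_k = 5L,
                              method = c("spearman", "pearson"),
                              alpha = 0.01) {
  method <- match.arg(method)
  # drop point-valued columns once, rather than once per scenario
  draws <- tibble::as_tibble(draws)
  draws <- draws[vapply(draws, function(col) length(unique(col)) > 1L, logical(1))]
  out <- purrr::map2(thq_tbl$scenario, thq_tbl$thq, function(sc, thq) {
    rk <- sensitivity_ranking(draws, thq, top_k = top_k, method = method,
                              alpha = alpha)
    dplyr::mutate(tibble::as_tibble(rk), scenario = sc, .before = 1)
  }) |>
    dplyr::bind_rows()
  attr(out, "method") <- method
  class(out) <- c("rpra_sensitivity", class(out))
  out
}
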