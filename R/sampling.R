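# Seeded Monte Carlo sampling of declared parameters, with Iman-Conover
# rank-correlation induction. Each parameter draws from its own stream,
# derived deterministically from (seed, name), so adding or removing a
# parameter never perturbs the draws of the others.

MAX_SEED <- 2147483646L  # 2^31 - 2; derived seeds stay below R's integer max

# Deterministic 31-bit string hash (djb2 variant), combined with the run seed.
param_stream_seed <- function(seed, name) {
  h <- 5381
  for (code in utf8ToInt(name)) h <- (h * 33 + code) %% MAX_SEED
  as.integer((abs(as.numeric(seed)) %% MAX_SEED * 48271 + h) %% MAX_SEED)
}

# Run `expr` under a local RNG state; the caller's stream is untouched.
with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed)
  force(expr)
}

# Inverse-CDF triangular sampler on (a, c, b) = (min, mode, max).
rtriangular <- function(n, min, mode, max) {
  u <- runif(n)
  f <- (mode - min) / (max - min)
  ifelse(u < f,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# Truncated lognormal via rejection, with an acceptance-rate guard.
rlnorm_truncated <- function(n, meanlog, sdlog, min, max, name) {
  out <- numeric(0)
  proposed <- 0L
  repeat {
    batch <- max(2L * (n - length(out)), 1000L)
    x <- rlnorm(batch, meanlog, sdlog)
    proposed <- proposed + batch
    x <- x[x >= min & x <= max]
    out <- c(out, x)
    if (length(out) >= n) return(out[seq_len(n)])
    if (proposed >= 10000L && length(out) / proposed < 0.01) {
      abort(paste0("parameter '", name, "': truncation bounds [", min, ", ",
                   max, "] exclude nearly all lognormal mass (acceptance < 1%)"))
    }
  }
}

#' Generate Monte Carlo trial values for one parameter
#'
#' Draws `n` values from the distribution declared in `spec`. Lognormal
#' specifications are parameterized from the arithmetic mean `m` and sd `s`
#' through the moment identities `meanlog = log(m^2 / sqrt(m^2 + s^2))` and
#' `sdlog^2 = log(1 + s^2/m^2)`, then rejection-truncated to `[min, max]`
#' when bounds are declared (so the *untruncated* distribution matches the
#' declared moments; truncation shifts the realized moments slightly).
#'
#' @param spec A one-row parameter table (see [parameter_spec()]).
#' @param n Number of iterations (>= 1).
#' @param seed Integer run seed; the parameter's private stream is derived
#'   from `(seed, spec$name)`.
#' @return A numeric vector of length `n`.
#' @examples
#' sample_parameter(parameter_spec("EF_ia", "point", mean = 350), n = 3, seed = 1)
#' @export
sample_parameter <- function(spec, n, seed) {
  spec <- validate_parameter_specs(spec)
  if (nrow(spec) != 1L) abort("sample_parameter() expects a single parameter row")
  if (n < 1) abort("n must be >= 1")
  s <- as.list(spec[1, ])
  if (s$family == "point") return(rep(s$mean, n))

  with_stream(param_stream_seed(seed, s$name), {
    if (s$family == "triangular") {
      mode <- if (is.finite(s$mode)) s$mode else pmin(pmax(s$mean, s$min), s$max)
      rtriangular(n, s$min, mode, s$max)
    } else {
      if (!is.finite(s$sd) || s$sd == 0) return(rep(s$mean, n))
      sdlog2 <- log(1 + s$sd^2 / s$mean^2)
      meanlog <- log(s$mean) - sdlog2 / 2
      lo <- if (is.finite(s$min)) s$min else 0
      hi <- if (is.finite(s$max)) s$max else Inf
      if (lo == 0 && !is.finite(hi)) {
        rlnorm(n, meanlog, sqrt(sdlog2))
      } else {
        rlnorm_truncated(n, meanlog, sqrt(sdlog2), lo, hi, s$name)
      }
    }
  })
}

#' Declare target rank correlations between parameters
#'
#' @param param1,param2 Character vectors of parameter names (recycled).
#' @param rho Target Spearman rank correlations in `[-1, 1]`.
#' @return A tibble with columns `param1, param2, rho`.
#' @examples
#' correlation_pairs(c("BW", "PUF_As"), c("SA_o", "Kd_As"), c(0.7, -0.7))
#' @export
correlation_pairs <- function(param1, param2, rho) {
  pairs <- tibble::tibble(param1 = as.character(param1),
                          param2 = as.character(param2),
                          rho = as.numeric(rho))
  if (any(abs(pairs$rho) > 1)) abort("rank correlations must lie in [-1, 1]")
  if (any(pairs$param1 == pairs$param2)) abort("a parameter cannot be paired with itself")
  pairs
}

#' Default inter-parameter dependence structure
#'
#' Body weight co-varies positively with both skin-surface-area parameters
#' (larger bodies expose more skin), the two skin areas co-vary with each
#' other for the same reason (without this third pair the triple would not
#' be jointly attainable), and each metal's plant uptake factor co-varies
#' negatively with its soil-water partition coefficient (stronger sorption
#' leaves less metal available for uptake).
#'
#' @param metals Character vector of metal names carrying `PUF_*`/`Kd_*`
#'   parameters.
#' @param bw_sa,puf_kd Magnitudes of the two dependence families.
#' @return A tibble of correlation pairs (see [correlation_pairs()]).
#' @export
default_correlations <- function(metals = default_metal_properties()$metal,
                                 bw_sa = 0.7, puf_kd = -0.7) {
  dplyr::bind_rows(
    correlation_pairs(c("BW", "BW", "SA_o"), c("SA_o", "SA_sw", "SA_sw"),
                      bw_sa),
    correlation_pairs(paste0("PUF_", metals), paste0("Kd_", metals), puf_kd)
  )
}

#' Impose target rank correlations on independent draws
#'
#' Distribution-free Iman-Conover reordering: each declared column is
#' re-sequenced to follow the ranks of a correlated normal-score matrix, so
#' every marginal distribution is preserved exactly (each output column is a
#' permutation of its input) while the achieved Spearman correlation of each
#' declared pair approaches its target. Columns not named in `pairs` are left
#' untouched; an empty `pairs` returns the input unchanged.
#'
#' The Spearman targets are mapped to Pearson correlations of the underlying
#' normal scores via `2 * sin(pi * rho / 6)` before factorization.
#'
#' @param draws A data frame of independent draws (iterations x parameters),
#'   e.g. from [draw_parameter_matrix()].
#' @param pairs A tibble from [correlation_pairs()].
#' @param seed Integer seed for the score permutations.
#' @return `draws` with the declared columns reordered.
#' @export
induce_correlations <- function(draws, pairs, seed = 1L) {
  draws <- tibble::as_tibble(draws)
  if (is.null(pairs) || nrow(pairs) == 0L) return(draws)
  pairs <- correlation_pairs(pairs$param1, pairs$param2, pairs$rho)
  unknown <- setdiff(unique(c(pairs$param1, pairs$param2)), names(draws))
  if (length(unknown)) {
    abort(paste0("correlation names not among draw columns: ",
                 paste(unknown, collapse = ", ")))
  }
  cols <- unique(c(rbind(pairs$param1, pairs$param2)))
  k <- length(cols)
  n <- nrow(draws)
  if (n < 2L) abort("need at least 2 iterations to induce correlations")

  target <- diag(k)
  dimnames(target) <- list(cols, cols)
  for (i in seq_len(nrow(pairs))) {
    r <- 2 * sin(pi * pairs$rho[i] / 6)  # Spearman -> normal-score Pearson
    target[pairs$param1[i], pairs$param2[i]] <- r
    target[pairs$param2[i], pairs$param1[i]] <- r
  }
  eig <- eigen(target, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    abort(paste0("declared correlations are not jointly attainable (matrix not ",
                 "positive semi-definite); offending pairs: ",
                 paste(pairs$param1, pairs$param2, sep = "~", collapse = ", ")))
  }
  # symmetric square root (tolerates the PSD boundary where chol() fails)
  root <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), k) %*% t(eig$vectors)

  scores <- with_stream(param_stream_seed(seed, "iman_conover"), {
    base <- qnorm(seq_len(n) / (n + 1))
    vapply(seq_len(k), function(j) sample(base), numeric(n))
  })
  # orthogonalize the sample scores, then rotate into the target structure
  e_chol <- chol(cor(scores))
  correlated <- scores %*% backsolve(e_chol, diag(k)) %*% root

  for (j in seq_len(k)) {
    col <- cols[j]
    draws[[col]] <- sort(draws[[col]])[rank(correlated[, j], ties.method = "first")]
  }
  draws
}

#' Draw a correlated Monte Carlo sample matrix
#'
#' Samples every parameter in `specs` independently from its private stream
#' (see [sample_parameter()]), then optionally imposes the declared rank
#' correlations by [induce_correlations()]. The result is bit-identical for
#' identical `(specs, correlations, seed, n)`.
#'
#' @param specs A parameter table (rows as in [parameter_spec()]).
#' @param n Number of iterations.
#' @param seed Integer run seed.
#' @param correlations Optional tibble from [correlation_pairs()].
#' @return A tibble with `n` rows and one column per parameter, with
#'   attributes `seed` and `n_iterations`.
#' @examples
#' specs <- dplyr::bind_rows(
#'   parameter_spec("BW", "lognormal", 60, 10, 40, 100, units = "kg"),
#'   parameter_spec("EF_oa", "point", 225, units = "d/yr")
#' )
#' draw_parameter_matrix(specs, n = 100, seed = 7)
#' @export
draw_parameter_matrix <- function(specs, n = 10000L, seed = 42L,
                                  correlations = NULL) {
  specs <- validate_parameter_specs(specs)
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    sample_parameter(specs[i, ], n = n, seed = seed)
  })
  draws <- tibble::as_tibble(setNames(cols, specs$name))
  draws <- induce_correlations(draws, correlations,
                               seed = param_stream_seed(seed, "correlation_stage"))
  attr(draws, "seed") <- seed
  attr(draws, "n_iterations") <- n
  draws
}
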