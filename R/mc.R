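#' Sample excess-risk coefficients from the asymptotic distribution
#'
#' Draws coefficient vectors from the multivariate normal centred at the
#' MLE with the fitted covariance of the excess block (the coefficients
#' defining the excess risk). Deterministic given the seed.
#'
#' @param fit a [fit_risk_model()] result with an available covariance.
#' @param n number of draws.
#' @param seed integer RNG seed.
#' @return an `n` x `n_excess` matrix with parameter names as columns.
#' @export
sample_params <- function(fit, n, seed) {
  V <- excess_vcov(fit)
  if (is.null(V)) {
    stop("covariance unavailable for this fit (singular information ",
         "matrix); Monte Carlo sampling refused", call. = FALSE)
  }
  mu <- fit$mle[fit$model$excess_params]
  draws <- withr::with_seed(as.integer(seed),
                            MASS::mvrnorm(n, mu = mu, Sigma = V))
  if (n == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(mu)))
  draws
}

#' Monte-Carlo ensemble of excess-risk realisations
#'
#' Evaluates the model's excess risk at each query point for every sampled
#' coefficient vector.
#'
#' @inheritParams sample_params
#' @param queries a [risk_query()] tibble.
#' @return object of class `mc_ensemble`: list with `model`, `queries`,
#'   `draws` (n x n_queries matrix), `estimate` (excess risk at the MLE)
#'   and `seed`.
#' @export
mc_ensemble <- function(fit, queries, n = 1000, seed = 1) {
  par_draws <- sample_params(fit, n, seed)
  full <- fit$mle
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(queries))
  for (i in seq_len(n)) {
    full[colnames(par_draws)] <- par_draws[i, ]
    draws[i, ] <- excess_risk(fit$model, full, queries)
  }
  structure(list(
    model = fit$model$name, family = fit$model$family, queries = queries,
    draws = draws, estimate = excess_risk(fit$model, fit$mle, queries),
    seed = as.integer(seed)
  ), class = "mc_ensemble")
}

#' Weighted empirical quantile (left-continuous inverse CDF)
#'
#' The package-wide percentile convention: the quantile at probability `p`
#' is the smallest pooled value whose cumulative normalized weight reaches
#' `p` (`inf {x : F(x) >= p}`), with no interpolation. With equal weights
#' this is the order statistic `x_(ceil(n*p))`. Worked example: values
#' `{1,2,3,4}` with total weight 0.5 pooled with `{10,20}` with total
#' weight 0.5 have weighted median 4.
#'
#' @param x numeric values.
#' @param w non-negative weights (recycled if scalar).
#' @param probs probabilities.
#' @return quantile values, one per probability.
#' @export
weighted_quantile <- function(x, w = 1, probs) {
  w <- rep_len(w, length(x))
  keep <- is.finite(x)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0) stop("no finite values to take quantiles of", call. = FALSE)
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) {
    x[ord][which(cw >= p - 1e-12)[1]]
  }, numeric(1))
}

#' Percentile confidence intervals from an MC ensemble
#'
#' Empirical percentile bounds (default 2.5% and 97.5%) of the realised
#' excess risks at each query, under the package's inverse-CDF percentile
#' convention. Non-finite realisations are excluded; their count is
#' reported in the `n_dropped` column. At zero dose every realisation's
#' excess vanishes, so both bounds are exactly 0.
#'
#' @param ensemble an [mc_ensemble()].
#' @param ci_level coverage (default 0.95).
#' @return tibble: one row per query with `estimate`, `lo`, `hi`,
#'   `n_dropped`.
#' @export
risk_ci <- function(ensemble, ci_level = 0.95) {
  stopifnot(ci_level > 0, ci_level < 1)
  pl <- (1 - ci_level) / 2
  qs <- ensemble$queries
  bounds <- vapply(seq_len(ncol(ensemble$draws)), function(j) {
    col <- ensemble$draws[, j]
    c(weighted_quantile(col, 1, c(pl, 1 - pl)), sum(!is.finite(col)))
  }, numeric(3))
  dplyr::mutate(qs, model = ensemble$model, estimate = ensemble$estimate,
                lo = bounds[1, ], hi = bounds[2, ], n_dropped = bounds[3, ],
                .before = 1)
}

#' Monte-Carlo convergence study of the CI width
#'
#' For each realisation count `N`, runs `n_repeats` independent ensembles
#' (sub-seeds derived deterministically from the master seed), records the
#' mean and repeat-to-repeat standard deviation of the 95% CI width at the
#' query, and the relative uncertainty of the width estimator,
#' `t_factor * sd / sqrt(n_repeats) / mean` — the small-sample-corrected
#' standard error of the mean width relative to the width itself.
#'
#' @param fit a fitted model with available covariance.
#' @param query a single-row [risk_query()].
#' @param n_list realisation counts (default the classic ladder
#'   5...10000).
#' @param n_repeats independent repeats per `N` (default 6).
#' @param t_factor small-sample correction factor (default 2.45, the 97.5%
#'   t-quantile used with six repeats).
#' @param ci_level coverage of the interval whose width is studied.
#' @param seed master seed.
#' @return a `convergence_table` tibble with columns `n`, `mean_width`,
#'   `sd_width`, `sd_width_corrected`, `rel_uncertainty`.
#' @export
convergence_study <- function(fit, query,
                              n_list = c(5, 10, 20, 50, 100, 200, 500, 1000,
                                         2000, 5000, 10000),
                              n_repeats = 6, t_factor = 2.45, ci_level = 0.95,
                              seed = 1) {
  stopifnot(nrow(query) == 1, !is.unsorted(n_list))
  rows <- purrr::map_dfr(seq_along(n_list), function(i) {
    widths <- vapply(seq_len(n_repeats), function(r) {
      ens <- mc_ensemble(fit, query, n = n_list[i],
                         seed = derive_seed(seed, i * 100 + r))
      ci <- risk_ci(ens, ci_level)
      ci$hi[1] - ci$lo[1]
    }, numeric(1))
    m <- mean(widths)
    s <- stats::sd(widths)
    corrected <- t_factor * s / sqrt(n_repeats)
    tibble::tibble(n = n_list[i], mean_width = m, sd_width = s,
                   sd_width_corrected = corrected,
                   rel_uncertainty = if (m == 0) 0 else corrected / m)
  })
  class(rows) <- c("convergence_table", class(rows))
  rows
}

# Deterministic sub-seed derivation (Lehmer step), kept within 32-bit range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 7919) %% 2147483629 + 1)
}

#' Smallest realisation count meeting a relative-uncertainty target
#'
#' @param table a [convergence_study()] result.
#' @param target_rel target relative uncertainty of the CI width (default
#'   0.05).
#' @return the smallest listed `n` whose relative uncertainty is at or
#'   below the target; the largest listed `n`, with a warning, if none
#'   qualifies.
#' @export
choose_n_realisations <- function(table, target_rel = 0.05) {
  stopifnot(nrow(table) > 0)
  ok <- which(table$rel_uncertainty <= target_rel)
  if (length(ok) == 0) {
    warning("no listed realisation count meets the target; returning the largest",
            call. = FALSE)
    return(table$n[nrow(table)])
  }
  table$n[ok[1]]
}
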