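#' Normalized information-criterion weights
#'
#' Akaike-style weights
#' `w_i = exp(-0.5 * (IC_i - min IC)) / sum_j exp(-0.5 * (IC_j - min IC))`,
#' applied identically to AIC and BIC values. Weights are invariant to
#' adding a constant to every IC value. Models with non-finite IC are
#' excluded with a warning.
#'
#' @param ic named numeric vector of IC values (names are model
#'   identifiers), or a data frame with columns `model` and `ic`.
#' @param criterion label, `"AIC"` or `"BIC"`.
#' @return a `weight_set` tibble with columns `model`, `ic`, `delta`,
#'   `weight`, ordered by decreasing weight.
#' @export
ic_weights <- function(ic, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (is.data.frame(ic)) ic <- stats::setNames(ic$ic, ic$model)
  if (is.null(names(ic)) || any(names(ic) == "")) {
    stop("IC values must be named by model", call. = FALSE)
  }
  bad <- !is.finite(ic)
  if (any(bad)) {
    warning("excluding model(s) with non-finite IC: ",
            paste(names(ic)[bad], collapse = ", "), call. = FALSE)
    ic <- ic[!bad]
  }
  if (length(ic) == 0) stop("no models with finite IC", call. = FALSE)
  delta <- ic - min(ic)
  w <- exp(-0.5 * delta)
  w <- w / sum(w)
  out <- tibble::tibble(model = names(ic), ic = unname(ic),
                        delta = unname(delta), weight = unname(w))
  out <- dplyr::arrange(out, dplyr::desc(.data$weight))
  attr(out, "criterion") <- criterion
  attr(out, "pruned") <- FALSE
  class(out) <- c("weight_set", class(out))
  out
}

#' Drop negligible-weight models and renormalize
#'
#' @param ws a [ic_weights()] result.
#' @param threshold minimum weight to keep (default 0.01).
#' @return a pruned, renormalized `weight_set`. If every weight falls
#'   below the threshold, the largest-weight model is kept with weight 1,
#'   with a warning.
#' @export
prune_weights <- function(ws, threshold = 0.01) {
  keep <- ws$weight >= threshold
  if (!any(keep)) {
    warning("all weights below threshold; keeping the largest-weight model",
            call. = FALSE)
    keep <- seq_len(nrow(ws)) == which.max(ws$weight)
  }
  out <- ws[keep, ]
  out$weight <- out$weight / sum(out$weight)
  attr(out, "criterion") <- attr(ws, "criterion")
  attr(out, "pruned") <- TRUE
  attr(out, "threshold") <- threshold
  class(out) <- c("weight_set", class(tibble::tibble()))
  out
}

#' Model-averaged (composite) excess risk
#'
#' The composite excess risk at each query is the weighted sum of the
#' per-model risks. ERR and EAR families carry separate weight sets and
#' are never averaged together.
#'
#' @param ws a `weight_set`.
#' @param per_model_risks named list (or matrix with model rows) of
#'   per-query risk vectors, one entry per weighted model.
#' @return numeric vector of composite risks, one per query.
#' @export
composite_risk <- function(ws, per_model_risks) {
  if (is.matrix(per_model_risks)) {
    per_model_risks <- stats::setNames(
      lapply(seq_len(nrow(per_model_risks)), function(i) per_model_risks[i, ]),
      rownames(per_model_risks))
  }
  missing <- setdiff(ws$model, names(per_model_risks))
  if (length(missing) > 0) {
    stop("missing risk values for weighted model(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- do.call(rbind, per_model_risks[ws$model])
  as.vector(ws$weight %*% vals)
}

#' Weighted-percentile CI of the composite excess risk
#'
#' Pools the MC realisations of every weighted model, assigning each
#' realisation of model `i` mass `w_i / n_i`, and takes the percentile
#' bounds of the resulting mixture distribution under the package's
#' inverse-CDF convention ([weighted_quantile()]). With a single weight-1
#' model this reproduces [risk_ci()] exactly.
#'
#' @param ws a `weight_set`.
#' @param ensembles named list of [mc_ensemble()] objects covering every
#'   weighted model; all must share the same query grid.
#' @param ci_level coverage (default 0.95).
#' @return tibble with the query columns plus composite `estimate`
#'   (weighted mean of the per-model MLE risks), `lo` and `hi`.
#' @export
composite_ci <- function(ws, ensembles, ci_level = 0.95) {
  missing <- setdiff(ws$model, names(ensembles))
  if (length(missing) > 0) {
    stop("missing ensemble(s) for weighted model(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ensembles <- ensembles[ws$model]
  q1 <- ensembles[[1]]$queries
  for (e in ensembles) {
    if (!identical(dim(e$queries), dim(q1))) {
      stop("ensembles do not share a query grid", call. = FALSE)
    }
  }
  pl <- (1 - ci_level) / 2
  n_q <- ncol(ensembles[[1]]$draws)
  bounds <- vapply(seq_len(n_q), function(j) {
    x <- unlist(lapply(ensembles, function(e) e$draws[, j]), use.names = FALSE)
    w <- unlist(lapply(seq_along(ensembles), function(i) {
      rep(ws$weight[i] / nrow(ensembles[[i]]$draws), nrow(ensembles[[i]]$draws))
    }), use.names = FALSE)
    if (all(!is.finite(x))) stop("empty pooled realisation set", call. = FALSE)
    weighted_quantile(x, w, c(pl, 1 - pl))
  }, numeric(2))
  est <- composite_risk(ws, lapply(ensembles, function(e) e$estimate))
  dplyr::mutate(q1, estimate = est, lo = bounds[1, ], hi = bounds[2, ],
                .before = 1)
}
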