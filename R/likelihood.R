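#' Grouped-Poisson negative log-likelihood
#'
#' Full Poisson negative log-likelihood of a model on a cohort table:
#' `sum over cells of mu - y*log(mu) + log(y!)` with `mu = pyr * lambda`.
#' Cells with `pyr = 0` are excluded. Parameter values composing to a
#' non-positive rate on any likelihood cell are infeasible: the value is
#' `+Inf` with attribute `infeasible = TRUE`.
#'
#' @param model a [risk_model()].
#' @param params named parameter vector (baseline block plus excess block;
#'   for stratified baselines the per-stratum log rates `s_<stratum>`).
#' @param table a [cohort_table()].
#' @return the negative log-likelihood (scalar).
#' @export
neg_log_likelihood <- function(model, params, table) {
  tab <- likelihood_cells(model, table)
  lambda <- cell_rate(model, params, tab)
  poisson_nll(tab$cases, tab$pyr * lambda)
}

likelihood_cells <- function(model, table) {
  tab <- table[table$pyr > 0, ]
  if (!is.null(model$dose_cap)) tab <- truncate_dose(tab, model$dose_cap)
  tab
}

poisson_nll <- function(y, mu) {
  if (any(!is.finite(mu)) || any(mu < 0) || any(mu == 0 & y > 0)) {
    return(structure(Inf, infeasible = TRUE))
  }
  ylogmu <- ifelse(y > 0, y * log(mu), 0)
  sum(mu - ylogmu + lfactorial(y))
}

# Penalized objective value for the optimizer: finite, increasing with the
# amount of infeasibility so line searches are pushed back into the
# feasible region.
penalized_nll <- function(y, mu) {
  bad <- !is.finite(mu) | mu < 0 | (mu == 0 & y > 0)
  if (any(bad)) {
    infeas <- sum(pmax(0, -mu[is.finite(mu)])) + sum(!is.finite(mu))
    return(1e9 * (1 + infeas))
  }
  ylogmu <- ifelse(y > 0, y * log(mu), 0)
  sum(mu - ylogmu + lfactorial(y))
}

#' Profile out a stratified baseline
#'
#' For fixed excess parameters, each stratum's baseline rate has a closed
#' conditional maximum-likelihood solution in the ERR (multiplicative)
#' structure, `lambda0_j = sum(y) / sum(pyr * (1 + ERR))`; in the EAR
#' (additive) structure it is obtained by one-dimensional root finding on
#' the score equation. Strata with zero cases sit at the boundary
#' `lambda0_j = 0`.
#'
#' @param model a [risk_model()] with a stratified baseline.
#' @param excess_params named vector covering the excess block.
#' @param table a [cohort_table()].
#' @return named vector of per-stratum log rates (`-Inf` for zero-case
#'   boundary strata).
#' @export
profile_stratified_baseline <- function(model, excess_params, table) {
  stopifnot(model$baseline_type == "stratified")
  tab <- likelihood_cells(model, table)
  xs <- excess_risk(model, excess_params, tab)
  lab <- strata_labels(model$baseline_form, tab)
  rates <- profile_strata_rates(model$family, tab$cases, tab$pyr, xs, lab)
  stats::setNames(log(rates), paste0("s_", names(rates)))
}

profile_strata_rates <- function(family, y, pyr, xs, lab) {
  f <- factor(lab, levels = unique(lab))
  Y <- tapply(y, f, sum)
  if (family == "ERR") {
    r <- 1 + xs
    Tj <- tapply(pyr * r, f, sum)
    if (any(Y > 0 & Tj <= 0)) {
      stop("stratum with positive cases but zero adjusted person-time",
           call. = FALSE)
    }
    rates <- ifelse(Y > 0, Y / Tj, 0)
  } else {
    rates <- vapply(levels(f), function(j) {
      idx <- f == j
      yj <- y[idx]; pj <- pyr[idx]; ej <- xs[idx]
      if (sum(yj) == 0) return(0)
      score <- function(l0) sum(pj) - sum(yj / (l0 + ej))
      upper <- sum(yj) / sum(pj) + max(0, -min(ej)) + 1
      lower <- max(0, -min(ej[yj > 0])) + 1e-12
      if (score(lower) >= 0) return(lower)
      stats::uniroot(score, c(lower, upper), extendInt = "upX",
                     tol = 1e-12)$root
    }, numeric(1))
    names(rates) <- levels(f)
  }
  rates
}

# Profiled NLL over the excess block for stratified-baseline ERR models.
profiled_nll_err <- function(y, pyr, xs, f) {
  r <- 1 + xs
  if (any(r <= 0)) return(1e9 * (1 + sum(pmax(0, -r))))
  Y <- tapply(y, f, sum)
  Tj <- tapply(pyr * r, f, sum)
  lam0 <- ifelse(Y > 0, Y / Tj, 0)
  ylog <- ifelse(Y > 0, Y * log(lam0), 0)
  sum(Y) - sum(ylog) - sum(ifelse(y > 0, y * log(pyr * r), 0)) +
    sum(lfactorial(y))
}

#' Fit a risk model to a grouped cohort by maximum likelihood
#'
#' Minimizes the grouped-Poisson negative log-likelihood with a
#' quasi-Newton optimizer (BFGS, numerical gradients) and multiple starts.
#' Parametric baselines are fitted jointly with the excess block
#' (initialised from a Poisson GLM of the baseline alone); stratified
#' baselines are profiled out analytically, so only the excess block is
#' optimised and each stratum still counts as one parameter in AIC/BIC.
#' Model-declared preprocessing (the Preston 4 Gy dose cap) is applied
#' automatically.
#'
#' The covariance matrix is the inverse of the observed information
#' (symmetric central-difference Hessian, relative step 1e-4) at the MLE;
#' a condition number above 1e12 marks it unavailable. AIC uses
#' `2*k - 2*logLik`, BIC uses `k*log(n_cells) - 2*logLik`, with the full
#' Poisson log-likelihood (including `log(y!)`; the constant cancels in
#' weight calculations).
#'
#' @param model a [risk_model()].
#' @param table a [cohort_table()].
#' @param constant_baseline optional parametric baseline form id (e.g.
#'   `"preston"`) replacing the model's own baseline: the constant-baseline
#'   fitting strategy, with baseline coefficients re-estimated jointly.
#' @param init optional named start vector for the free parameters.
#' @param fixed optional named vector of parameters held at the given
#'   values (Epicure-style fixing); they are excluded from the free block
#'   and from the parameter count.
#' @param n_starts number of optimizer starts (first is the GLM-informed
#'   start, the rest deterministic jitters of it).
#' @param control optional list: `maxit` (default 600), `reltol`
#'   (default 1e-10).
#' @return an object of class `risk_fit`.
#' @export
fit_risk_model <- function(model, table, constant_baseline = NULL, init = NULL,
                           fixed = NULL, n_starts = 3, control = list()) {
  if (!is.null(constant_baseline)) model <- with_baseline(model, constant_baseline)
  tab <- likelihood_cells(model, table)
  if (nrow(tab) == 0) stop("no cells with positive person-years", call. = FALSE)
  y <- tab$cases
  pyr <- tab$pyr
  stratified <- model$baseline_type == "stratified"
  maxit <- control$maxit %||% 600
  reltol <- control$reltol %||% 1e-10

  if (!is.null(fixed) && is.null(names(fixed))) {
    stop("fixed must be a named vector", call. = FALSE)
  }
  if (stratified) {
    all_free <- model$excess_params
    f <- factor(strata_labels(model$baseline_form, tab),
                levels = unique(strata_labels(model$baseline_form, tab)))
    if (model$family != "ERR") {
      stop("stratified baselines are profiled analytically only for ERR ",
           "models (the registered set); see profile_stratified_baseline()",
           call. = FALSE)
    }
    free <- setdiff(all_free, names(fixed))
    objective <- function(theta) {
      full <- c(stats::setNames(theta, free), fixed)
      xs <- excess_risk(model, full, tab)
      profiled_nll_err(y, pyr, xs, f)
    }
    n_extra <- nlevels(f)
  } else {
    X <- baseline_design(model$baseline_form, tab)
    all_free <- c(colnames(X), model$excess_params)
    free <- setdiff(all_free, names(fixed))
    objective <- function(theta) {
      full <- c(stats::setNames(theta, free), fixed)[all_free]
      lam0 <- exp(as.vector(X %*% full[colnames(X)]))
      xs <- excess_risk(model, full, tab)
      lambda <- if (model$family == "ERR") lam0 * (1 + xs) else lam0 + xs
      penalized_nll(y, pyr * lambda)
    }
    n_extra <- 0L
  }
  bad_fixed <- setdiff(names(fixed), all_free)
  if (length(bad_fixed) > 0) {
    stop("fixed parameter(s) not in the model: ",
         paste(bad_fixed, collapse = ", "), call. = FALSE)
  }

  parscale <- make_params(free, 1)
  if (model$family == "EAR") {
    dose_pars <- intersect(c("alpha", "beta", "alpha_m", "alpha_f"), free)
    parscale[dose_pars] <- 1e-3
  }

  starts <- build_starts(model, tab, free, init, n_starts)
  run_one <- function(st) {
    # restarting BFGS resets its curvature approximation, which polishes
    # optima in the nearly-flat directions of weakly identified modifiers
    out <- stats::optim(st, objective, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol,
                                       parscale = unname(parscale[free])))
    for (round in 1:3) {
      nxt <- stats::optim(out$par, objective, method = "BFGS",
                          control = list(maxit = maxit, reltol = reltol,
                                         parscale = unname(parscale[free])))
      improved <- out$value - nxt$value
      if (nxt$value <= out$value) out <- nxt
      if (improved < 1e-8 * max(1, abs(out$value))) break
    }
    out
  }
  runs <- lapply(starts, function(st) {
    tryCatch(run_one(st),
             error = function(e) list(value = Inf, convergence = 99L,
                                      par = st, message = conditionMessage(e)))
  })
  best <- runs[[which.min(vapply(runs, function(r) r$value, numeric(1)))]]
  mle <- stats::setNames(best$par, free)
  grad <- central_gradient(objective, mle)
  gradient_norm <- sqrt(sum(grad^2))
  converged <- is.finite(best$value) && best$convergence == 0
  fit_log <- c(
    sprintf("model=%s family=%s baseline=%s", model$name, model$family,
            model$baseline_form),
    sprintf("starts=%d best_value=%.6f optim_code=%d", length(starts),
            best$value, best$convergence),
    sprintf("gradient_norm=%.3e", gradient_norm)
  )
  if (!converged) fit_log <- c(fit_log, "WARNING: optimizer did not converge")

  hess <- central_hessian(objective, mle)
  vcov <- NULL
  if (all(is.finite(hess)) && all(diag(hess) > 0)) {
    # invert on the correlation scale so disparate parameter scales do not
    # masquerade as singularity; refuse only genuinely degenerate cases
    d <- sqrt(diag(hess))
    hs <- hess / tcrossprod(d)
    cond <- tryCatch(kappa(hs, exact = TRUE), error = function(e) Inf)
    if (is.finite(cond) && cond < 1e12) {
      vs <- tryCatch(solve(hs), error = function(e) NULL)
      if (!is.null(vs)) {
        vcov <- vs / tcrossprod(d)
        vcov <- (vcov + t(vcov)) / 2
        dimnames(vcov) <- list(free, free)
      }
    } else {
      fit_log <- c(fit_log,
                   sprintf("covariance unavailable: information matrix condition %.3g", cond))
    }
  } else {
    fit_log <- c(fit_log, "covariance unavailable: non-finite or non-positive curvature")
  }

  mle_full <- c(mle, fixed)
  strata_rates <- NULL
  if (stratified) {
    strata_rates <- profile_stratified_baseline(model, mle_full, table)
  }
  loglik <- -best$value
  ll_sat <- sum(stats::dpois(y, y, log = TRUE))
  k <- length(free) + n_extra
  n_cells <- nrow(tab)
  structure(list(
    model = model, mle = mle_full, free = free, fixed = fixed,
    strata_rates = strata_rates, vcov = vcov,
    loglik = loglik, deviance = 2 * (ll_sat - loglik), n_params = k,
    n_cells = n_cells, aic = 2 * k - 2 * loglik,
    bic = k * log(n_cells) - 2 * loglik, converged = converged,
    gradient_norm = gradient_norm, fit_log = fit_log
  ), class = "risk_fit")
}

with_baseline <- function(model, form) {
  if (!form %in% c("grant", "preston", "beir_ar", "ozasa_ar", "unscear")) {
    stop("unknown parametric baseline form '", form, "'", call. = FALSE)
  }
  model$baseline_type <- "parametric"
  model$baseline_form <- form
  model$baseline_params <- baseline_param_names(form)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_starts <- function(model, tab, free, init, n_starts) {
  base <- make_params(free)
  if (!is.null(init)) {
    base[names(init)] <- init
  } else {
    if (model$baseline_type == "parametric") {
      X <- baseline_design(model$baseline_form, tab)
      co <- tryCatch(suppressWarnings(
        stats::glm.fit(X, tab$cases, offset = log(tab$pyr),
                       family = stats::poisson())$coefficients),
        error = function(e) NULL)
      if (!is.null(co)) {
        co[!is.finite(co)] <- 0
        base[colnames(X)] <- co
      } else {
        base[grep("^k1|^k0", free)] <- log(max(sum(tab$cases), 1) / sum(tab$pyr))
      }
    }
    scale <- if (model$family == "EAR") sum(tab$cases) / sum(tab$pyr) else 1
    for (nm in intersect(c("alpha", "alpha_m", "alpha_f"), free)) {
      base[nm] <- 0.1 * scale
    }
  }
  starts <- list(base)
  if (n_starts > 1) {
    for (j in seq_len(n_starts - 1)) {
      jit <- withr::with_seed(1000L + j, stats::rnorm(length(free), sd = 0.2))
      st <- base + jit * pmax(abs(base), if (model$family == "EAR") 1e-3 else 0.1)
      starts[[j + 1]] <- st
    }
  }
  starts
}

central_gradient <- function(fn, x, rel_step = 1e-6) {
  h <- rel_step * pmax(abs(x), 1)
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    (fn(xp) - fn(xm)) / (2 * h[i])
  }, numeric(1))
}

# Symmetric central-difference Hessian, base per-parameter relative step
# 1e-4 (absolute 1e-4 below magnitude 1). Weakly identified directions have
# curvature signals below floating-point noise at that step; the step is
# then widened geometrically (up to 0.5) until the second difference is
# resolvable, so near-flat curvatures are measured at the scale where they
# exist instead of being read from rounding noise.
central_hessian <- function(fn, x, rel_step = 1e-4) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  noise <- 1e4 * .Machine$double.eps * max(abs(f0), 1)
  for (i in seq_len(p)) {
    repeat {
      xp <- x; xm <- x
      xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
      d2 <- fn(xp) - 2 * f0 + fn(xm)
      if (abs(d2) > noise || h[i] >= 0.5) break
      h[i] <- h[i] * 4
    }
    H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h[i]^2
  }
  if (p > 1) {
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.risk_fit <- function(x, ...) {
  cat(sprintf("<risk_fit %s [%s]%s>\n", x$model$name, x$model$family,
              if (!x$converged) " NOT CONVERGED" else ""))
  cat(sprintf("  logLik %.3f  deviance %.3f  AIC %.1f  BIC %.1f  (k=%d, cells=%d)\n",
              x$loglik, x$deviance, x$aic, x$bic, x$n_params, x$n_cells))
  invisible(x)
}

#' Covariance of the excess-risk coefficient block
#'
#' @param fit a [fit_risk_model()] result.
#' @return covariance matrix over the excess parameters, or `NULL` when the
#'   information matrix was too ill-conditioned.
#' @export
excess_vcov <- function(fit) {
  if (is.null(fit$vcov)) return(NULL)
  idx <- intersect(fit$model$excess_params, colnames(fit$vcov))
  fit$vcov[idx, idx, drop = FALSE]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a fitted risk model
#'
#' @param x a `risk_fit`.
#' @param ... unused.
#' @return tibble with term, block (baseline/excess), estimate and
#'   standard error (where the covariance is available).
#' @method tidy risk_fit
#' @export
tidy.risk_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, length(x$mle))
  tibble::tibble(
    term = names(x$mle),
    block = ifelse(names(x$mle) %in% x$model$excess_params, "excess", "baseline"),
    estimate = unname(x$mle),
    std.error = unname(se)
  )
}

#' One-row fit summary
#'
#' @param x a `risk_fit`.
#' @param ... unused.
#' @return tibble with log-likelihood, deviance, AIC, BIC, parameter and
#'   cell counts and convergence status.
#' @method glance risk_fit
#' @export
glance.risk_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name, family = x$model$family,
    baseline = x$model$baseline_form, logLik = x$loglik,
    deviance = x$deviance, AIC = x$aic, BIC = x$bic,
    n_params = x$n_params, n_cells = x$n_cells, converged = x$converged
  )
}

#' Plausibility screen for fitted models
#'
#' The linear-quadratic-exponential model is excluded from multi-model
#' inference when its fitted curvature is negative while the exponential
#' cell-sterilisation coefficient is positive, a combination that makes the
#' excess risk fall off implausibly at high doses. All other models pass.
#'
#' @param fit a `risk_fit`.
#' @return list with `plausible` (logical) and `reason` (text).
#' @export
plausibility_check <- function(fit) {
  if (fit$model$name == "LittleLQE") {
    beta <- fit$mle[["beta"]]
    delta <- fit$mle[["delta"]]
    if (beta < 0 && delta > 0) {
      return(list(plausible = FALSE,
                  reason = sprintf(
                    "beta = %.4g (negative) and delta = %.4g (positive): excess risk decreases implausibly with dose",
                    beta, delta)))
    }
    return(list(plausible = TRUE,
                reason = sprintf("beta = %.4g, delta = %.4g", beta, delta)))
  }
  list(plausible = TRUE, reason = "rule applies to the LQE model only")
}

#' Rank candidate parametric baselines by AIC
#'
#' Fits each candidate baseline alone (zero excess risk) to the table and
#' ranks by AIC; the winner is the baseline used by the constant-baseline
#' fitting strategy.
#'
#' @param table a [cohort_table()].
#' @param candidates parametric baseline form ids.
#' @return list with `best` (form id) and `table` (per-candidate AIC tibble).
#' @export
select_best_baseline <- function(table,
                                 candidates = c("grant", "preston", "beir_ar",
                                                "ozasa_ar", "unscear")) {
  fits <- purrr::map(candidates, function(form) {
    tryCatch(fit_baseline_only(form, table), error = function(e) NULL)
  })
  rows <- purrr::map2_dfr(candidates, fits, function(form, f) {
    if (is.null(f) || !f$converged) {
      if (is.null(f)) {
        warning("baseline '", form, "' failed to fit; excluded", call. = FALSE)
      } else {
        warning("baseline '", form, "' did not converge; excluded", call. = FALSE)
      }
      return(tibble::tibble(baseline = form, n_params = NA_integer_,
                            logLik = NA_real_, AIC = NA_real_,
                            converged = FALSE))
    }
    tibble::tibble(baseline = form, n_params = f$n_params, logLik = f$loglik,
                   AIC = f$aic, converged = TRUE)
  })
  ok <- rows[rows$converged, ]
  if (nrow(ok) == 0) stop("no candidate baseline converged", call. = FALSE)
  list(best = ok$baseline[which.min(ok$AIC)], table = rows)
}

fit_baseline_only <- function(form, table) {
  tab <- table[table$pyr > 0, ]
  X <- baseline_design(form, tab)
  y <- tab$cases
  pyr <- tab$pyr
  objective <- function(k) penalized_nll(y, pyr * exp(as.vector(X %*% k)))
  start <- make_params(colnames(X))
  co <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, offset = log(pyr), family = stats::poisson())$coefficients),
    error = function(e) NULL)
  if (!is.null(co)) {
    co[!is.finite(co)] <- 0
    start[colnames(X)] <- co
  }
  opt <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 600, reltol = 1e-10))
  k <- ncol(X)
  ll <- -opt$value
  structure(list(
    model = list(name = paste0("baseline:", form), family = "baseline",
                 baseline_form = form, excess_params = character(0)),
    mle = stats::setNames(opt$par, colnames(X)), vcov = NULL, loglik = ll,
    deviance = 2 * (sum(stats::dpois(y, y, log = TRUE)) - ll),
    n_params = k, n_cells = nrow(tab), aic = 2 * k - 2 * ll,
    bic = k * log(nrow(tab)) - 2 * ll, converged = opt$convergence == 0,
    gradient_norm = NA_real_, fit_log = character(0)
  ), class = "risk_fit")
}
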