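#' Configuration for the synthetic cohort generator
#'
#' Defines an LSS-like grouped covariate grid (2 cities x 2 sexes x dose
#' categories x age-at-exposure categories x attained-age categories, plus
#' a not-in-city block at zero dose) and the "true" model whose rates
#' generate the Poisson case counts. Person-years are allocated across the
#' grid proportionally to `exp(-pyr_decay * (a - e)) * exp(-dose_decay * d)`
#' and normalized to `total_pyr`, reproducing the qualitative LSS features
#' that late attained ages and high doses carry few person-years. Birth
#' year is derived as `exposure_year - age_at_exposure`.
#'
#' @param seed integer RNG seed; every stochastic operation requires one.
#' @param dose_values dose grid in Gy (default 0 plus 7 log-spaced values
#'   between 0.05 and 4).
#' @param e_values age-at-exposure category midpoints, years.
#' @param a_values attained-age category midpoints, years; only cells with
#'   `a > e` are generated.
#' @param total_pyr total person-years allocated over the table.
#' @param pyr_decay exponential decay rate (per year of time since
#'   exposure) of the person-year allocation.
#' @param dose_decay exponential decay rate (per Gy) of the person-year
#'   allocation across dose categories.
#' @param frac_nic fraction of person-years in the not-in-city group.
#' @param frac_kerma_gt4 fraction of the top dose category's person-years
#'   flagged as shielded kerma > 4 Gy.
#' @param exposure_year calendar year defining `birth_year = exposure_year - e`.
#' @param true_model a [risk_model()] generating the counts.
#' @param true_params named parameter vector for `true_model`.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             dose_values = c(0, signif(exp(seq(log(0.05), log(4), length.out = 7)), 3)),
                             e_values = seq(5, 75, by = 10),
                             a_values = seq(15, 95, by = 10),
                             total_pyr = 5e6,
                             pyr_decay = 0.02,
                             dose_decay = 2,
                             frac_nic = 0.2,
                             frac_kerma_gt4 = 0.02,
                             exposure_year = 1945,
                             true_model = risk_model("GrantL", "ERR"),
                             true_params = default_true_params(true_model)) {
  stopifnot(
    all(dose_values >= 0), !is.unsorted(dose_values),
    frac_nic >= 0, frac_nic <= 1, frac_kerma_gt4 >= 0, frac_kerma_gt4 <= 1,
    total_pyr > 0, pyr_decay >= 0
  )
  structure(list(
    seed = as.integer(seed), dose_values = dose_values, e_values = e_values,
    a_values = a_values, total_pyr = total_pyr, pyr_decay = pyr_decay,
    dose_decay = dose_decay, frac_nic = frac_nic,
    frac_kerma_gt4 = frac_kerma_gt4, exposure_year = exposure_year,
    true_model = true_model, true_params = true_params
  ), class = "generator_config")
}

#' Plausible "true" parameters for a generator model
#'
#' Round-number coefficients of LSS-like magnitude: a sex-averaged ERR
#' near 0.5 at 1 Gy (females above males), risk decreasing with attained
#' age and age at exposure, a baseline solid-cancer rate near 1e-2 per
#' person-year at age 70 rising steeply with age. EAR-family doses scale
#' the response to roughly 50 excess cases per 1e4 person-years per Gy.
#'
#' @param model a [risk_model()].
#' @return named parameter vector covering baseline and excess blocks.
#' @export
default_true_params <- function(model) {
  scale <- if (model$family == "EAR") 5e-3 else 1
  excess <- switch(model$excess_form,
    grant = c(alpha = 0.5 * scale, beta = 0.1 * scale, tau = -0.2, nu = -1.5,
              phi = -0.5, sigma = 0.3),
    beir = c(alpha_m = 0.35 * scale, alpha_f = 0.6 * scale, tau = -0.3, nu = -1.4),
    inworks = c(alpha = 0.5 * scale, beta = 0.1 * scale, tau = -0.2,
                nu1 = -1.0, nu2 = -1.5, nu3 = -2.0, sigma = 0.3),
    unscear = c(alpha = 0.5 * scale, beta = 0.05 * scale, sigma = 0.25,
                epsilon = -0.8, nu = -0.5),
    little = c(alpha = 0.5 * scale, beta = 0.05 * scale, delta = -0.05,
               sigma = 0.25, epsilon = -0.8, nu = -0.5)
  )
  excess <- excess[names(excess) %in% model$excess_params]
  if (model$baseline_type == "stratified") {
    return(excess)  # stratum log-rates are derived from the grid at generation time
  }
  base <- make_params(model$baseline_params)
  base[grep("^k1_m", names(base))] <- log(0.012)
  base[grep("^k1_f", names(base))] <- log(0.009)
  if (model$baseline_form %in% c("grant", "preston")) {
    base[c("k2_m", "k2_f")] <- if (model$baseline_form == "grant") 5 else 0.05
    if (model$baseline_form == "preston") base[c("k3_m", "k3_f")] <- 5
    base[c("cnic_h", "cnic_n")] <- -0.1
  }
  if (model$baseline_form == "grant") base["k5"] <- 0.25
  if (model$baseline_form %in% c("beir_ar", "ozasa_ar")) base[c("k5_m", "k5_f")] <- 5
  if (model$baseline_form == "unscear") {
    base["k0"] <- log(0.0105)
    base["k1"] <- -0.15
    base["k2"] <- 5
  }
  c(base, excess)
}

#' Zero-initialised named parameter vector
#'
#' @param names parameter names.
#' @param value fill value.
#' @return named numeric vector.
#' @export
make_params <- function(names, value = 0) {
  stats::setNames(rep(value, length(names)), names)
}

#' Generate a synthetic grouped cohort
#'
#' Builds the covariate grid of `config`, allocates person-years, computes
#' each cell's true incidence rate under the true model and draws the case
#' counts as independent Poisson variables. The returned table carries the
#' ground truth needed by [perturb_cohort()] and by recovery tests:
#' attribute `expected` (per-cell expected counts) and attribute `truth`
#' (the true model and parameters).
#'
#' For true models with a stratified baseline, per-stratum true log rates
#' are derived from the same age-structured parametric law used for the
#' Grant baseline, so every registered model can act as the truth.
#'
#' @param config a [generator_config()].
#' @return a [cohort_table()] with ground-truth attributes.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  grid <- synth_grid(config)
  model <- config$true_model
  params <- config$true_params
  if (model$baseline_type == "stratified") {
    lab <- unique(strata_labels(model$baseline_form, grid))
    ref <- risk_model("GrantL", "ERR")
    base_par <- default_true_params(ref)
    base_par <- base_par[ref$baseline_params]
    idx <- match(paste0("s_", strata_labels(model$baseline_form, grid)), paste0("s_", lab))
    lam0 <- baseline_rate(ref, base_par, grid)
    strat_rates <- log(tapply(lam0, idx, mean))
    params <- c(params, stats::setNames(as.numeric(strat_rates), paste0("s_", lab)))
  }
  lambda <- cell_rate(model, params, grid)
  if (any(lambda < 0)) {
    bad <- which(lambda < 0)[1]
    stop(sprintf(paste0("true model yields a negative rate at cell %d ",
                        "(dose=%g, a=%g, e=%g, %s): invalid true parameters"),
                 bad, grid$dose[bad], grid$attained_age[bad],
                 grid$age_at_exposure[bad], grid$sex[bad]), call. = FALSE)
  }
  mu <- grid$pyr * lambda
  grid$cases <- withr::with_seed(config$seed, stats::rpois(length(mu), mu))
  tab <- cohort_table(grid, provenance = config_digest(config))
  attr(tab, "expected") <- mu
  attr(tab, "truth") <- list(model = model, params = params)
  tab
}

synth_grid <- function(config) {
  grid <- tidyr::expand_grid(
    city = c("hiroshima", "nagasaki"),
    nic = FALSE,
    sex = c("male", "female"),
    dose = config$dose_values,
    age_at_exposure = config$e_values,
    attained_age = config$a_values
  )
  grid <- dplyr::filter(grid, .data$attained_age > .data$age_at_exposure)
  # not-in-city block: zero dose, same demographic structure
  nic_grid <- dplyr::mutate(dplyr::filter(grid, .data$dose == 0), nic = TRUE)
  grid <- dplyr::bind_rows(grid, nic_grid)
  grid$kerma_gt4 <- FALSE
  f4 <- config$frac_kerma_gt4
  if (f4 > 0) {
    top <- !grid$nic & grid$dose == max(config$dose_values)
    flagged <- dplyr::mutate(grid[top, ], kerma_gt4 = TRUE)
    grid <- dplyr::bind_rows(grid, flagged)
    grid$k4_split <- ifelse(!grid$nic & grid$dose == max(config$dose_values),
                            ifelse(grid$kerma_gt4, f4, 1 - f4), 1)
  } else {
    grid$k4_split <- 1
  }
  grid$birth_year <- config$exposure_year - grid$age_at_exposure
  w <- exp(-config$pyr_decay * (grid$attained_age - grid$age_at_exposure)) *
    exp(-config$dose_decay * grid$dose) * grid$k4_split
  w_nic <- sum(w[grid$nic])
  w_city <- sum(w[!grid$nic])
  grid$pyr <- ifelse(grid$nic,
                     w / w_nic * config$total_pyr * config$frac_nic,
                     w / w_city * config$total_pyr * (1 - config$frac_nic))
  grid$k4_split <- NULL
  grid$cases <- 0
  grid
}

config_digest <- function(config) {
  flat <- c(config$seed, config$dose_values, config$e_values, config$a_values,
            config$total_pyr, config$pyr_decay, config$dose_decay,
            config$frac_nic, config$frac_kerma_gt4, config$exposure_year,
            as.numeric(config$true_params))
  sprintf("synthetic:%s:%s:%.6g", config$true_model$name,
          config$true_model$family, sum(flat * seq_along(flat)))
}

#' Redraw case counts from the stored expected counts
#'
#' Parametric bootstrap of the data layer: all case counts are redrawn as
#' independent Poisson variables with the generator's expected counts.
#'
#' @param table a cohort table produced by [generate_cohort()].
#' @param seed integer RNG seed.
#' @return a cohort table with the same grid and fresh counts.
#' @export
perturb_cohort <- function(table, seed) {
  mu <- attr(table, "expected")
  if (is.null(mu)) {
    stop("table carries no stored expected counts; generate it with ",
         "generate_cohort()", call. = FALSE)
  }
  out <- table
  out$cases <- withr::with_seed(as.integer(seed), stats::rpois(length(mu), mu))
  attr(out, "expected") <- mu
  attr(out, "truth") <- attr(table, "truth")
  out
}
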