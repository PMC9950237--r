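#' Registered excess-risk models
#'
#' The package implements the published all-solid-cancer risk models that
#' are conventionally compared in LSS-based multi-model inference: the
#' BEIR VII phase 2 linear model, the Grant, Ozasa, Preston,
#' INWORKS-Leuraud and UNSCEAR models in linear (L) and linear-quadratic
#' (LQ) dose response, and the linear-quadratic-exponential model of
#' Little and colleagues. Each model exists in an ERR (multiplicative) and
#' an EAR (additive) family; the baseline rate is either a parametric
#' log-linear form or handled by stratification, following the published
#' parametrisations.
#'
#' Sex is coded `s = -1` (male) / `+1` (female) in the `(1 + sigma*s)`
#' factor and in all sex-interaction baseline terms; city is coded by the
#' Nagasaki indicator (`naga`); `NIC` and `K > 4 Gy` enter as 0/1
#' indicators.
#'
#' @param name model identifier, one of
#'   `"BEIR"`, `"GrantL"`, `"GrantLQ"`, `"OzasaL"`, `"OzasaLQ"`,
#'   `"PrestonL"`, `"PrestonLQ"`, `"INWORKSL"`, `"INWORKSLQ"`,
#'   `"UNSCEARL"`, `"UNSCEARLQ"`, `"LittleLQE"`.
#' @param family `"ERR"` or `"EAR"`.
#' @return an object of class `risk_model`.
#' @export
risk_model <- function(name, family = c("ERR", "EAR")) {
  family <- match.arg(family)
  reg <- model_definitions()
  if (!name %in% names(reg)) {
    stop("unknown model '", name, "'; see model_registry()", call. = FALSE)
  }
  def <- reg[[name]]
  baseline_form <- if (family == "ERR") def$baseline_err else def$baseline_ear
  baseline_type <- if (baseline_form %in% c("strat500", "strat547")) "stratified" else "parametric"
  spec <- list(
    name = name,
    family = family,
    dose_response = def$dose_response,
    excess_form = def$excess_form,
    excess_params = def$excess_params,
    baseline_type = baseline_type,
    baseline_form = baseline_form,
    baseline_params = if (baseline_type == "parametric") baseline_param_names(baseline_form) else NULL,
    dose_cap = def$dose_cap,
    n_literal_excess = def$n_literal_excess,
    n_literal_baseline = def$n_literal_baseline[[if (family == "ERR") "ERR" else "EAR"]]
  )
  structure(spec, class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model %s [%s], %s dose response>\n", x$name, x$family,
              x$dose_response))
  cat("  excess form: ", x$excess_form, " (",
      paste(x$excess_params, collapse = ", "), ")\n", sep = "")
  cat("  baseline:    ", x$baseline_form,
      if (x$baseline_type == "stratified") " (stratified)" else "", "\n", sep = "")
  if (!is.null(x$dose_cap)) cat("  dose cap:    ", x$dose_cap, " Gy\n", sep = "")
  invisible(x)
}

# Model set: excess forms, dose responses, family-specific baselines and
# the literal coefficient-group counts of the published parametrisations
# (sex-specific symbols count once in the literal count; the implemented
# scalar counts are larger and are what AIC/BIC use).
model_definitions <- function() {
  grant_like <- function(dr, cap = NULL, bl_err, bl_ear, nlit_bl) {
    lq <- dr == "linear_quadratic"
    list(
      dose_response = dr,
      excess_form = "grant",
      excess_params = c("alpha", if (lq) "beta", "tau", "nu", "phi", "sigma"),
      baseline_err = bl_err, baseline_ear = bl_ear,
      dose_cap = cap,
      n_literal_excess = if (lq) 6L else 5L,
      n_literal_baseline = nlit_bl
    )
  }
  inworks <- function(dr) {
    lq <- dr == "linear_quadratic"
    list(
      dose_response = dr,
      excess_form = "inworks",
      excess_params = c("alpha", if (lq) "beta", "tau", "nu1", "nu2", "nu3", "sigma"),
      baseline_err = "strat547", baseline_ear = "ozasa_ar",
      dose_cap = NULL,
      n_literal_excess = if (lq) 7L else 6L,
      n_literal_baseline = list(ERR = 547L, EAR = 10L)
    )
  }
  unscear <- function(dr, form = "unscear") {
    lq <- dr %in% c("linear_quadratic", "linear_quadratic_exponential")
    list(
      dose_response = dr,
      excess_form = if (form == "little") "little" else "unscear",
      excess_params = c("alpha", if (lq) "beta",
                        if (form == "little") "delta",
                        "sigma", "epsilon", "nu"),
      baseline_err = "unscear", baseline_ear = "unscear",
      dose_cap = NULL,
      n_literal_excess = if (form == "little") 6L else if (lq) 5L else 4L,
      n_literal_baseline = list(ERR = 22L, EAR = 22L)
    )
  }
  list(
    BEIR = list(
      dose_response = "linear",
      excess_form = "beir",
      excess_params = c("alpha_m", "alpha_f", "tau", "nu"),
      baseline_err = "strat500", baseline_ear = "beir_ar",
      dose_cap = NULL,
      n_literal_excess = 3L,
      n_literal_baseline = list(ERR = 500L, EAR = 9L)
    ),
    GrantL = grant_like("linear", NULL, "grant", "grant", list(ERR = 6L, EAR = 6L)),
    GrantLQ = grant_like("linear_quadratic", NULL, "grant", "grant", list(ERR = 6L, EAR = 6L)),
    OzasaL = grant_like("linear", NULL, "strat500", "ozasa_ar", list(ERR = 500L, EAR = 10L)),
    OzasaLQ = grant_like("linear_quadratic", NULL, "strat500", "ozasa_ar", list(ERR = 500L, EAR = 10L)),
    PrestonL = grant_like("linear", 4, "preston", "preston", list(ERR = 8L, EAR = 8L)),
    PrestonLQ = grant_like("linear_quadratic", 4, "preston", "preston", list(ERR = 8L, EAR = 8L)),
    INWORKSL = inworks("linear"),
    INWORKSLQ = inworks("linear_quadratic"),
    UNSCEARL = unscear("linear"),
    UNSCEARLQ = unscear("linear_quadratic"),
    LittleLQE = unscear("linear_quadratic_exponential", form = "little")
  )
}

#' List every registered model
#'
#' @param family `"ERR"`, `"EAR"` or `"both"`.
#' @return a tibble with one row per model and family, its dose response,
#'   baseline description, parameter counts (implemented scalars and the
#'   literal published symbol-group counts) and the `risk_model` object in
#'   a list column.
#' @export
model_registry <- function(family = c("both", "ERR", "EAR")) {
  family <- match.arg(family)
  fams <- if (family == "both") c("ERR", "EAR") else family
  rows <- purrr::map_dfr(fams, function(f) {
    purrr::map_dfr(names(model_definitions()), function(nm) {
      m <- risk_model(nm, f)
      tibble::tibble(
        model = nm, family = f, dose_response = m$dose_response,
        baseline = m$baseline_form, baseline_type = m$baseline_type,
        n_excess = length(m$excess_params),
        n_baseline = if (m$baseline_type == "parametric") length(m$baseline_params) else NA_integer_,
        n_literal_excess = m$n_literal_excess,
        n_literal_baseline = m$n_literal_baseline,
        spec = list(m)
      )
    })
  })
  rows
}

# ---- excess-risk forms -----------------------------------------------------

#' Evaluate a model's excess risk
#'
#' Vectorized evaluation of the excess risk (ERR dimensionless, EAR per
#' person-year) at query points. A zero dose gives exactly zero excess for
#' every registered form.
#'
#' @param model a [risk_model()].
#' @param params named numeric vector covering `model$excess_params`
#'   (extra names are ignored, so a full fitted vector can be passed).
#' @param data data frame with columns `dose`, `attained_age`,
#'   `age_at_exposure`, `sex`, and optionally `kerma_gt4` (default `FALSE`).
#' @return numeric vector, one value per row of `data`.
#' @export
excess_risk <- function(model, params, data) {
  stopifnot(inherits(model, "risk_model"))
  p <- resolve_params(params, model$excess_params)
  d <- data$dose
  a <- data$attained_age
  e <- data$age_at_exposure
  if (any(d < 0)) stop("dose must be non-negative", call. = FALSE)
  if (any(a < e)) stop("attained_age must be >= age_at_exposure", call. = FALSE)
  s <- sex_code(data$sex)
  k4 <- if ("kerma_gt4" %in% names(data)) as.numeric(data$kerma_gt4) else rep(0, length(d))
  beta <- if ("beta" %in% names(p)) p[["beta"]] else 0
  switch(model$excess_form,
    grant = (p[["alpha"]] * d + beta * d^2) *
      exp(p[["tau"]] * (e - 30) / 10 + p[["nu"]] * log(a / 70) + p[["phi"]] * k4) *
      (1 + p[["sigma"]] * s),
    beir = {
      estar <- ifelse(e < 30, (e - 30) / 10, 0)
      alpha_s <- ifelse(s < 0, p[["alpha_m"]], p[["alpha_f"]])
      alpha_s * d * exp(p[["tau"]] * estar) * (a / 70)^p[["nu"]]
    },
    inworks = {
      # attained-age bands closed below: nu1 for a <= 60, nu2 for 60 < a <= 80
      nu <- ifelse(a <= 60, p[["nu1"]], ifelse(a <= 80, p[["nu2"]], p[["nu3"]]))
      (p[["alpha"]] * d + beta * d^2) *
        exp(p[["tau"]] * (e - 30) / 10 + nu * (a - 70) / 10) *
        (1 + p[["sigma"]] * s)
    },
    unscear = {
      check_time_since_exposure(a, e)
      (p[["alpha"]] * d + beta * d^2) *
        exp(p[["sigma"]] * s + p[["epsilon"]] * log((a - e) / 40) +
              p[["nu"]] * log(a / 70))
    },
    little = {
      check_time_since_exposure(a, e)
      (p[["alpha"]] * d + beta * d^2) * exp(p[["delta"]] * d) *
        exp(p[["sigma"]] * s + p[["epsilon"]] * log((a - e) / 40) +
              p[["nu"]] * log(a / 70))
    },
    stop("unknown excess form ", model$excess_form, call. = FALSE)
  )
}

check_time_since_exposure <- function(a, e) {
  if (any(a <= e)) {
    stop("attained_age must exceed age_at_exposure for models with a ",
         "time-since-exposure term", call. = FALSE)
  }
}

sex_code <- function(sex) {
  if (is.numeric(sex)) return(sex)
  out <- ifelse(tolower(sex) == "male", -1, ifelse(tolower(sex) == "female", 1, NA))
  if (anyNA(out)) stop("sex must be 'male' or 'female'", call. = FALSE)
  out
}

resolve_params <- function(params, needed) {
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    stop("unresolved parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- params[needed]
  if (any(!is.finite(p))) stop("non-finite parameter value", call. = FALSE)
  p
}

# ---- baseline forms --------------------------------------------------------

baseline_param_names <- function(form) {
  sexed <- function(base) as.vector(t(outer(base, c("m", "f"), paste, sep = "_")))
  switch(form,
    grant = c(sexed(paste0("k", 1:4)), "k5", "cnic_h", "cnic_n"),
    preston = c(sexed(paste0("k", 1:7)), "cnic_h", "cnic_n"),
    beir_ar = c("k1_m_h", "k1_m_n", "k1_f_h", "k1_f_n", sexed(paste0("k", 2:8)), "k9"),
    ozasa_ar = c("k1_m_h", "k1_m_n", "k1_f_h", "k1_f_n", sexed(paste0("k", 2:9)), "k10"),
    unscear = paste0("k", 0:22),
    stop("unknown baseline form ", form, call. = FALSE)
  )
}

# Design matrix of a parametric (log-linear) baseline: rate = exp(X %*% k).
# Threshold subscripts are closed as printed: e>50 and e>30 strict, a>70
# strict in the Grant spline knot, a>=40 and a>=70 inclusive in the
# BEIR/Ozasa absolute-rate forms.
baseline_design <- function(form, data) {
  a <- data$attained_age
  e <- data$age_at_exposure
  s <- sex_code(data$sex)
  m <- as.numeric(s < 0)
  f <- as.numeric(s > 0)
  naga <- as.numeric(tolower(data$city) == "nagasaki")
  hiro <- 1 - naga
  nic <- as.numeric(data$nic)
  La <- log(a / 70)
  E <- (e - 30) / 10
  sex_block <- function(cols) {
    out <- do.call(cbind, lapply(cols, function(x) cbind(x * m, x * f)))
    out
  }
  X <- switch(form,
    grant = cbind(
      sex_block(list(1, La, La^2, La^2 * (a > 70))),
      (data$birth_year - 1915) / 10, nic * hiro, nic * naga),
    preston = cbind(
      sex_block(list(1, naga, La, La^2, La^2 * (a > 70), E, E^2)),
      nic * hiro, nic * naga),
    beir_ar = cbind(
      m * hiro, m * naga, f * hiro, f * naga,
      sex_block(list(E, E^2, ((e - 50) / 10)^2 * (e > 50),
                     La, La^2, log(a / 40)^2 * (a >= 40), La^2 * (a >= 70))),
      E * La),
    ozasa_ar = cbind(
      m * hiro, m * naga, f * hiro, f * naga,
      sex_block(list(E, E^2, E^2 * (e > 30), ((e - 50) / 10)^2 * (e > 50),
                     La, La^2, log(a / 40)^2 * (a >= 40), La^2 * (a >= 70))),
      E * La),
    unscear = {
      check_time_since_exposure(a, e)
      Lt <- log((a - e) / 40)
      cbind(1, s, La, La^2, La^3, La^4, Lt, Lt^2, E, E^2,
            s * La, s * La^2, s * La^3, s * Lt, s * Lt^2,
            Lt * La, Lt * La^2, Lt * La^3, Lt^2 * La, Lt^2 * La^2,
            E * La, E * La^2, E * La^3)
    },
    stop("unknown baseline form ", form, call. = FALSE)
  )
  colnames(X) <- baseline_param_names(form)
  X
}

# Stratum labels of a stratified baseline scheme.
strata_labels <- function(form, data) {
  switch(form,
    strat500 = paste(data$sex, data$city, data$age_at_exposure,
                     data$attained_age, sep = ":"),
    strat547 = paste(data$sex, data$city, data$birth_year,
                     data$attained_age, sep = ":"),
    stop("baseline form ", form, " is not stratified", call. = FALSE)
  )
}

#' Evaluate a model's baseline rate
#'
#' Parametric baselines evaluate the published log-linear expression;
#' stratified baselines look up the per-stratum log rate (parameter
#' `s_<sex:city:...>`) for each cell's stratum.
#'
#' @param model a [risk_model()].
#' @param params named numeric vector; for stratified baselines the
#'   per-stratum log rates named `s_<stratum>`.
#' @param data cohort cells (data frame with the covariate columns).
#' @return baseline rate per person-year, one value per row.
#' @export
baseline_rate <- function(model, params, data) {
  stopifnot(inherits(model, "risk_model"))
  if (model$baseline_type == "parametric") {
    X <- baseline_design(model$baseline_form, data)
    k <- resolve_params(params, colnames(X))
    as.vector(exp(X %*% k))
  } else {
    lab <- paste0("s_", strata_labels(model$baseline_form, data))
    missing <- setdiff(unique(lab), names(params))
    if (length(missing) > 0) {
      stop("cell outside known strata: ", paste(utils::head(missing, 3), collapse = "; "),
           call. = FALSE)
    }
    exp(unname(params[lab]))
  }
}

#' Cell-level incidence rate under a model
#'
#' Composes baseline and excess per the family: additive
#' `lambda0 + EAR` for EAR models, multiplicative `lambda0 * (1 + ERR)`
#' for ERR models. Non-positive composed rates are possible for infeasible
#' parameter values and are returned as-is; the fitting layer treats them
#' as an infeasible-parameter condition.
#'
#' @inheritParams baseline_rate
#' @return incidence rate per person-year, one value per row.
#' @export
cell_rate <- function(model, params, data) {
  lam0 <- baseline_rate(model, params, data)
  xs <- excess_risk(model, params, data)
  if (model$family == "ERR") lam0 * (1 + xs) else lam0 + xs
}

#' Build a query grid for risk evaluation
#'
#' @param dose Gy (vector allowed).
#' @param attained_age,age_at_exposure years.
#' @param sex `"male"`/`"female"` (vector allowed).
#' @param kerma_gt4 logical.
#' @return tibble of the crossed query points.
#' @export
risk_query <- function(dose = 1, attained_age = 70, age_at_exposure = 30,
                       sex = c("female", "male"), kerma_gt4 = FALSE) {
  q <- tidyr::expand_grid(dose = dose, attained_age = attained_age,
                          age_at_exposure = age_at_exposure, sex = sex,
                          kerma_gt4 = kerma_gt4)
  if (any(q$attained_age < q$age_at_exposure)) {
    stop("attained_age must be >= age_at_exposure", call. = FALSE)
  }
  q
}
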