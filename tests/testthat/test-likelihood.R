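# Independent per-cell oracle: Grant-form ERR rate written out by hand,
# plus dpois for the Poisson terms.
oracle_nll_grantl_err <- function(params, tab) {
  k <- params
  L <- log(tab$attained_age / 70)
  s <- ifelse(tab$sex == "male", -1, 1)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    ks <- if (s[i] < 0) c(k[["k1_m"]], k[["k2_m"]], k[["k3_m"]], k[["k4_m"]])
          else c(k[["k1_f"]], k[["k2_f"]], k[["k3_f"]], k[["k4_f"]])
    cnic <- if (tab$city[i] == "hiroshima") k[["cnic_h"]] else k[["cnic_n"]]
    lam0 <- exp(ks[1] + ks[2] * L[i] + ks[3] * L[i]^2 +
                  ks[4] * L[i]^2 * (tab$attained_age[i] > 70) +
                  k[["k5"]] * (tab$birth_year[i] - 1915) / 10 +
                  cnic * tab$nic[i])
    err <- k[["alpha"]] * tab$dose[i] *
      exp(k[["tau"]] * (tab$age_at_exposure[i] - 30) / 10 +
            k[["nu"]] * L[i] + k[["phi"]] * tab$kerma_gt4[i]) *
      (1 + k[["sigma"]] * s[i])
    mu <- tab$pyr[i] * lam0 * (1 + err)
    total <- total - stats::dpois(tab$cases[i], mu, log = TRUE)
  }
  total
}

random_table <- function(seed, n = 12) {
  withr::with_seed(seed, cohort_table(tibble::tibble(
    city = sample(c("hiroshima", "nagasaki"), n, replace = TRUE),
    nic = sample(c(TRUE, FALSE), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_at_exposure = round(stats::runif(n, 5, 40), 4),
    attained_age = round(stats::runif(n, 45, 90), 3),
    birth_year = round(stats::runif(n, 1900, 1940)),
    dose = round(stats::runif(n, 0, 4), 3),
    kerma_gt4 = sample(c(TRUE, FALSE), n, replace = TRUE),
    pyr = round(stats::runif(n, 100, 5000), 2),
    cases = stats::rpois(n, 3)
  )))
}

test_that("the Poisson term matches hand evaluation", {
  # one cell: mu = 2, y = 3 -> 2 - 3 ln 2 + ln 6
  tab <- toy_cohort()[1, ]
  tab$pyr <- 1000; tab$cases <- 3; tab$dose <- 0
  m <- risk_model("GrantL", "ERR")
  p <- c(make_params(m$baseline_params), make_params(m$excess_params))
  # set baseline so lambda = 0.002 at this cell (a=50, byr=1935, male)
  L <- log(50 / 70)
  p["k1_m"] <- log(0.002) - p["k5"] * 2
  p["k5"] <- 0
  p["k2_m"] <- 0
  expect_equal(neg_log_likelihood(m, p, tab), 2 - 3 * log(2) + log(6),
               tolerance = 1e-12)
  # y = 0 contributes exactly mu
  tab$cases <- 0
  expect_equal(neg_log_likelihood(m, p, tab), 2, tolerance = 1e-12)
  # infeasible parameters give +Inf with a flag
  tab$dose <- 1; tab$cases <- 1
  p["alpha"] <- -3
  v <- neg_log_likelihood(m, p, tab)
  expect_equal(unclass(v), Inf, ignore_attr = TRUE)
  expect_true(attr(v, "infeasible"))
})

test_that("likelihood matches a brute-force per-cell oracle on random tables", {
  m <- risk_model("GrantL", "ERR")
  for (seed in 1:50) {
    tab <- random_table(seed)
    p <- withr::with_seed(1000 + seed, c(
      make_params(m$baseline_params, stats::rnorm(11, 0, 0.3)),
      make_params(m$excess_params, stats::runif(5, 0, 0.3))))
    p["k1_m"] <- p["k1_m"] - 5
    p["k1_f"] <- p["k1_f"] - 5
    expect_equal(neg_log_likelihood(m, p, tab), oracle_nll_grantl_err(p, tab),
                 tolerance = 1e-10, info = seed)
  }
})

test_that("constant-rate fit recovers the closed-form MLE total cases / total PY", {
  # two cells identical except city; dose 0 everywhere so only the male
  # intercept is live: exp(k1_m) must converge to 8/4000
  tab <- cohort_table(tibble::tibble(
    city = c("hiroshima", "nagasaki"), nic = FALSE, sex = "male",
    age_at_exposure = 30, attained_age = 70, birth_year = 1915,
    dose = 0, kerma_gt4 = FALSE, pyr = c(1000, 3000), cases = c(2, 6)))
  fit <- fit_risk_model(risk_model("GrantL", "ERR"), tab, n_starts = 1)
  expect_equal(exp(fit$mle[["k1_m"]]), 8 / 4000, tolerance = 1e-8)
})

test_that("baseline-only fits agree with the Poisson GLM cross-check", {
  tab <- small_cohort(seed = 61)
  f <- radmmi:::fit_baseline_only("grant", tab)
  X <- radmmi:::baseline_design("grant", tab[tab$pyr > 0, ])
  g <- stats::glm.fit(X, tab$cases[tab$pyr > 0],
                      offset = log(tab$pyr[tab$pyr > 0]),
                      family = stats::poisson())
  expect_equal(unname(f$mle), unname(g$coefficients), tolerance = 1e-5)
  # glm fitted values are the expected counts (offset included)
  expect_equal(f$loglik,
               sum(stats::dpois(tab$cases[tab$pyr > 0], g$fitted.values,
                                log = TRUE)),
               tolerance = 1e-8)
})

test_that("profiled stratified baseline matches a brute-force grid search", {
  # 2 strata x 2 dose cells each
  tab <- cohort_table(tibble::tibble(
    city = "hiroshima", nic = FALSE, sex = rep(c("male", "female"), each = 2),
    age_at_exposure = 20, attained_age = 60, birth_year = 1925,
    dose = rep(c(0, 2), 2), kerma_gt4 = FALSE,
    pyr = c(4000, 1000, 5000, 1500), cases = c(8, 4, 9, 5)))
  m <- risk_model("OzasaL", "ERR")
  excess <- c(alpha = 0.4, tau = 0, nu = 0, phi = 0, sigma = 0)
  prof <- profile_stratified_baseline(m, excess, tab)
  # independent oracle: per-stratum 1-D golden-section over the rate
  nll_at <- function(l0, idx) {
    err <- 0.4 * tab$dose[idx]
    mu <- tab$pyr[idx] * l0 * (1 + err)
    -sum(stats::dpois(tab$cases[idx], mu, log = TRUE))
  }
  for (st in list(1:2, 3:4)) {
    opt <- stats::optimize(nll_at, c(1e-6, 1e-2), idx = st, tol = 1e-12)
    lab <- paste0("s_", radmmi:::strata_labels("strat500", tab[st[1], ]))
    expect_equal(exp(prof[[lab]]), opt$minimum, tolerance = 1e-6)
  }
  # zero excess reduces to the crude stratum rate
  prof0 <- profile_stratified_baseline(m, make_params(m$excess_params), tab)
  expect_equal(exp(unname(prof0[1])), 12 / 5000, tolerance = 1e-12)
  # zero-case stratum sits at the boundary
  tab0 <- tab
  tab0$cases <- c(0, 0, 9, 5)
  p0 <- profile_stratified_baseline(m, excess, tab0)
  expect_equal(exp(p0[[1]]), 0)
  # EAR structure: root-finding matches the additive score equation
  mA <- risk_model("GrantL", "EAR")
  mA$baseline_type <- "stratified"; mA$baseline_form <- "strat500"
  excessA <- c(alpha = 5e-4, tau = 0, nu = 0, phi = 0, sigma = 0)
  profA <- radmmi:::profile_strata_rates(
    "EAR", tab$cases, tab$pyr, 5e-4 * tab$dose,
    radmmi:::strata_labels("strat500", tab))
  nllA_at <- function(l0, idx) {
    mu <- tab$pyr[idx] * (l0 + 5e-4 * tab$dose[idx])
    -sum(stats::dpois(tab$cases[idx], mu, log = TRUE))
  }
  optA <- stats::optimize(nllA_at, c(1e-6, 1e-2), idx = 1:2, tol = 1e-12)
  expect_equal(unname(profA[1]), optA$minimum, tolerance = 1e-6)
})

test_that("fit statistics are internally consistent", {
  tab <- small_cohort(seed = 71)
  fit <- fit_risk_model(risk_model("GrantL", "ERR"), tab, n_starts = 1)
  expect_true(fit$converged)
  expect_gte(fit$deviance, 0)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_equal(fit$bic, fit$n_params * log(fit$n_cells) - 2 * fit$loglik)
  # AIC differences are invariant to the ln y! constant
  const <- sum(lfactorial(tab$cases[tab$pyr > 0]))
  fit2 <- fit_risk_model(risk_model("GrantLQ", "ERR"), tab, n_starts = 1)
  d_with <- fit2$aic - fit$aic
  d_without <- (fit2$aic + 2 * const) - (fit$aic + 2 * const)
  expect_equal(d_with, d_without, tolerance = 1e-9)
  # nested L/LQ: the larger model fits at least as well
  expect_gte(fit2$loglik, fit$loglik - 1e-6)
  # covariance block is symmetric with positive variances
  V <- excess_vcov(fit)
  expect_equal(V, t(V))
  expect_true(all(diag(V) > 0))
  # stratified fits count each stratum as a parameter
  fs <- fit_risk_model(risk_model("OzasaL", "ERR"), tab, n_starts = 1)
  expect_equal(fs$n_params,
               length(fs$model$excess_params) + length(fs$strata_rates))
})

test_that("fixed parameters are honoured and excluded from the free block", {
  tab <- small_cohort(seed = 65)
  m <- risk_model("GrantL", "ERR")
  fit <- fit_risk_model(m, tab, fixed = c(tau = 0, phi = -0.5), n_starts = 1)
  expect_equal(fit$mle[["tau"]], 0)
  expect_equal(fit$mle[["phi"]], -0.5)
  expect_false(any(c("tau", "phi") %in% colnames(fit$vcov)))
  expect_equal(fit$n_params, 16 - 2)
  # fixing at the unconstrained MLE cannot improve the likelihood
  full <- fit_risk_model(m, tab, n_starts = 1)
  expect_lte(fit$loglik, full$loglik + 1e-6)
  expect_error(fit_risk_model(m, tab, fixed = c(zeta = 1)), "not in the model")
})

test_that("the plausibility rule is scoped to the LQE model's sign pattern", {
  fake_fit <- function(name, beta, delta) {
    structure(list(model = risk_model(name, "ERR"),
                   mle = c(alpha = 0.3, beta = beta, delta = delta,
                           sigma = 0, epsilon = 0, nu = 0),
                   converged = TRUE), class = "risk_fit")
  }
  expect_false(plausibility_check(fake_fit("LittleLQE", -0.1, 0.2))$plausible)
  expect_true(plausibility_check(fake_fit("LittleLQE", 0.1, -0.2))$plausible)
  g <- structure(list(model = risk_model("GrantLQ", "ERR"),
                      mle = c(alpha = 0.3, beta = -0.5, tau = 0, nu = 0,
                              phi = 0, sigma = 0), converged = TRUE),
                 class = "risk_fit")
  expect_true(plausibility_check(g)$plausible)
})

test_that("baseline selection ranks candidates by AIC and favours the truth", {
  # data simulated from the Grant baseline (a strict sub-model of Preston
  # in the covariates it uses): the generating form should win at this n
  tab <- small_cohort(seed = 81)
  sel <- select_best_baseline(tab, candidates = c("grant", "unscear"))
  expect_equal(sel$best, "grant")
  expect_equal(nrow(sel$table), 2)
  expect_true(all(c("baseline", "AIC", "converged") %in% names(sel$table)))
  # single candidate returned trivially
  expect_equal(select_best_baseline(tab, candidates = "grant")$best, "grant")
})
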