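test_that("registry exposes the published model set with correct counts", {
  reg <- model_registry()
  expect_equal(sort(unique(reg$model)),
               sort(c("BEIR", "GrantL", "GrantLQ", "OzasaL", "OzasaLQ",
                      "PrestonL", "PrestonLQ", "INWORKSL", "INWORKSLQ",
                      "UNSCEARL", "UNSCEARLQ", "LittleLQE")))
  grant <- risk_model("GrantLQ", "ERR")
  expect_equal(grant$n_literal_excess, 6L)           # alpha beta tau nu phi sigma
  expect_equal(risk_model("GrantL", "ERR")$n_literal_excess, 5L)  # L drops beta
  expect_equal(risk_model("INWORKSLQ", "ERR")$n_literal_excess, 7L)
  expect_equal(risk_model("INWORKSLQ", "ERR")$n_literal_baseline, 547L)
  expect_equal(risk_model("BEIR", "ERR")$n_literal_baseline, 500L)
  # BEIR has no LQ variant: its published form is linear only
  expect_equal(risk_model("BEIR", "ERR")$dose_response, "linear")
  expect_false(any(grepl("beta", risk_model("BEIR", "ERR")$excess_params)))
  # linear variants carry one fewer excess coefficient than their LQ form
  for (pair in list(c("GrantL", "GrantLQ"), c("OzasaL", "OzasaLQ"),
                    c("PrestonL", "PrestonLQ"), c("INWORKSL", "INWORKSLQ"),
                    c("UNSCEARL", "UNSCEARLQ"))) {
    expect_equal(length(risk_model(pair[1], "ERR")$excess_params) + 1L,
                 length(risk_model(pair[2], "ERR")$excess_params))
  }
  # Preston models declare the 4 Gy dose cap
  expect_equal(risk_model("PrestonL", "EAR")$dose_cap, 4)
  expect_null(risk_model("GrantL", "EAR")$dose_cap)
})

test_that("excess risk matches hand evaluation at reference points", {
  # Grant LQ with all modifiers centred: (0.4 + 0.1) * (1 + 0.3)
  g <- risk_model("GrantLQ", "ERR")
  p <- c(alpha = 0.4, beta = 0.1, tau = 0, nu = 0, phi = 0, sigma = 0.3)
  expect_equal(excess_risk(g, p, risk_query(dose = 1, sex = "female")), 0.65)
  expect_equal(excess_risk(g, p, risk_query(dose = 1, sex = "male")),
               0.5 * 0.7)
  # BEIR e* threshold: e >= 30 makes the exposure-age modifier vanish
  b <- risk_model("BEIR", "ERR")
  pb <- c(alpha_m = 0.3, alpha_f = 0.9, tau = 0.5, nu = -1)
  expect_equal(excess_risk(b, pb, risk_query(dose = 1, attained_age = 35,
                                             age_at_exposure = 31,
                                             sex = "male")),
               0.3 * (35 / 70)^(-1))
  # e < 30 branch: e* = (20-30)/10 = -1
  expect_equal(excess_risk(b, pb, risk_query(dose = 1, attained_age = 70,
                                             age_at_exposure = 20,
                                             sex = "female")),
               0.9 * exp(-0.5))
  # every form vanishes exactly at zero dose
  for (nm in unique(model_registry()$model)) {
    m <- risk_model(nm, "ERR")
    pp <- make_params(m$excess_params, 0.3)
    expect_equal(excess_risk(m, pp, risk_query(dose = 0, attained_age = 50)),
                 c(0, 0), info = nm)
  }
})

test_that("attained-age bands make the INWORKS form discontinuous in age only", {
  m <- risk_model("INWORKSLQ", "ERR")
  p <- c(alpha = 0.4, beta = 0, tau = 0, nu1 = -0.5, nu2 = -1.5, nu3 = -2,
         sigma = 0)
  lo <- excess_risk(m, p, risk_query(dose = 1, attained_age = 59.999, sex = "female"))
  hi <- excess_risk(m, p, risk_query(dose = 1, attained_age = 60.001, sex = "female"))
  expect_gt(abs(hi - lo), 0.05)  # jump at the band boundary
  # but continuous in dose on a fine grid
  d <- seq(0, 4, by = 0.01)
  v <- excess_risk(m, p, risk_query(dose = d, sex = "female"))
  expect_lt(max(abs(diff(v))), 0.02)
})

test_that("setting beta to zero collapses LQ forms onto their L forms", {
  q <- withr::with_seed(7, tibble::tibble(
    dose = stats::runif(1000, 0, 4),
    attained_age = stats::runif(1000, 45, 90),
    age_at_exposure = stats::runif(1000, 5, 40),
    sex = sample(c("male", "female"), 1000, replace = TRUE),
    kerma_gt4 = sample(c(TRUE, FALSE), 1000, replace = TRUE)
  ))
  for (pair in list(c("GrantL", "GrantLQ"), c("INWORKSL", "INWORKSLQ"),
                    c("UNSCEARL", "UNSCEARLQ"))) {
    mL <- risk_model(pair[1], "ERR")
    mLQ <- risk_model(pair[2], "ERR")
    p <- make_params(mLQ$excess_params, 0.4)
    p["beta"] <- 0
    expect_equal(excess_risk(mLQ, p, q), excess_risk(mL, p, q), info = pair[2])
  }
})

test_that("the sex factor is symmetric under the +/-1 coding", {
  g <- risk_model("GrantL", "ERR")
  p <- c(alpha = 0.5, tau = 0, nu = 0, phi = 0, sigma = 0.3)
  f <- excess_risk(g, p, risk_query(dose = 1, sex = "female"))
  m <- excess_risk(g, p, risk_query(dose = 1, sex = "male"))
  expect_equal(f, 0.5 * 1.3)
  expect_equal(m, 0.5 * 0.7)
  expect_equal(f * m, 0.5^2 * (1 - 0.3^2))  # (1+sigma)(1-sigma) structure
})

test_that("every excess and baseline coefficient is reachable", {
  # covariate cells spanning both sexes, cities, NIC states and the
  # threshold knots (e > 30, e > 50, a >= 40, a > 70)
  cells <- tidyr::expand_grid(
    city = c("hiroshima", "nagasaki"), sex = c("male", "female"),
    nic = c(FALSE, TRUE), age_at_exposure = c(10, 55),
    attained_age = c(45, 75)) |>
    dplyr::filter(.data$attained_age > .data$age_at_exposure) |>
    dplyr::mutate(birth_year = 1945 - .data$age_at_exposure, dose = 1,
                  kerma_gt4 = FALSE)
  qq <- dplyr::bind_rows(
    risk_query(dose = 2, attained_age = 85, age_at_exposure = 20,
               sex = c("male", "female"), kerma_gt4 = c(FALSE, TRUE)),
    risk_query(dose = 2, attained_age = 75, age_at_exposure = 20),
    risk_query(dose = 2, attained_age = 55, age_at_exposure = 35))
  for (nm in unique(model_registry()$model)) {
    for (fam in c("ERR", "EAR")) {
      m <- risk_model(nm, fam)
      base <- make_params(m$excess_params, 0.11)
      v0 <- excess_risk(m, base, qq)
      for (par in m$excess_params) {
        pp <- base
        pp[par] <- pp[par] + 0.37
        expect_false(isTRUE(all.equal(excess_risk(m, pp, qq), v0)),
                     info = paste(nm, fam, par))
      }
      if (m$baseline_type == "parametric") {
        kb <- make_params(m$baseline_params, 0.05)
        b0 <- baseline_rate(m, kb, cells)
        for (par in m$baseline_params) {
          pp <- kb
          pp[par] <- pp[par] + 0.31
          expect_false(isTRUE(all.equal(baseline_rate(m, pp, cells), b0)),
                       info = paste(nm, fam, par))
        }
      }
    }
  }
})

test_that("baseline rates evaluate the printed expressions", {
  g <- risk_model("GrantL", "ERR")
  k0 <- make_params(g$baseline_params)
  cell <- toy_cohort()[1, ]
  cell$nic <- FALSE
  expect_equal(baseline_rate(g, k0, cell), 1)  # all k = 0 -> exp(0)
  # at a = 70, byr = 1915 only the sex intercept survives
  cell$attained_age <- 70
  cell$birth_year <- 1915
  k <- k0
  k["k1_m"] <- -5; k["k2_m"] <- 3; k["k3_m"] <- 2; k["k4_m"] <- 1; k["k5"] <- 9
  expect_equal(baseline_rate(g, k, cell), exp(-5))
  # stratified: the stratum log-rate is returned regardless of covariates
  s <- risk_model("OzasaL", "ERR")
  lab <- radmmi:::strata_labels("strat500", cell)
  expect_equal(baseline_rate(s, stats::setNames(-6, paste0("s_", lab)), cell),
               exp(-6))
  expect_error(baseline_rate(s, c(s_other = -6), cell), "outside known strata")
})

test_that("cell rates compose additively for EAR and multiplicatively for ERR", {
  cell <- toy_cohort()[2, ]  # female, dose 1, a 70, e 30, byr 1915
  gE <- risk_model("GrantL", "ERR")
  pE <- c(make_params(gE$baseline_params), alpha = 0.5, tau = 0, nu = 0,
          phi = 0, sigma = 0.3)
  pE["k1_f"] <- log(0.001)
  expect_equal(cell_rate(gE, pE, cell), 0.001 * (1 + 0.65))
  gA <- risk_model("GrantL", "EAR")
  pA <- pE
  pA["alpha"] <- 0.005
  expect_equal(cell_rate(gA, pA, cell), 0.001 + 0.0065)
  # zero dose reduces both to the baseline
  cell0 <- cell; cell0$dose <- 0
  expect_equal(cell_rate(gE, pE, cell0), 0.001)
  expect_equal(cell_rate(gA, pA, cell0), 0.001)
})

test_that("time-since-exposure forms reject a = e and unresolved parameters error", {
  u <- risk_model("UNSCEARL", "ERR")
  p <- make_params(u$excess_params, 0.2)
  q <- tibble::tibble(dose = 1, attained_age = 30, age_at_exposure = 30,
                      sex = "female")
  expect_error(excess_risk(u, p, q), "time-since-exposure")
  expect_error(excess_risk(u, p[-1], risk_query(dose = 1)), "unresolved")
})
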