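# Shared fixtures: all data built in code, deterministic seeds.

# Minimal hand-written 3-cell table.
toy_cohort <- function() {
  cohort_table(tibble::tibble(
    city = c("hiroshima", "hiroshima", "nagasaki"),
    nic = c(FALSE, FALSE, TRUE),
    sex = c("male", "female", "female"),
    age_at_exposure = c(10, 30, 20),
    attained_age = c(50, 70, 60),
    birth_year = c(1935, 1915, 1925),
    dose = c(0.5, 1.0, 0),
    kerma_gt4 = c(FALSE, FALSE, FALSE),
    pyr = c(1000, 2000, 1500),
    cases = c(1, 2, 3)
  ))
}

# Compact LSS-like generator configuration used across fitting tests:
# 2 cities x 2 sexes x 5 dose categories x 3 exposure-age x 6 attained-age
# cells (~450 with the NIC and kerma blocks), 1e7 person-years.
small_config <- function(seed = 1, ...) {
  generator_config(
    seed = seed,
    dose_values = c(0, 0.25, 0.75, 1.5, 3),
    e_values = c(10, 25, 40),
    a_values = seq(30, 80, by = 10),
    total_pyr = 1e7,
    frac_nic = 0.1,
    frac_kerma_gt4 = 0.02,
    ...
  )
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(small_config(seed = seed, ...))
}

# Grid with exposure ages spanning the e > 30 and e > 50 baseline knots,
# so the absolute-rate baselines are identified; used by study-level tests.
wide_config <- function(seed = 1, ...) {
  generator_config(
    seed = seed,
    dose_values = c(0, 0.25, 0.75, 1.5, 3),
    e_values = c(15, 35, 55),
    a_values = seq(45, 85, by = 10),
    total_pyr = 1e7,
    frac_nic = 0.1,
    frac_kerma_gt4 = 0.02,
    ...
  )
}

expect_cohort <- function(x) {
  expect_s3_class(x, "cohort_tbl")
  expect_true(all(radmmi:::cohort_columns() %in% names(x)))
}
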