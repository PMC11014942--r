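test_that("Delta-17O anomaly is zero on the mass-dependent line and linear off it", {
  # on-line points carry no anomaly, whatever their d18O
  for (x in c(-30, 0, 4.6, 92)) {
    expect_equal(delta17O_anomaly(0.52 * x, x), 0)
  }
  expect_equal(delta17O_anomaly(10, 0), 10)
  expect_equal(delta17O_anomaly(18, 20), 7.6)   # 18 - 0.52 * 20
  expect_error(delta17O_anomaly(NaN, 1),
               class = "nitrosource_error_invalid_measurement")
  expect_error(delta17O_anomaly(1, 1, lambda_mdf = 1.2),
               class = "nitrosource_error_config")
})

test_that("biological endmember d18O is the 1:2 O2:water mix", {
  expect_equal(biological_endmember_d18O(-12.7, 23.9), (2 * -12.7 + 23.9) / 3)
  expect_equal(biological_endmember_d18O(-12.7, 23.9), -0.5)
  expect_equal(biological_endmember_d18O(0, 0), 0)
  # identical pools give the pool value for any weight
  for (w in c(0, 0.25, 2 / 3, 1)) {
    expect_equal(biological_endmember_d18O(7.7, 7.7, w), 7.7)
  }
  expect_error(biological_endmember_d18O(0, 0, w_water = 1.5),
               class = "nitrosource_error_config")
})

test_that("two-endmember balance reproduces hand-computed fractions", {
  r <- two_endmember_fraction(4.6, em_bio = 0.6, em_atm = 92)
  expect_equal(r$f_bio, (92 - 4.6) / (92 - 0.6))
  expect_equal(r$f_atm + r$f_bio, 1)
  expect_false(r$clipped)

  r17 <- two_endmember_fraction(1.3, em_bio = 0, em_atm = 32, tracer = "D17O")
  expect_equal(r17$f_bio, 1 - 1.3 / 32)
  expect_identical(r17$tracer, "D17O")

  # endpoint identity
  endpoint <- two_endmember_fraction(0.6, 0.6, 92)
  expect_equal(endpoint$f_atm, 0)
  expect_equal(endpoint$f_bio, 1)

  expect_error(two_endmember_fraction(1, 5, 5),
               class = "nitrosource_error_degenerate_endmember")
})

test_that("out-of-hull observations clip with a flag or warn without clipping", {
  r <- two_endmember_fraction(-3, em_bio = 0.6, em_atm = 92, clip = TRUE)
  expect_equal(r$f_atm, 0)
  expect_true(r$clipped)
  expect_true(r$out_of_hull)
  expect_warning(
    r2 <- two_endmember_fraction(-3, em_bio = 0.6, em_atm = 92, clip = FALSE),
    class = "nitrosource_warning_out_of_hull"
  )
  expect_lt(r2$f_atm, 0)
  expect_equal(r2$f_atm + r2$f_bio, 1)
})

test_that("inversion oracle: forward mix then apportion recovers the fraction", {
  set.seed(101)
  for (i in 1:1000) {
    em_b <- stats::runif(1, -20, 20)
    em_a <- em_b + sample(c(-1, 1), 1) * stats::runif(1, 1e-6, 100)
    f <- stats::runif(1)
    obs <- f * em_a + (1 - f) * em_b
    got <- two_endmember_fraction(obs, em_b, em_a)$f_atm
    expect_lt(abs(got - f), 1e-12)
  }
})

test_that("f_atm increases strictly with the observation when em_atm > em_bio", {
  obs <- seq(0.6, 92, length.out = 50)
  f <- two_endmember_fraction(obs, 0.6, 92)$f_atm
  expect_true(all(diff(f) > 0))
})

test_that("aggregation modes: mean-first averages, per-sample passes through", {
  expect_equal(aggregate_observations(4.6), 4.6)
  expect_equal(aggregate_observations(c(2, 6)), 4)
  expect_identical(aggregate_observations(c(1, 2, 3), mode = "per_sample"),
                   c(1, 2, 3))
  expect_error(aggregate_observations(numeric()),
               class = "nitrosource_error_no_data")
})

test_that("Monte-Carlo propagation: determinism, noise collapse, median near closed form", {
  em <- default_endmembers()
  # zero noise collapses to the closed form with zero-width interval
  z <- monte_carlo_fraction(4.6, 0, em$biological, em$atmospheric,
                            n_draws = 500, seed = 3)
  expect_equal(z$ci_low, z$ci_high)
  expect_equal(z$f_atm_median, z$f_atm)

  a <- monte_carlo_fraction(4.6, 0.3, em$biological, em$atmospheric,
                            n_draws = 2e4, seed = 42)
  b <- monte_carlo_fraction(4.6, 0.3, em$biological, em$atmospheric,
                            n_draws = 2e4, seed = 42)
  expect_identical(a, b)

  # median of the propagated f_bio stays near the closed-form oracle
  expect_lt(abs(a$f_bio_median - 0.9562), 0.005)

  # independent re-simulation with a different generator (inverse-CDF on
  # uniforms) agrees with the package's draws
  set.seed(977)
  f_ind <- 1 - pmin(pmax(
    (stats::qnorm(stats::runif(2e4), 4.6, 0.3) - 0.6) / (92 - 0.6), 0), 1)
  expect_lt(abs(stats::median(f_ind) - a$f_bio_median), 0.005)

  # interval width shrinks monotonically toward zero with sigma
  widths <- vapply(c(0.3, 0.1, 0.01), function(s) {
    r <- monte_carlo_fraction(4.6, s, em$biological, em$atmospheric,
                              n_draws = 5e3, seed = 5)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  expect_error(
    monte_carlo_fraction(4.6, -0.1, em$biological, em$atmospheric,
                         n_draws = 10, seed = 1),
    class = "nitrosource_error_invalid_uncertainty"
  )
  expect_error(
    monte_carlo_fraction(4.6, 0.3, em$biological, em$atmospheric,
                         n_draws = 10, seed = NULL),
    class = "nitrosource_error_config"
  )
})

test_that("apportion_dataset reports one row per sample type and tracer", {
  res <- apportion_dataset(make_isotope_table(), n_draws = 1000, seed = 8)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$tracer, c("d18O", "D17O"))
  sed18 <- res[res$tracer == "d18O", ]
  expect_equal(sed18$point_obs, 4.6)
  expect_equal(sed18$f_bio, (92 - 4.6) / (92 - 0.6), tolerance = 1e-12)
  expect_true(all(res$f_atm + res$f_bio == 1))
  # Monte-Carlo interval brackets the point estimate for the same observation
  expect_true(all(res$ci_low <= res$f_atm & res$f_atm <= res$ci_high))
})

test_that("apportion_dataset handles D17O-only groups, d17O derivation, empty input", {
  only17 <- tibble::tibble(sample_id = "a", sample_type = "soil", D17O = 1.0)
  r <- apportion_dataset(only17, n_draws = 0)
  expect_equal(nrow(r), 1L)
  expect_identical(r$tracer, "D17O")

  # d17O + d18O derive the anomaly when D17O is not measured
  derived <- tibble::tibble(sample_id = "a", sample_type = "soil",
                            d18O = 10, d17O = 0.52 * 10 + 1.0)
  r2 <- apportion_dataset(derived, n_draws = 0)
  r2_17 <- r2[r2$tracer == "D17O", ]
  expect_equal(r2_17$point_obs, 1.0)

  empty <- tibble::tibble(sample_id = character(), sample_type = character(),
                          d18O = double())
  expect_equal(nrow(apportion_dataset(empty, n_draws = 0)), 0L)
})

test_that("per-sample mode averages per-sample fractions", {
  tab <- make_isotope_table()
  res <- apportion_dataset(tab, mode = "per_sample", n_draws = 0)
  sed18 <- res[res$tracer == "d18O", ]
  by_hand <- mean((tab$d18O - 0.6) / (92 - 0.6))
  expect_equal(sed18$f_atm, by_hand, tolerance = 1e-12)
})

test_that("isotope table validation rejects bad schemas and fills precisions", {
  expect_error(validate_isotope_table(tibble::tibble(x = 1)),
               class = "nitrosource_error_schema")
  expect_error(
    validate_isotope_table(tibble::tibble(sample_id = "a",
                                          sample_type = "ocean")),
    class = "nitrosource_error_schema"
  )
  v <- validate_isotope_table(tibble::tibble(sample_id = "a",
                                             sample_type = "sediment",
                                             d18O = 4.6))
  expect_equal(v$sigma_d18O, 0.3)
  expect_equal(v$sigma_D17O, 0.8)
  expect_equal(v$sigma_d15N, 0.6)
})
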