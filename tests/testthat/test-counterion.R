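test_that("expected slope reproduces the counterion ladder", {
  expect_equal(round(expected_slope(22.99), 3), 1.075)            # Na+
  expect_equal(round(expected_slope(18.04), 3), 1.059)            # NH4+
  expect_equal(round(expected_slope(24.305, valence = 2), 3), 1.039)  # Mg2+
  expect_equal(round(expected_slope(1.00728), 3), 1.003)          # H+
  expect_error(expected_slope(22.99, valence = 3), "valence")
})

test_that("the difference equation matches full-minus-empty exactly", {
  # worked example: j*m_N = 1.000 MDa, ammonium-like effective cation
  p <- counterion_params(M = 3.732e6, i = 208, j = 1e6 / 307.94,
                         m_N = 307.94, m_plus = 12.63, m_minus = 59.04)
  expect_equal(predicted_mass_difference(p) / 1e6, 1.0261,
               tolerance = 1e-4)
  expect_equal(predicted_mass_difference(p),
               full_particle_mass(p) - empty_particle_mass(p),
               tolerance = 1e-12)
  # i = 0 reduction
  p0 <- counterion_params(M = 0, i = 0, j = 1000, m_plus = 22.99)
  expect_equal(predicted_mass_difference(p0),
               (1 + 22.99 / p0$m_N) * 1000 * p0$m_N, tolerance = 1e-12)
})

test_that("difference-form and two-state-form agree for random params", {
  set.seed(71)
  for (rep in 1:20) {
    p <- counterion_params(M = stats::runif(1, 3e6, 4e6),
                           i = stats::runif(1, 0, 500),
                           j = stats::runif(1, 1000, 5000),
                           m_N = stats::runif(1, 300, 320),
                           m_plus = stats::runif(1, 1, 40),
                           m_minus = stats::runif(1, 0, 80),
                           valence = sample(1:2, 1))
    expect_equal(predicted_mass_difference(p),
                 full_particle_mass(p) - empty_particle_mass(p),
                 tolerance = 1e-9)
  }
})

test_that("expected_slope equals the slope of the difference equation", {
  m_plus <- 18.04; m_N <- 307.94; i <- 180
  js <- c(1000, 2000, 4000)
  d <- vapply(js, function(j) predicted_mass_difference(
    counterion_params(M = 0, i = i, j = j, m_N = m_N, m_plus = m_plus)), 0)
  slope <- diff(d) / diff(js * m_N)
  expect_equal(slope, rep(expected_slope(m_plus, 1, m_N), 2),
               tolerance = 1e-12)
})

test_that("noise-free points are recovered exactly by the OLS fit", {
  x <- genome_mass_from_length(table1$n_bases)
  y <- 1.041 * x - 16000
  fit <- fit_counterion_model(data.frame(sequence_mass = x,
                                         measured_difference = y))
  expect_equal(fit$slope, 1.041, tolerance = 1e-9)
  expect_equal(fit$intercept, -16000, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points: interpolating line
  fit2 <- fit_counterion_model(c(1e6, 2e6), c(1.05e6, 2.10e6))
  expect_equal(fit2$slope, 1.05, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate fit inputs raise errors", {
  expect_error(fit_counterion_model(c(1e6), c(1e6)), "at least 2")
  expect_error(fit_counterion_model(c(1e6, 1e6), c(1e6, 1.1e6)),
               "identical")
  expect_error(fit_counterion_model(data.frame(a = 1, b = 2)), "columns")
})

test_that("noisy simulation recovers the generating slope (oracle)", {
  set.seed(88)
  x <- genome_mass_from_length(table1$n_bases)
  slopes <- replicate(500, {
    y <- 1.041 * x - 16000 + stats::rnorm(length(x), 0, 1e4)
    fit_counterion_model(data.frame(sequence_mass = x,
                                    measured_difference = y))$slope
  })
  expect_lt(abs(mean(slopes) - 1.041), 0.005)
  # sampling SD of the slope matches the OLS closed form within 10%
  sd_theory <- 1e4 / sqrt(sum((x - mean(x))^2))
  set.seed(89)
  slopes2 <- replicate(1000, {
    y <- 1.041 * x - 16000 + stats::rnorm(length(x), 0, 1e4)
    fit_counterion_model(data.frame(sequence_mass = x,
                                    measured_difference = y))$slope
  })
  expect_equal(sd(slopes2), sd_theory, tolerance = 0.1)
})

test_that("fit interpretation recovers cation mass and basic sites", {
  interp <- interpret_fit(list(slope = 1.041, intercept = -0.016e6),
                          m_N = 307.94)
  expect_equal(interp$m_plus_eff, 12.63, tolerance = 1e-2)
  # ammonium + acetate: ~3.5 sites per capsid protein, consistent with ~3
  expect_equal(interp$i_per_protein, 3.46, tolerance = 0.01)
  expect_false(interp$negative_sites)
  expect_equal(interpret_fit(list(slope = 1.0, intercept = 0))$i_total, 0)
  expect_warning(
    flagged <- interpret_fit(list(slope = 1.0, intercept = 5e3)),
    "negative basic-site count")
  expect_true(flagged$negative_sites)
})

test_that("round trip: params -> predictions -> fit -> interpretation", {
  m_N <- mean_ionized_nucleotide_mass()
  m_plus <- 18.04; m_minus <- 59.04; i <- 210
  x <- genome_mass_from_length(table1$n_bases)
  d <- vapply(x / m_N, function(j) predicted_mass_difference(
    counterion_params(M = 3.732e6, i = i, j = j, m_N = m_N,
                      m_plus = m_plus, m_minus = m_minus)), 0)
  fit <- fit_counterion_model(data.frame(sequence_mass = x,
                                         measured_difference = d))
  interp <- interpret_fit(fit, m_N = m_N, m_plus_assumed = m_plus,
                          m_minus_assumed = m_minus)
  expect_equal(interp$m_plus_eff, m_plus, tolerance = 1e-6)
  expect_equal(interp$i_total, i, tolerance = 1e-6)
})
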