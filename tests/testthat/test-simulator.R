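test_that("simulation is reproducible and validates its inputs", {
  mix <- empty_full_mixture(goi_mass = 683385)
  ev1 <- simulate_ion_events(mix, n_ions = 500, seed = 42)
  ev2 <- simulate_ion_events(mix, n_ions = 500, seed = 42)
  expect_identical(ev1, ev2)
  ev3 <- simulate_ion_events(mix, n_ions = 500, seed = 43)
  expect_false(identical(ev1$mass, ev3$mass))

  expect_equal(nrow(simulate_ion_events(mix, n_ions = 0, seed = 1)), 0L)
  bad <- mix; bad[[1]]$weight <- 0.9
  expect_error(simulate_ion_events(bad, n_ions = 10, seed = 1),
               "sum to 1")
  expect_error(simulate_ion_events(mix, n_ions = -1, seed = 1), ">= 0")
})

test_that("per-event mass equals mz * z and flags drive acceptance", {
  ev <- simulate_ion_events(empty_full_mixture(683385), n_ions = 2000,
                            seed = 7)
  expect_equal(ev$mass, ev$mz * ev$z, tolerance = 1e-9)
  cfg <- default_cfg
  p_flag <- cfg$multiple_ion_rate + cfg$short_trap_rate -
    cfg$multiple_ion_rate * cfg$short_trap_rate
  n_flagged <- sum(ev$multiple_ion | ev$short_trap)
  se <- sqrt(p_flag * (1 - p_flag) * nrow(ev))
  expect_lt(abs(n_flagged - p_flag * nrow(ev)), 4 * se)
})

test_that("single-species sample moments match the forward model", {
  mix <- list(mixture_component("empty", packaging_state("empty"), 1))
  cfg0 <- noiseless_mz_cfg
  ev <- simulate_ion_events(mix, cfg = cfg0, n_ions = 1e5, seed = 3)
  ps <- expected_peak_shape(capsid_mass_pmf(aav8), cfg = cfg0,
                            n_grid = 4001)
  se <- ps$sd / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$mass) - ps$mean), 4 * se)
  expect_equal(sd(ev$mass), ps$sd, tolerance = 0.02)
})

test_that("well-separated 50/50 mixture recovers its weights", {
  n <- 1e4
  mix <- empty_full_mixture(goi_mass = 1.4e6, w_full = 0.5)
  ev <- simulate_ion_events(mix, n_ions = n, seed = 11)
  mid <- 3.732e6 + 1.4e6 / 2
  frac_full <- mean(ev$mass > mid)
  expect_lt(abs(frac_full - 0.5), 3 * sqrt(0.25 / n))
})

test_that("full particles carry the counterion-inflated genome mass", {
  goi <- genome_mass_from_length(2219)
  mix <- list(mixture_component("full",
                                packaging_state("full_GOI", goi_mass = goi),
                                1))
  ev <- simulate_ion_events(mix, cfg = noiseless_mz_cfg, n_ions = 2e4,
                            seed = 13, dna_inflation = 1.041,
                            dna_offset = -16000)
  expected <- mean_capsid_mass(aav8) + 1.041 * goi - 16000
  se <- sd(ev$mass) / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$mass) - expected), 4 * se)
})

test_that("headful particles are pinned near the packaging capacity", {
  mix <- list(mixture_component("headful",
                                packaging_state("headful",
                                                capacity_sd = 5e4), 1))
  ev <- simulate_ion_events(mix, cfg = noiseless_mz_cfg, n_ions = 1e4,
                            seed = 17)
  expect_equal(mean(ev$mass), 5.33e6, tolerance = 0.005)
  # total-mass spread is set by capacity_sd + noise, not by capsid
  # heterogeneity (DNA fills each capsid to the same total)
  expect_lt(sd(ev$mass), 8e4)
})

test_that("multimer orders scale mass and charge factors apply", {
  mix <- list(
    mixture_component("dimer", packaging_state("multimer"), 0.5,
                      multimer_order = 2L),
    mixture_component("dimer-ext", packaging_state("multimer"), 0.5,
                      multimer_order = 2L, charge_shape_factor = 1.26))
  ev <- simulate_ion_events(mix, n_ions = 4000, seed = 19)
  expect_equal(mean(ev$mass), 2 * mean_capsid_mass(aav8), tolerance = 0.01)
  z_compact <- mean(ev$z[ev$component == "dimer"])
  z_ext <- mean(ev$z[ev$component == "dimer-ext"])
  expect_equal(z_ext / z_compact, 1.26, tolerance = 0.02)
})

test_that("incubation rescales only the extra-DNA fragment load", {
  mix <- list(mixture_component("empty", packaging_state("empty"), 1,
                                extra_dna_mean = 32e3, extra_dna_sd = 1e4))
  expect_identical(apply_incubation(mix, 0), mix)
  gone <- apply_incubation(mix, 1)
  expect_equal(gone[[1]]$extra_dna_mean, 0)
  expect_equal(gone[[1]]$extra_dna_sd, 0)
  expect_error(apply_incubation(mix, 1.2), "\\[0, 1\\]")

  # removing all extra DNA shifts the simulated peak down by ~32 kDa
  # (mirrors the empty-capsid shift observed on temperature cycling)
  cfg0 <- noiseless_mz_cfg
  ev_pre <- simulate_ion_events(mix, cfg = cfg0, n_ions = 2e4, seed = 23)
  ev_post <- simulate_ion_events(gone, cfg = cfg0, n_ions = 2e4, seed = 24)
  shift <- mean(ev_pre$mass) - mean(ev_post$mass)
  expect_equal(shift, 32e3, tolerance = 0.1)
  # and the width returns to the capsid-plus-instrument baseline
  ps <- expected_peak_shape(capsid_mass_pmf(aav8), cfg = cfg0)
  expect_equal(sd(ev_post$mass), ps$sd, tolerance = 0.03)
  expect_gt(sd(ev_pre$mass), sd(ev_post$mass))
})

test_that("event tables round-trip through delimited text", {
  ev <- simulate_ion_events(empty_full_mixture(683385), n_ions = 200,
                            seed = 29)
  path <- tempfile(fileext = ".tsv")
  write_ion_events(ev, path)
  expect_match(readLines(path, n = 2)[2], "^# seed: 29$")
  back <- read_ion_events(path)
  expect_equal(back$mass, ev$mass, tolerance = 1e-9)
  expect_equal(back$z, ev$z, tolerance = 1e-9)
  expect_identical(back$multiple_ion, ev$multiple_ion)
  expect_identical(attr(back, "seed"), 29L)
})
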