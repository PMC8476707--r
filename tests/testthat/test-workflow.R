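test_that("scenario configs are validated with field paths", {
  expect_error(read_scenario_config(tempfile()), "not found")
  expect_error(validate_scenario_config(list()), "mixture")
  expect_error(validate_scenario_config(
    list(mixture = list(list(kind = "empty")))), "mixture\\[1\\].weight")
  expect_error(validate_scenario_config(
    list(mixture = list(list(weight = 1)))), "mixture\\[1\\].kind")
  expect_error(validate_scenario_config(
    list(mixture = list(list(kind = "empty", weight = 0.7)))), "sum to 1")
  expect_error(validate_scenario_config(
    list(capsid = list(vp_masses = c(1, 2)),
         mixture = list(list(kind = "empty", weight = 1)))),
    "capsid.vp_masses")
})

test_that("defaulted fields are logged with their provenance", {
  cfg <- validate_scenario_config(
    list(mixture = list(list(kind = "empty", weight = 1)), seed = 5))
  expect_s3_class(cfg, "scenario_config")
  expect_true("capsid.vp_masses" %in% cfg$defaults_log$field)
  expect_false("seed" %in% cfg$defaults_log$field)
  expect_true(all(cfg$defaults_log$provenance %in%
                    c("reference value", "design default")))
})

test_that("a zero-ion scenario produces valid empty outputs", {
  cfg <- validate_scenario_config(
    list(name = "nil", n_ions = 0, seed = 1,
         mixture = list(list(kind = "empty", weight = 1)),
         analysis = list(fit_components = FALSE, classify = FALSE)))
  out <- tempfile()
  res <- run_scenario(cfg, output_dir = out)
  expect_equal(nrow(res$runs[[1]]$events), 0L)
  expect_true(file.exists(file.path(out, "nil", "events.tsv")))
  expect_true(file.exists(file.path(out, "run_log.txt")))
})

test_that("identical config and seed give byte-identical bundles", {
  cfg <- read_scenario_config(scenario_path("refstd.json"))
  cfg$n_ions <- 2000L
  out1 <- tempfile(); out2 <- tempfile()
  run_scenario(cfg, output_dir = out1)
  run_scenario(cfg, output_dir = out2)
  f1 <- list.files(out1, recursive = TRUE)
  f2 <- list.files(out2, recursive = TRUE)
  expect_identical(f1, f2)
  expect_gt(length(f1), 0L)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  # a different seed changes the events
  out3 <- tempfile()
  run_scenario(cfg, output_dir = out3, seed = 99)
  expect_false(identical(
    unname(tools::md5sum(file.path(out1, "AAV8-RSS", "events.tsv"))),
    unname(tools::md5sum(file.path(out3, "AAV8-RSS", "events.tsv")))))
})

test_that("vector panel places each GOI peak at its expected mass", {
  cfg <- read_scenario_config(scenario_path("vector-panel.json"))
  cfg$n_ions <- 4000L  # scaled down for test runtime; acceptance uses 1e4
  res <- run_scenario(cfg)
  expect_length(res$runs, 8L)
  empty <- mean_capsid_mass(aav8)
  for (r in res$runs) {
    spec <- r$spectrum
    full_expect <- expected_vector_mass(empty, r$goi_mass)
    # mode among bins near the full peak is within one bin of expectation
    near <- which(abs(spec$bin_mid - full_expect) < 2e5)
    mode_mid <- spec$bin_mid[near][which.max(spec$counts[near])]
    expect_lt(abs(mode_mid - full_expect), 1.5 * spec$bin_width)
  }
})

test_that("counterion panel run recovers the generating line", {
  cfg <- read_scenario_config(scenario_path("counterion-panel.json"))
  cfg$n_ions <- 4000L
  res <- run_scenario(cfg)
  expect_s3_class(res$counterion_fit, "counterion_fit")
  expect_equal(res$counterion_fit$slope, 1.041, tolerance = 0.01)
  expect_gt(res$counterion_fit$r_squared, 0.99)
})

test_that("the CLI subcommands run end to end", {
  expect_invisible(cdms_cli(character()))
  expect_output(cdms_cli(c("expected-mass", "--bases", "2219")),
                "3.732 MDa")
  expect_error(cdms_cli("bogus"), "unknown subcommand")

  # fit-counterions on a points table
  pts <- tempfile(fileext = ".tsv")
  x <- genome_mass_from_length(table1$n_bases)
  utils::write.table(
    data.frame(name = table1$name, sequence_mass_da = x,
               measured_difference_da = 1.041 * x - 16000),
    pts, sep = "\t", quote = FALSE, row.names = FALSE)
  rep_json <- tempfile(fileext = ".json")
  expect_output(cdms_cli(c("fit-counterions", "--points", pts,
                           "--out", rep_json)), "slope 1.0410")
  rep <- jsonlite::read_json(rep_json)
  expect_equal(rep$slope, 1.041, tolerance = 1e-9)

  # simulate then analyze an event file
  out <- tempfile()
  expect_output(cdms_cli(c("simulate", "--config",
                           scenario_path("refstd.json"), "--out", out,
                           "--n-ions", "500", "--seed", "3")),
                "1 run\\(s\\)")
  ev_file <- file.path(out, "AAV8-RSS", "events.tsv")
  expect_true(file.exists(ev_file))
  out2 <- tempfile()
  expect_output(cdms_cli(c("analyze", "--events", ev_file, "--out", out2,
                           "--empty-mass", "3732045", "--goi-mass",
                           format(genome_mass_from_length(3400),
                                  scientific = FALSE),
                           "--window-sd", "55000")),
                "packaging-state fractions")
  expect_true(file.exists(file.path(out2, "classification.tsv")))
})
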