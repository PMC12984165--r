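test_that("reference configuration loads with the three published profiles", {
  cfg <- system.file("extdata", "reference_config.yaml", package = "mammocea")
  bundle <- load_config(cfg)
  st <- bundle$strategies
  expect_setequal(st$name, c("conventional", "companion", "standalone"))
  expect_equal(st$sensitivity[match(c("conventional", "companion", "standalone"), st$name)],
               c(0.691, 0.715, 0.805))
  expect_equal(st$specificity[match(c("conventional", "companion", "standalone"), st$name)],
               c(0.954, 0.968, 0.893))
  expect_equal(st$cost_per_scan[match(c("conventional", "companion", "standalone"), st$name)],
               c(110, 97.5, 80))
  expect_identical(bundle$policy$compliance, 0.4)
  expect_identical(bundle$economics$discount_rate, 0.03)
})

test_that("invalid configurations are rejected with named errors", {
  expect_error(strategy_profile("x", 1.2, 0.9, 10), "sensitivity",
               class = "mammocea_validation_error")
  expect_error(strategy_profile("x", 0.7, -0.1, 10), "specificity",
               class = "mammocea_validation_error")
  expect_error(screening_policy(start_age = 70, stop_age = 69),
               class = "mammocea_validation_error")
  expect_error(screening_policy(horizon = 5), "horizon",
               class = "mammocea_validation_error")
  expect_error(economic_settings(wtp_threshold = 0), "wtp",
               class = "mammocea_validation_error")

  # specificity out of range inside a config file
  cfg <- system.file("extdata", "reference_config.yaml", package = "mammocea")
  raw <- yaml::read_yaml(cfg)
  raw$strategies[[1]]$specificity <- 1.2
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, bad)
  expect_error(load_config(bad), "specificity", class = "mammocea_validation_error")

  # unknown top-level keys are rejected, missing sections named
  raw2 <- yaml::read_yaml(cfg)
  raw2$surprise <- 1
  bad2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw2, bad2)
  expect_error(load_config(bad2), "surprise", class = "mammocea_schema_error")

  raw3 <- yaml::read_yaml(cfg)
  raw3$utilities <- NULL
  bad3 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw3, bad3)
  expect_error(load_config(bad3), "utilities", class = "mammocea_schema_error")

  # a strategy entry missing a field names the field
  raw4 <- yaml::read_yaml(cfg)
  raw4$strategies[[2]]$sensitivity <- NULL
  bad4 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw4, bad4)
  expect_error(load_config(bad4), "sensitivity", class = "mammocea_schema_error")
})

test_that("configuration round-trips save -> load unchanged", {
  path <- tempfile(fileext = ".yaml")
  save_config(ref_bundle, path)
  reloaded <- load_config(path)
  keep <- c("schema_version", "strategies", "natural_history", "costs", "utilities")
  expect_equal(reloaded[keep], ref_bundle[keep], tolerance = 1e-8)
  expect_equal(unclass(reloaded$policy), unclass(ref_bundle$policy))
  expect_equal(unclass(reloaded$economics), unclass(ref_bundle$economics))
})

test_that("fee substitution reproduces and generalises the scan prices", {
  expect_equal(derive_scan_costs(110, 17.5, 5),
               c(conventional = 110, companion = 97.5, standalone = 80))
  # ai_fee equal to the read fee leaves the companion price unchanged
  expect_equal(derive_scan_costs(110, 5, 5),
               c(conventional = 110, companion = 110, standalone = 105))
  expect_equal(derive_scan_costs(100, 10, 0),
               c(conventional = 100, companion = 90, standalone = 80))
  expect_error(derive_scan_costs(30, 20, 5), "exceed",
               class = "mammocea_validation_error")
})

test_that("fee substitution is linear and companion - standalone equals the read fee", {
  set.seed(42)
  for (i in 1:25) {
    base <- runif(1, 50, 300)
    fee <- runif(1, 0, base / 2)
    ai <- runif(1, 0, 30)
    v <- derive_scan_costs(base, fee, ai)
    expect_equal(v[["companion"]] - v[["standalone"]], fee)
    expect_equal(v[["conventional"]], base)
    # linearity in each argument
    d <- derive_scan_costs(base + 1, fee, ai) - v
    expect_equal(unname(d), c(1, 1, 1))
    d2 <- derive_scan_costs(base, fee, ai + 1) - v
    expect_equal(unname(d2), c(0, 1, 1))
  }
  ref <- setNames(ref_bundle$strategies$cost_per_scan, ref_bundle$strategies$name)
  expect_lt(ref[["companion"]], ref[["conventional"]])
  expect_lt(ref[["standalone"]], ref[["companion"]])
})

test_that("generated synthetic bundles always re-validate", {
  for (seed in c(1L, 99L, 4242L)) {
    set.seed(seed)
    b <- generate_bundle(synthetic_bundle_spec(
      seed = seed,
      onset_scale = runif(1, 0.001, 0.006),
      treatment_cost_base = runif(1, 10000, 40000)
    ))
    expect_silent(validate_bundle(b))
  }
})
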