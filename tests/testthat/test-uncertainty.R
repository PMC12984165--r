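test_that("method-of-moments shapes match the closed forms", {
  bm <- beta_moments(0.5, 0.05)
  expect_equal(bm$alpha, 49.5)
  expect_equal(bm$beta, 49.5)
  gm <- gamma_moments(110, 5.5)
  expect_equal(gm$shape, 400)
  expect_equal(gm$scale, 0.275)
  # Beta moment condition: SD too large for the mean
  expect_error(beta_moments(0.99, 0.2), "moment condition",
               class = "mammocea_validation_error")
})

test_that("zero dispersion collapses draws onto the base values", {
  set.seed(5)
  drawn <- sample_psa_draw(ref_bundle, cost_cv = 0, utility_sd = 0)
  expect_equal(drawn$costs, ref_bundle$costs)
  expect_equal(drawn$utilities, ref_bundle$utilities)
  expect_equal(drawn$strategies$cost_per_scan, ref_bundle$strategies$cost_per_scan)
})

test_that("structural parameters are never sampled", {
  set.seed(6)
  for (i in 1:20) {
    d <- sample_psa_draw(ref_bundle)
    expect_identical(d$strategies$sensitivity, ref_bundle$strategies$sensitivity)
    expect_identical(d$strategies$specificity, ref_bundle$strategies$specificity)
    expect_identical(d$policy$compliance, ref_bundle$policy$compliance)
    expect_identical(d$economics$discount_rate, ref_bundle$economics$discount_rate)
    # every drawn utility stays a probability
    expect_true(all(unlist(d$utilities) >= 0 & unlist(d$utilities) <= 1))
    expect_true(all(unlist(d$costs) >= 0))
  }
})

test_that("tornado with zero perturbation has zero width everywhere", {
  tor <- one_way_dsa(ref_bundle, parameters = c("compliance", "biopsy_cost"),
                     perturbation = 0)
  expect_equal(tor$width, c(0, 0))
  expect_equal(tor$icer_low, tor$icer_high)
  expect_equal(tor$icer_low, tor$base_icer)
})

test_that("listing a parameter twice gives identical tornado rows", {
  tor <- one_way_dsa(ref_bundle, parameters = c("biopsy_cost", "biopsy_cost"))
  expect_equal(tor$icer_low[1], tor$icer_low[2])
  expect_equal(tor$icer_high[1], tor$icer_high[2])
})

test_that("tornado rows equal independent recomputation at the perturbed value", {
  tor <- one_way_dsa(ref_bundle, parameters = c("compliance", "ultrasound_cost"),
                     perturbation = 0.1)
  for (p in tor$parameter) {
    for (side in c(0.9, 1.1)) {
      b <- ref_bundle
      if (p == "compliance") {
        b$policy$compliance <- b$policy$compliance * side
      } else {
        b$costs$ultrasound_cost <- b$costs$ultrasound_cost * side
      }
      ref <- accumulate(run_cohort(b, "conventional"), b)
      can <- accumulate(run_cohort(b, "companion"), b)
      want <- incremental(ref, can)$icer
      col <- if (side < 1) "icer_low" else "icer_high"
      expect_equal(tor[[col]][tor$parameter == p], want)
    }
  }
})

test_that("tornado widths are sorted and the ordering is a permutation", {
  params <- c("compliance", "biopsy_cost", "specificity.companion")
  # specificity 0.968 * 1.1 > 1 must be clipped audibly, never silently
  expect_warning(tor <- one_way_dsa(ref_bundle, parameters = params),
                 "clipped")
  expect_setequal(tor$parameter, params)
  expect_true(all(diff(tor$width) <= 1e-12))
  expect_true(all(tor$width >= 0))
})

test_that("a single PSA draw gives degenerate probabilities summing to one", {
  p <- run_psa(ref_bundle, n_draws = 1, wtp_grid = c(0, 50000), seed = 2)
  expect_true(all(p$ceac$probability %in% c(0, 1)))
  sums <- tapply(p$ceac$probability, p$ceac$wtp, sum)
  expect_equal(as.vector(sums), rep(1, 2))
})

test_that("zero-dispersion PSA reproduces the deterministic NMB ranking", {
  b <- ref_bundle
  b$psa <- list(cost_cv = 0, utility_sd = 0)
  grid <- seq(0, 100000, by = 25000)
  p <- run_psa(b, n_draws = 5, wtp_grid = grid, seed = 9)
  econ <- purrr::map_dfr(c("conventional", "companion", "standalone"),
                         function(s) accumulate(run_cohort(b, s), b))
  for (i in seq_along(grid)) {
    nmb <- grid[i] * econ$total_qalys - econ$total_cost
    best <- econ$strategy[which.max(nmb)]
    probs <- p$ceac[p$ceac$wtp == grid[i], ]
    expect_equal(probs$probability[probs$strategy == best], 1)
  }
})

test_that("a seeded PSA rerun is bit-identical", {
  p1 <- run_psa(ref_bundle, n_draws = 60, wtp_grid = seq(0, 100000, 20000), seed = 31)
  p2 <- run_psa(ref_bundle, n_draws = 60, wtp_grid = seq(0, 100000, 20000), seed = 31)
  expect_identical(p1$ceac, p2$ceac)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(ref_bundle, n_draws = 60, wtp_grid = seq(0, 100000, 20000), seed = 32)
  expect_false(identical(p1$ceac, p3$ceac))
})

test_that("CEAC curves are valid probabilities with qualitative shape logged", {
  p <- run_psa(ref_bundle, n_draws = 150, wtp_grid = seq(0, 100000, 10000), seed = 8)
  expect_true(all(p$ceac$probability >= 0 & p$ceac$probability <= 1))
  sums <- tapply(p$ceac$probability, p$ceac$wtp, sum)
  expect_equal(as.vector(sums), rep(1, length(unique(p$ceac$wtp))),
               tolerance = 1 / 150)
  # qualitative expectations on the synthetic reference world (logged, not
  # enforced: the synthetic natural history need not reproduce them)
  conv <- p$ceac[p$ceac$strategy == "conventional", ]
  alone <- p$ceac[p$ceac$strategy == "standalone", ]
  message(sprintf(
    "CEAC shape: conventional max probability %.2f; standalone non-decreasing: %s",
    max(conv$probability), all(diff(alone$probability) >= -1 / 150)))
  succeed()
})
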