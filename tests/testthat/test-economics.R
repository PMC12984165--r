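test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(10, 0), 1)
  expect_equal(discount_factor(0:5, 0.03), 1.03^-(0:5))
})

test_that("an immortal healthy cohort accrues the annuity QALY total", {
  b <- inert_bundle()
  b$utilities$healthy <- 1
  b$economics <- economic_settings(discount_rate = 0, wtp_threshold = 50000)
  tr <- run_cohort(b, "conventional", compliance = 0)
  res <- accumulate(tr, b)
  expect_equal(res$total_qalys, 10000 * 50)

  b$economics <- economic_settings(discount_rate = 0.03, wtp_threshold = 50000)
  res_d <- accumulate(tr, b)
  expect_equal(res_d$total_qalys, 10000 * sum(1.03^-(0:49)))
})

test_that("accumulate equals an itemised per-cycle brute-force ledger", {
  tr <- run_cohort(ref_bundle, "companion")
  res <- accumulate(tr, ref_bundle)

  co <- ref_bundle$costs
  ut <- ref_bundle$utilities
  r <- ref_bundle$economics$discount_rate
  scan <- get_strategy(ref_bundle, "companion")$cost_per_scan
  stages <- c("0", "I", "II", "III", "IV")

  cost <- 0; qaly <- 0
  for (t in 1:50) {
    d <- 1 / (1 + r)^(t - 1)
    occ <- tr$occupancy[t, ]
    ev <- tr$events[t, ]
    c_t <- ev$mammograms * scan +
      (ev$tp + ev$fp) * (co$ultrasound_cost +
                           co$biopsy_fraction_of_recalls * co$biopsy_cost)
    for (s in 1:5) {
      c_t <- c_t + occ[[paste0("dx_", stages[s])]] * co$treatment_cost[s] +
        occ[[paste0("rem_", stages[s])]] * co$remission_fraction * co$treatment_cost[s] +
        occ[[paste0("rec_", stages[s])]] * co$recurrence_cost
    }
    q_t <- occ[["healthy"]] * ut$healthy +
      sum(occ[paste0("undx_", stages)]) * ut$undiagnosed +
      sum(occ[paste0("dx_", stages)] * ut$by_stage) +
      sum(occ[paste0("rem_", stages)]) * ut$remission +
      sum(occ[paste0("rec_", stages)]) * ut$recurrence
    cost <- cost + d * c_t
    qaly <- qaly + d * q_t
  }
  expect_equal(res$total_cost, cost)
  expect_equal(res$total_qalys, qaly)
})

test_that("cost breakdown sums to the total and QALYs respect the annuity bound", {
  for (s in c("conventional", "standalone")) {
    res <- accumulate(run_cohort(ref_bundle, s), ref_bundle)
    breakdown <- res$cost_screening + res$cost_workup + res$cost_treatment +
      res$cost_remission + res$cost_recurrence
    expect_equal(res$total_cost, breakdown, tolerance = 1e-9)
    bound <- 10000 * sum(1.03^-(0:49))
    expect_lte(res$total_qalys, bound)
    expect_gt(res$total_qalys, 0)
  }
})

test_that("discounting never increases totals", {
  tr <- run_cohort(ref_bundle, "conventional")
  b0 <- ref_bundle
  b0$economics <- economic_settings(discount_rate = 0, wtp_threshold = 50000)
  undisc <- accumulate(tr, b0)
  disc <- accumulate(tr, ref_bundle)
  expect_lt(disc$total_cost, undisc$total_cost)
  expect_lt(disc$total_qalys, undisc$total_qalys)
})

test_that("incremental comparisons handle ratios, dominance and NMB", {
  a <- economic_result("conventional", 100000, 2000)
  b <- economic_result("candidate", 90000, 2010)
  inc <- incremental(a, b, wtp = 50000)
  expect_equal(inc$delta_cost, -10000)
  expect_equal(inc$delta_qalys, 10)
  expect_equal(inc$icer, -1000)
  expect_match(inc$dominance, "dominant")
  expect_equal(inc$nmb, 50000 * 10 + 10000)

  # self-comparison: all deltas zero, no ratio
  self <- incremental(a, a, wtp = 50000)
  expect_equal(self$delta_cost, 0)
  expect_equal(self$delta_qalys, 0)
  expect_true(is.na(self$icer))
  expect_equal(self$nmb, 0)

  # equal QALYs with different cost: labelled by cost, no ratio
  c_ <- economic_result("cheaper", 95000, 2000)
  bycost <- incremental(a, c_, wtp = 50000)
  expect_true(is.na(bycost$icer))
  expect_match(bycost$dominance, "by cost")

  # NMB is linear in the willingness to pay
  w <- c(0, 25000, 50000, 100000)
  nmbs <- vapply(w, function(x) incremental(a, b, x)$nmb, numeric(1))
  fit <- diff(nmbs) / diff(w)
  expect_equal(fit, rep(inc$delta_qalys, 3))
})
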