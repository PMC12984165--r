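test_that("specificity splits cancer-free attendees into FP and TN", {
  occ <- occ_empty()
  occ["healthy"] <- 1000
  conv <- strategy_profile("conventional", 0.691, 0.954, 110)
  out <- classify_screen(occ, compliance = 1, strategy = conv)
  expect_equal(out$fp, 46)
  expect_equal(out$tn, 954)
  expect_equal(out$tp, 0)
  expect_equal(out$fn, 0)
  expect_equal(out$attendees, 1000)
})

test_that("sensitivity splits preclinical attendees into TP and FN, preserving stage", {
  occ <- occ_empty()
  occ["undx_I"] <- 60
  occ["undx_III"] <- 40
  alone <- strategy_profile("standalone", 0.805, 0.893, 80)
  out <- classify_screen(occ, compliance = 1, strategy = alone)
  expect_equal(out$tp, 80.5)
  expect_equal(out$fn, 19.5)
  expect_equal(out$tp_stage_I, 0.805 * 60)
  expect_equal(out$tp_stage_III, 0.805 * 40)
  expect_equal(out$tp_stage_0 + out$tp_stage_II + out$tp_stage_IV, 0)
})

test_that("a perfect test yields neither false positives nor false negatives", {
  occ <- occ_empty()
  occ["healthy"] <- 500
  occ["undx_II"] <- 25
  perfect <- strategy_profile("perfect", 1, 1, 0)
  out <- classify_screen(occ, compliance = 0.7, strategy = perfect)
  expect_equal(out$fp, 0)
  expect_equal(out$fn, 0)
  expect_equal(out$tp, 0.7 * 25)
  expect_equal(out$tn, 0.7 * 500)
})

test_that("only healthy and preclinical states are screen-eligible", {
  occ <- occ_empty()
  occ["rem_I"] <- 100
  occ["rec_II"] <- 50
  occ["dx_0"] <- 25
  occ["dead_other"] <- 500
  out <- classify_screen(occ, compliance = 1,
                         strategy = strategy_profile("x", 0.8, 0.9, 10))
  expect_equal(out$attendees, 0)
})

test_that("compliance outside [0,1] is rejected", {
  expect_error(classify_screen(occ_empty(), 1.3,
                               strategy_profile("x", 0.8, 0.9, 10)),
               class = "mammocea_validation_error")
})

test_that("work-up pricing matches the itemised recall cascade", {
  costs0 <- list(ultrasound_cost = 150, biopsy_cost = 800,
                 biopsy_fraction_of_recalls = 0.5)
  expect_equal(workup_cost(list(tp = 0, fp = 0), costs0), 0)
  expect_equal(workup_cost(list(tp = 4, fp = 6), costs0), 10 * 150 + 5 * 800)

  # itemised oracle: price each fractional recall one by one
  set.seed(11)
  for (i in 1:10) {
    tp <- runif(1, 0, 50); fp <- runif(1, 0, 300)
    us <- runif(1, 50, 400); bx <- runif(1, 300, 2000); frac <- runif(1)
    costs <- list(ultrasound_cost = us, biopsy_cost = bx,
                  biopsy_fraction_of_recalls = frac)
    oracle <- (tp + fp) * us + frac * (tp + fp) * bx
    expect_equal(workup_cost(list(tp = tp, fp = fp), costs), oracle)
  }
})

test_that("doubling compliance doubles first-round TP and FP expectations", {
  occ <- seed_prevalence(ref_bundle$natural_history, 10000)
  conv <- get_strategy(ref_bundle, "conventional")
  half <- classify_screen(occ, 0.2, conv)
  full <- classify_screen(occ, 0.4, conv)
  expect_equal(full$tp, 2 * half$tp)
  expect_equal(full$fp, 2 * half$fp)
  expect_equal(full$attendees, 2 * half$attendees)
})

test_that("cumulative FP and FN follow the specificity and sensitivity orderings", {
  tallies <- sapply(c("conventional", "companion", "standalone"),
                    function(s) run_cohort(ref_bundle, s)$tallies)
  # specificity 0.968 > 0.954 > 0.893 -> FP: companion < conventional < standalone
  expect_lt(tallies["fp", "companion"], tallies["fp", "conventional"])
  expect_lt(tallies["fp", "conventional"], tallies["fp", "standalone"])
  # sensitivity 0.805 > 0.715 > 0.691 -> FN: standalone < companion < conventional
  expect_lt(tallies["fn", "standalone"], tallies["fn", "companion"])
  expect_lt(tallies["fn", "companion"], tallies["fn", "conventional"])
})

test_that("higher participation raises absolute false-positive counts", {
  fp <- vapply(c(0.2, 0.4, 0.8), function(cp) {
    run_cohort(ref_bundle, "companion", compliance = cp)$tallies[["fp"]]
  }, numeric(1))
  expect_true(all(diff(fp) > 0))
})
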