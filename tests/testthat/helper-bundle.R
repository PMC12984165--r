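# Shared fixtures, built in code. The reference bundle is deterministic, so
# one copy serves the whole suite.
ref_bundle <- reference_bundle()

# A natural-history block with every rate zero: useful for identity checks.
zero_nh <- function(ages = 49:100) {
  list(
    ages = as.integer(ages),
    onset_rate = rep(0, length(ages)),
    other_cause_mortality = rep(0, length(ages)),
    stage_progression = rep(0, 5),
    clinical_detection = rep(0, 5),
    recurrence_rate = rep(0, 5),
    bc_mortality = rep(0, 5),
    bc_mortality_recurrence = 0
  )
}

# Bundle variant with selected natural-history rates replaced.
with_nh <- function(bundle, ...) {
  bundle$natural_history <- modifyList(bundle$natural_history, list(...))
  bundle
}

# Immortal, cancer-free world: nothing ever happens to the cohort.
inert_bundle <- function() {
  b <- ref_bundle
  b$natural_history <- zero_nh(b$natural_history$ages)
  b
}

occ_empty <- function() setNames(numeric(23), health_states())
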