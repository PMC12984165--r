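# Synthetic parameter generation ---------------------------------------------
#
# The national registry tables that parameterise the real evaluation are not
# redistributable, so the package ships a generator that emits complete,
# internally consistent bundles with the same structure: age-specific onset
# rising with age, ordered stage costs and utilities, registry-like
# mortality, and the three published reading-strategy profiles embedded
# verbatim.

#' Specification for a synthetic parameter bundle
#'
#' Defaults encode the reference scenario: a logistic-in-age onset curve
#' scaled to a lifetime risk near 1 in 10, mean preclinical stage dwell
#' times of 2 / 2 / 1.5 / 1.25 years, a steep clinical-detection gradient
#' (late-stage disease presents readily), Gompertz-like other-cause
#' mortality, stage treatment costs escalating from SGD 20,000 (stage 0) to
#' SGD 100,000 (stage IV) and stage utilities declining from 0.86 to 0.48.
#'
#' @param seed Integer seed controlling the registry-like jitter applied to
#'   other-cause mortality.
#' @param onset_scale Asymptotic annual onset probability.
#' @param onset_midpoint,onset_slope Logistic midpoint (age, years) and
#'   width (years) of the onset curve.
#' @param stage_dwell Mean preclinical dwell time (years) in stages 0-III
#'   before progressing one stage.
#' @param clinical_detection Annual probability an undiagnosed cancer
#'   presents symptomatically, by stage 0-IV (non-decreasing).
#' @param bc_mortality Annual breast-cancer death probability by stage 0-IV
#'   while undiagnosed or under treatment.
#' @param bc_mortality_recurrence Annual breast-cancer death probability in
#'   recurrence.
#' @param recurrence_rate Annual recurrence probability from remission, by
#'   stage at diagnosis.
#' @param oc_mortality_base,oc_mortality_growth Other-cause mortality at age
#'   50 and its exponential growth per year of age.
#' @param oc_mortality_jitter_sd Lognormal SD of the seeded jitter applied
#'   to other-cause mortality (monotonicity restored afterwards).
#' @param treatment_cost_base,treatment_cost_escalation Stage-0 treatment
#'   cost (SGD) and the multiplicative escalation factor per stage.
#' @param remission_fraction Fraction of the stage treatment cost booked per
#'   surveillance year in remission.
#' @param recurrence_cost Stage-invariant annual recurrence treatment cost.
#' @param ultrasound_cost,biopsy_cost,biopsy_fraction_of_recalls Recall
#'   work-up prices and the recall-to-biopsy fraction.
#' @param mammogram_base_cost,radiologist_read_fee,ai_fee Fee-substitution
#'   inputs for the three per-scan prices.
#' @param utility_healthy,utility_undiagnosed,utility_by_stage,utility_remission,utility_recurrence
#'   Health-state utility weights.
#' @param cost_cv,utility_sd Probabilistic-analysis dispersion: coefficient
#'   of variation for Gamma-distributed costs, absolute SD for
#'   Beta-distributed utilities.
#' @param compliance,start_age,stop_age,interval,horizon,cohort_size,discount_rate,wtp_threshold
#'   Policy and economic settings (published reference values).
#' @return A `synthetic_bundle_spec` list.
#' @export
synthetic_bundle_spec <- function(
    seed = 20230L,
    onset_scale = 0.0030, onset_midpoint = 60, onset_slope = 8,
    stage_dwell = c(2, 2, 1.5, 1.25),
    clinical_detection = c(0.05, 0.12, 0.25, 0.50, 0.80),
    bc_mortality = c(0.001, 0.005, 0.02, 0.08, 0.30),
    bc_mortality_recurrence = 0.25,
    recurrence_rate = c(0.005, 0.01, 0.03, 0.06, 0.10),
    oc_mortality_base = 0.002, oc_mortality_growth = 0.085,
    oc_mortality_jitter_sd = 0.03,
    treatment_cost_base = 20000, treatment_cost_escalation = 1.5,
    remission_fraction = 0.05, recurrence_cost = 40000,
    ultrasound_cost = 180, biopsy_cost = 800,
    biopsy_fraction_of_recalls = 0.5,
    mammogram_base_cost = 110, radiologist_read_fee = 17.5, ai_fee = 5,
    utility_healthy = 0.92, utility_undiagnosed = 0.90,
    utility_by_stage = c(0.86, 0.82, 0.75, 0.62, 0.48),
    utility_remission = 0.84, utility_recurrence = 0.60,
    cost_cv = 0.05, utility_sd = 0.05,
    compliance = 0.4, start_age = 50, stop_age = 69, interval = 2,
    horizon = 50, cohort_size = 10000,
    discount_rate = 0.03, wtp_threshold = 50000) {
  spec <- as.list(environment())
  class(spec) <- "synthetic_bundle_spec"
  spec
}

#' Generate a full parameter bundle from a synthetic specification
#'
#' Deterministic in the spec (including its seed): the same spec always
#' yields an identical bundle. The three published strategy profiles
#' (0.691/0.954, 0.715/0.968, 0.805/0.893) and every published policy value
#' are embedded as-is; only the natural-history block is synthesised.
#'
#' @param spec A [synthetic_bundle_spec()].
#' @return A validated parameter bundle of class `cea_bundle`.
#' @examples
#' bundle <- generate_bundle(synthetic_bundle_spec())
#' bundle$strategies
#' @export
generate_bundle <- function(spec = synthetic_bundle_spec()) {
  stopifnot(inherits(spec, "synthetic_bundle_spec"))
  ages <- (spec$start_age - 1L):(spec$start_age + spec$horizon)

  onset <- spec$onset_scale /
    (1 + exp(-(ages - spec$onset_midpoint) / spec$onset_slope))
  if (any(onset > 1)) {
    abort(sprintf("onset probability exceeds 1 at age %d",
                  ages[which(onset > 1)[1]]),
          class = "mammocea_generation_error")
  }

  oc <- spec$oc_mortality_base *
    exp(spec$oc_mortality_growth * (ages - spec$start_age))
  if (spec$oc_mortality_jitter_sd > 0) {
    oc <- withr::with_seed(spec$seed, {
      oc * exp(stats::rnorm(length(oc), 0, spec$oc_mortality_jitter_sd))
    })
  }
  oc <- cummax(pmin(oc, 0.9)) # registry-like: monotone in age, capped

  progression <- c(1 / spec$stage_dwell, 0)[1:5]
  progression[5] <- 0 # stage IV does not progress further
  bad <- which(progression > 1)
  if (length(bad)) {
    abort(sprintf("stage dwell time below one year gives progression > 1 at stage %s",
                  STAGE_LABELS[bad[1]]),
          class = "mammocea_generation_error")
  }

  treatment_cost <- spec$treatment_cost_base *
    spec$treatment_cost_escalation^(0:4)

  scan <- derive_scan_costs(spec$mammogram_base_cost,
                            spec$radiologist_read_fee, spec$ai_fee)
  strategies <- dplyr::bind_rows(
    strategy_profile("conventional", 0.691, 0.954, scan[["conventional"]]),
    strategy_profile("companion", 0.715, 0.968, scan[["companion"]]),
    strategy_profile("standalone", 0.805, 0.893, scan[["standalone"]])
  )

  bundle <- structure(
    list(
      schema_version = CONFIG_SCHEMA_VERSION,
      strategies = strategies,
      policy = screening_policy(
        start_age = spec$start_age, stop_age = spec$stop_age,
        interval = spec$interval, compliance = spec$compliance,
        horizon = spec$horizon, cohort_size = spec$cohort_size
      ),
      economics = economic_settings(
        discount_rate = spec$discount_rate,
        wtp_threshold = spec$wtp_threshold
      ),
      natural_history = list(
        ages = as.integer(ages),
        onset_rate = unname(onset),
        other_cause_mortality = unname(oc),
        stage_progression = unname(progression),
        clinical_detection = unname(spec$clinical_detection),
        recurrence_rate = unname(spec$recurrence_rate),
        bc_mortality = unname(spec$bc_mortality),
        bc_mortality_recurrence = spec$bc_mortality_recurrence
      ),
      costs = list(
        treatment_cost = unname(treatment_cost),
        remission_fraction = spec$remission_fraction,
        recurrence_cost = spec$recurrence_cost,
        ultrasound_cost = spec$ultrasound_cost,
        biopsy_cost = spec$biopsy_cost,
        biopsy_fraction_of_recalls = spec$biopsy_fraction_of_recalls,
        mammogram_base_cost = spec$mammogram_base_cost,
        radiologist_read_fee = spec$radiologist_read_fee,
        ai_fee = spec$ai_fee
      ),
      utilities = list(
        healthy = spec$utility_healthy,
        undiagnosed = spec$utility_undiagnosed,
        by_stage = unname(spec$utility_by_stage),
        remission = spec$utility_remission,
        recurrence = spec$utility_recurrence
      ),
      psa = list(cost_cv = spec$cost_cv, utility_sd = spec$utility_sd)
    ),
    class = "cea_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' The reference parameter bundle
#'
#' The default synthetic bundle: every published quantity (three strategy
#' sensitivity/specificity pairs, the SGD 110 / 97.50 / 80 per-scan prices
#' and the SGD 5 AI fee behind them, 3% discounting, 40% compliance,
#' SGD 50,000/QALY threshold, 10,000 women, ages 50-69 screened biennially
#' over a 50-year horizon) hard-coded, with the synthetic natural-history
#' block standing in for registry data.
#'
#' @param ... Overrides passed to [synthetic_bundle_spec()].
#' @return A validated `cea_bundle`.
#' @export
reference_bundle <- function(...) {
  generate_bundle(synthetic_bundle_spec(...))
}

# Individual-level microsimulation -------------------------------------------

#' Microsimulate individual life histories (cohort-engine oracle)
#'
#' Simulates `n` independent women with per-cycle Bernoulli events drawn in
#' exactly the composition order the cohort engine uses (other-cause death,
#' breast-cancer death, attendance and test result at screening cycles,
#' clinical presentation, progression, onset, then the treatment /
#' remission / recurrence moves keyed on the start-of-cycle state). Tallies
#' are scaled to the policy cohort size; by the law of large numbers every
#' tally converges to the cohort-expectation trace, which is how the Markov
#' engine is validated.
#'
#' @param bundle A validated parameter bundle.
#' @param strategy Strategy name or [strategy_profile()] row.
#' @param n Number of simulated women.
#' @param seed Integer seed.
#' @param compliance Optional compliance override.
#' @return List with `tallies` (scaled to cohort size), `se` (standard
#'   errors of the scaled tallies), `n`, and `final_occupancy` (scaled).
#' @export
microsimulate <- function(bundle, strategy = "conventional", n = 10000,
                          seed = 1, compliance = NULL) {
  if (is.character(strategy)) strategy <- get_strategy(bundle, strategy)
  stopifnot(n >= 1)
  policy <- bundle$policy
  nh <- bundle$natural_history
  compliance <- compliance %||% policy$compliance
  sens <- strategy$sensitivity
  spec <- strategy$specificity
  scale <- policy$cohort_size / n

  tally_names <- c("mammograms", "tp", "fp", "tn", "fn",
                   paste0("screen_detect_", STAGE_LABELS),
                   paste0("clinical_detect_", STAGE_LABELS),
                   "undiagnosed_cases", "early_stage", "late_stage",
                   "deaths_bc", "deaths_other")
  # per-person accumulators, so tally standard errors come for free
  per <- matrix(0L, n, length(tally_names), dimnames = list(NULL, tally_names))

  withr::with_seed(seed, {
    state <- rep.int(S_HEALTHY, n)

    run_cycle <- function(age, screening) {
      at <- nh_at_age(nh, age)
      s0 <- state
      alive <- s0 != S_DEADBC & s0 != S_DEADOTHER

      # 1. other-cause death
      die_oc <- alive & runif(n) < at$oc_mort
      state[die_oc] <<- S_DEADOTHER
      per[die_oc, "deaths_other"] <<- per[die_oc, "deaths_other"] + 1L
      alive <- alive & !die_oc

      # 2. breast-cancer death (undiagnosed / treatment by stage; recurrence)
      p_bc <- numeric(n)
      for (s in 1:5) {
        p_bc[s0 == S_UNDX[s] | s0 == S_DX[s]] <- nh$bc_mortality[s]
      }
      p_bc[s0 %in% S_REC] <- nh$bc_mortality_recurrence
      die_bc <- alive & runif(n) < p_bc
      state[die_bc] <<- S_DEADBC
      per[die_bc, "deaths_bc"] <<- per[die_bc, "deaths_bc"] + 1L
      alive <- alive & !die_bc

      # 3. screening: attendance, then test result
      detected <- rep.int(FALSE, n)
      if (screening && compliance > 0) {
        eligible <- alive & (s0 == S_HEALTHY | s0 %in% S_UNDX)
        attend <- eligible & runif(n) < compliance
        per[attend, "mammograms"] <<- per[attend, "mammograms"] + 1L
        h_att <- attend & s0 == S_HEALTHY
        fp <- h_att & runif(n) < (1 - spec)
        per[fp, "fp"] <<- per[fp, "fp"] + 1L
        per[h_att & !fp, "tn"] <<- per[h_att & !fp, "tn"] + 1L
        u_att <- attend & s0 %in% S_UNDX
        tp <- u_att & runif(n) < sens
        per[tp, "tp"] <<- per[tp, "tp"] + 1L
        per[u_att & !tp, "fn"] <<- per[u_att & !tp, "fn"] + 1L
        for (s in 1:5) {
          hit <- tp & s0 == S_UNDX[s]
          state[hit] <<- S_DX[s]
          col <- paste0("screen_detect_", STAGE_LABELS[s])
          per[hit, col] <<- per[hit, col] + 1L
          stage_col <- if (s %in% EARLY_STAGES) "early_stage" else "late_stage"
          per[hit, stage_col] <<- per[hit, stage_col] + 1L
        }
        detected <- tp
      }

      # 4. clinical / interval presentation
      p_clin <- numeric(n)
      for (s in 1:5) p_clin[s0 == S_UNDX[s]] <- nh$clinical_detection[s]
      clin <- alive & !detected & s0 %in% S_UNDX & runif(n) < p_clin
      for (s in 1:5) {
        hit <- clin & s0 == S_UNDX[s]
        state[hit] <<- S_DX[s]
        col <- paste0("clinical_detect_", STAGE_LABELS[s])
        per[hit, col] <<- per[hit, col] + 1L
        stage_col <- if (s %in% EARLY_STAGES) "early_stage" else "late_stage"
        per[hit, stage_col] <<- per[hit, stage_col] + 1L
      }
      detected <- detected | clin

      # 5. preclinical stage progression
      p_prog <- numeric(n)
      for (s in 1:4) p_prog[s0 == S_UNDX[s]] <- nh$stage_progression[s]
      prog <- alive & !detected & s0 %in% S_UNDX[1:4] & runif(n) < p_prog
      state[prog] <<- state[prog] + 1L

      # 6. onset
      onset <- alive & s0 == S_HEALTHY & runif(n) < at$onset
      state[onset] <<- S_UNDX[1]
      per[onset, "undiagnosed_cases"] <<- per[onset, "undiagnosed_cases"] + 1L

      # 7. treatment -> remission, remission -> recurrence, recurrence -> remission
      for (s in 1:5) {
        state[alive & s0 == S_DX[s]] <<- S_REM[s]
        rec <- alive & s0 == S_REM[s] & runif(n) < nh$recurrence_rate[s]
        state[rec] <<- S_REC[s]
        state[alive & s0 == S_REC[s]] <<- S_REM[s]
      }
      invisible(NULL)
    }

    # burn-in year (no screening), then the policy horizon
    run_cycle(policy$start_age - 1L, screening = FALSE)
    per[] <- 0L # burn-in events are not part of the modelled horizon tallies
    for (t in seq_len(policy$horizon)) {
      age <- policy$start_age + t - 1L
      run_cycle(age, screening = is_screening_age(age, policy))
    }
  })

  raw <- colSums(per)
  # scaled tally = scale * sum(per); SE = scale * sd(per) * sqrt(n)
  se <- scale * apply(per, 2, stats::sd) * sqrt(n)
  occ <- tabulate(state, nbins = N_STATES) * scale
  names(occ) <- health_states()
  list(
    tallies = raw * scale,
    se = se,
    n = n,
    final_occupancy = occ
  )
}
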