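# Cohort trace propagation ---------------------------------------------------

is_screening_age <- function(age, policy) {
  age >= policy$start_age && age <= policy$stop_age &&
    (age - policy$start_age) %% policy$interval == 0
}

#' Run the closed cohort through the Markov model
#'
#' Propagates the occupancy vector through annual cycles over the policy
#' horizon. In screening cycles (every `interval` years from `start_age`
#' while age does not exceed `stop_age`) the strategy's test
#' characteristics are applied to the compliant fraction of the
#' screen-eligible occupancy. Within each cycle events compose in the fixed
#' order: other-cause death, breast-cancer death, screen detection,
#' clinical/interval detection, progression, onset, and the treatment /
#' remission / recurrence flows. Diagnostic tallies (mammograms, TP, FP,
#' TN, FN, screen and clinical detections by stage, onsets, deaths) are
#' accrued per cycle; occupancy is conserved to within 1e-6 persons per
#' cycle or the run aborts.
#'
#' @param bundle A validated parameter bundle.
#' @param strategy Strategy name (`"conventional"`, `"companion"`,
#'   `"standalone"`) or a one-row [strategy_profile()].
#' @param initial Optional initial occupancy vector; defaults to the
#'   burn-in prevalence from [seed_prevalence()].
#' @param compliance Optional compliance override (otherwise the policy's).
#' @return A `cohort_trace` object: `occupancy` (cycles+1 x 23 matrix),
#'   `events` (per-cycle tibble), `tallies` (cumulative totals), plus the
#'   policy and strategy used.
#' @export
run_cohort <- function(bundle, strategy = "conventional", initial = NULL,
                       compliance = NULL) {
  if (is.character(strategy)) strategy <- get_strategy(bundle, strategy)
  policy <- bundle$policy
  compliance <- compliance %||% policy$compliance
  check_prob(compliance, "compliance")

  if (policy$attendance_model == "fixed" && compliance > 0 && compliance < 1) {
    # lifelong attender subgroup vs never-attenders, mixed by compliance
    tr_a <- run_cohort_core(bundle, strategy, initial, compliance = 1)
    tr_n <- run_cohort_core(bundle, strategy, initial, compliance = 0)
    return(mix_traces(tr_a, tr_n, compliance, strategy, policy))
  }
  run_cohort_core(bundle, strategy, initial, compliance)
}

run_cohort_core <- function(bundle, strategy, initial, compliance) {
  policy <- bundle$policy
  nh <- bundle$natural_history
  horizon <- policy$horizon
  states <- health_states()

  occ <- if (is.null(initial)) {
    seed_prevalence(nh, policy$cohort_size, policy$start_age - 1L)
  } else {
    if (abs(sum(initial) - policy$cohort_size) > 1e-6) {
      abort("initial occupancy must sum to cohort_size", class = "mammocea_validation_error")
    }
    setNames(as.numeric(initial), states)
  }

  occupancy <- matrix(0, horizon + 1L, N_STATES, dimnames = list(NULL, states))
  occupancy[1L, ] <- occ

  ev_names <- c("age", "screening_cycle", "mammograms", "tp", "fp", "tn", "fn",
                paste0("screen_detect_", STAGE_LABELS),
                paste0("clinical_detect_", STAGE_LABELS),
                "onsets", "deaths_bc", "deaths_other")
  events <- matrix(0, horizon, length(ev_names), dimnames = list(NULL, ev_names))

  for (t in seq_len(horizon)) {
    age <- policy$start_age + t - 1L
    at <- nh_at_age(nh, age)
    screening <- is_screening_age(age, policy)

    # survivors of this cycle's mortality, the base for detection events
    surv <- occ
    surv[S_HEALTHY] <- occ[S_HEALTHY] * (1 - at$oc_mort)
    surv[S_UNDX] <- occ[S_UNDX] * (1 - at$oc_mort) * (1 - nh$bc_mortality)

    p_screen <- 0
    sc <- NULL
    if (screening && compliance > 0) {
      sc <- classify_screen(surv, compliance, strategy)
      p_screen <- compliance * strategy$sensitivity
    }

    M <- build_transition_matrix(age, nh, p_screen)
    occ_next <- drop(occ %*% M)

    drift <- abs(sum(occ_next) - sum(occ))
    if (drift > 1e-6) {
      abort(sprintf("cohort not conserved at cycle %d (drift %.3g persons)", t, drift),
            class = "mammocea_internal_error")
    }

    events[t, "age"] <- age
    events[t, "screening_cycle"] <- as.numeric(screening)
    if (!is.null(sc)) {
      events[t, "mammograms"] <- sc$attendees
      events[t, "tp"] <- sc$tp
      events[t, "fp"] <- sc$fp
      events[t, "tn"] <- sc$tn
      events[t, "fn"] <- sc$fn
      events[t, paste0("screen_detect_", STAGE_LABELS)] <-
        as.numeric(sc[paste0("tp_stage_", STAGE_LABELS)])
    }
    clin <- surv[S_UNDX] * (1 - p_screen) * nh$clinical_detection
    events[t, paste0("clinical_detect_", STAGE_LABELS)] <- clin
    events[t, "onsets"] <- occ[S_HEALTHY] * (1 - at$oc_mort) * at$onset
    events[t, "deaths_bc"] <- occ_next[S_DEADBC] - occ[S_DEADBC]
    events[t, "deaths_other"] <- occ_next[S_DEADOTHER] - occ[S_DEADOTHER]

    occ <- occ_next
    occupancy[t + 1L, ] <- occ
  }

  new_cohort_trace(occupancy, events, strategy, policy, compliance)
}

new_cohort_trace <- function(occupancy, events, strategy, policy, compliance) {
  ev <- tibble::as_tibble(as.data.frame(events))
  ev <- dplyr::mutate(ev, cycle = dplyr::row_number() - 1L, .before = 1L)
  sd_cols <- paste0("screen_detect_", STAGE_LABELS)
  cd_cols <- paste0("clinical_detect_", STAGE_LABELS)
  detect_stage <- colSums(ev[sd_cols]) + colSums(ev[cd_cols])
  tallies <- c(
    mammograms = sum(ev$mammograms),
    tp = sum(ev$tp), fp = sum(ev$fp), tn = sum(ev$tn), fn = sum(ev$fn),
    setNames(colSums(ev[sd_cols]), sd_cols),
    setNames(colSums(ev[cd_cols]), cd_cols),
    undiagnosed_cases = sum(ev$onsets),
    early_stage = sum(detect_stage[EARLY_STAGES]),
    late_stage = sum(detect_stage[LATE_STAGES]),
    deaths_bc = sum(ev$deaths_bc),
    deaths_other = sum(ev$deaths_other)
  )
  structure(
    list(occupancy = occupancy, events = ev, tallies = tallies,
         strategy = strategy, policy = policy, compliance = compliance),
    class = "cohort_trace"
  )
}

mix_traces <- function(tr1, tr0, w, strategy, policy) {
  occupancy <- w * tr1$occupancy + (1 - w) * tr0$occupancy
  keep <- c("cycle", "age", "screening_cycle")
  ev <- tr1$events
  num <- setdiff(names(ev), keep)
  ev[num] <- w * tr1$events[num] + (1 - w) * tr0$events[num]
  events <- as.matrix(ev[setdiff(names(ev), "cycle")])
  new_cohort_trace(occupancy, events, strategy, policy, w)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> strategy '%s', %d cycles, compliance %.0f%%\n",
              x$strategy$name, nrow(x$events), 100 * x$compliance))
  cat(sprintf("  mammograms %.0f | TP %.1f FP %.1f TN %.0f FN %.1f | BC deaths %.1f\n",
              x$tallies["mammograms"], x$tallies["tp"], x$tallies["fp"],
              x$tallies["tn"], x$tallies["fn"], x$tallies["deaths_bc"]))
  invisible(x)
}

#' Tidy a cohort trace into long occupancy
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Tibble with columns `cycle`, `age`, `state`, `persons`.
#' @export
tidy.cohort_trace <- function(x, ...) {
  occ <- tibble::as_tibble(as.data.frame(x$occupancy))
  occ$cycle <- seq_len(nrow(occ)) - 1L
  occ$age <- x$policy$start_age + occ$cycle
  tidyr::pivot_longer(occ, cols = -c("cycle", "age"),
                      names_to = "state", values_to = "persons")
}

#' One-line summary of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return One-row tibble of cumulative diagnostic tallies.
#' @export
glance.cohort_trace <- function(x, ...) {
  tibble::as_tibble(as.list(x$tallies))
}
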