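#' Discount factor for a cycle index
#'
#' @param t Cycle index (years from model start, 0-based).
#' @param r Annual discount rate.
#' @return `1 / (1 + r)^t`, vectorised over `t`.
#' @examples
#' discount_factor(0:3, 0.03)
#' @export
discount_factor <- function(t, r) {
  check_nonneg(t, "t")
  check_nonneg(r, "r")
  1 / (1 + r)^t
}

state_utility_vector <- function(utilities) {
  u <- numeric(N_STATES)
  u[S_HEALTHY] <- utilities$healthy
  u[S_UNDX] <- utilities$undiagnosed
  u[S_DX] <- utilities$by_stage
  u[S_REM] <- utilities$remission
  u[S_REC] <- utilities$recurrence
  u[c(S_DEADBC, S_DEADOTHER)] <- 0
  u
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per cycle t the model books: screening cost (mammograms x per-scan
#' price), recall work-up (ultrasound for every recall, biopsy for a
#' fraction), stage-specific treatment cost for the occupancy under
#' treatment, surveillance cost for remission (a fraction of the stage
#' treatment cost per year), and the stage-invariant recurrence cost.
#' QALYs are state occupancy weighted by utilities. Both streams are
#' booked at cycle start and discounted by `1/(1+r)^t`; an optional
#' half-cycle correction averages adjacent occupancies instead.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param bundle The parameter bundle the trace was run under (costs,
#'   utilities, discount rate); the strategy's per-scan cost is taken from
#'   the trace's own strategy unless `costs_override` supplies one.
#' @param costs_override,utilities_override,cost_per_scan_override Optional
#'   replacement blocks (used by the probabilistic sensitivity analysis,
#'   which re-prices a fixed trace).
#' @return An `economic_result`: one-row tibble with `strategy`,
#'   `total_cost`, `total_qalys` and the cost breakdown
#'   (`cost_screening`, `cost_workup`, `cost_treatment`, `cost_remission`,
#'   `cost_recurrence`), all discounted.
#' @export
accumulate <- function(trace, bundle, costs_override = NULL,
                       utilities_override = NULL,
                       cost_per_scan_override = NULL) {
  costs <- costs_override %||% bundle$costs
  utilities <- utilities_override %||% bundle$utilities
  r <- bundle$economics$discount_rate
  horizon <- nrow(trace$events)
  d <- discount_factor(seq_len(horizon) - 1L, r)

  occ <- trace$occupancy[seq_len(horizon), , drop = FALSE]
  if (isTRUE(trace$policy$half_cycle)) {
    occ <- (occ + trace$occupancy[seq_len(horizon) + 1L, , drop = FALSE]) / 2
  }

  per_scan <- cost_per_scan_override %||% trace$strategy$cost_per_scan
  ev <- trace$events

  cost_screening <- sum(d * ev$mammograms * per_scan)
  cost_workup <- sum(d * workup_cost(list(tp = ev$tp, fp = ev$fp), costs))
  cost_treatment <- sum(d * (occ[, S_DX, drop = FALSE] %*% costs$treatment_cost))
  cost_remission <- sum(d * (occ[, S_REM, drop = FALSE] %*%
                               (costs$remission_fraction * costs$treatment_cost)))
  cost_recurrence <- sum(d * rowSums(occ[, S_REC, drop = FALSE]) * costs$recurrence_cost)

  u <- state_utility_vector(utilities)
  total_qalys <- sum(d * (occ %*% u))

  out <- tibble::tibble(
    strategy = trace$strategy$name,
    total_cost = cost_screening + cost_workup + cost_treatment +
      cost_remission + cost_recurrence,
    total_qalys = total_qalys,
    cost_screening = cost_screening,
    cost_workup = cost_workup,
    cost_treatment = cost_treatment,
    cost_remission = cost_remission,
    cost_recurrence = cost_recurrence
  )
  class(out) <- c("economic_result", class(out))
  out
}

#' Construct an economic result from known totals
#'
#' Wraps externally supplied discounted totals (e.g. published benchmark
#' values) in the same container [accumulate()] returns, so they can feed
#' [incremental()] directly.
#'
#' @param strategy Strategy label.
#' @param total_cost,total_qalys Discounted totals.
#' @return An `economic_result` row (breakdown columns `NA`).
#' @export
economic_result <- function(strategy, total_cost, total_qalys) {
  out <- tibble::tibble(
    strategy = strategy, total_cost = total_cost, total_qalys = total_qalys,
    cost_screening = NA_real_, cost_workup = NA_real_,
    cost_treatment = NA_real_, cost_remission = NA_real_,
    cost_recurrence = NA_real_
  )
  class(out) <- c("economic_result", class(out))
  out
}

#' Incremental comparison of two strategies
#'
#' Computes the incremental cost, incremental QALYs, the incremental
#' cost-effectiveness ratio and net monetary benefit of a candidate
#' strategy against a reference. A negative ICER arising from a cheaper,
#' more effective candidate is labelled dominant (cost-saving per QALY
#' gained) alongside the signed ratio; when the QALY difference is zero the
#' ratio is suppressed and the comparison is labelled by cost alone.
#'
#' @param reference,candidate `economic_result` rows from the same cohort
#'   and policy settings.
#' @param wtp Willingness-to-pay threshold (SGD/QALY) for the net monetary
#'   benefit.
#' @return One-row tibble of class `incremental_comparison`: `delta_cost`,
#'   `delta_qalys`, `icer`, `dominance`, `nmb`.
#' @export
incremental <- function(reference, candidate, wtp = 50000) {
  delta_cost <- candidate$total_cost - reference$total_cost
  delta_qalys <- candidate$total_qalys - reference$total_qalys
  if (delta_qalys != 0) {
    icer <- delta_cost / delta_qalys
    dominance <- if (delta_cost < 0 && delta_qalys > 0) {
      "dominant (cost-saving per QALY gained)"
    } else if (delta_cost > 0 && delta_qalys < 0) {
      "dominated"
    } else {
      NA_character_
    }
  } else {
    icer <- NA_real_
    dominance <- if (delta_cost == 0) {
      NA_character_
    } else if (delta_cost < 0) {
      "dominant by cost (equal QALYs)"
    } else {
      "dominated by cost (equal QALYs)"
    }
  }
  out <- tibble::tibble(
    reference = reference$strategy, candidate = candidate$strategy,
    delta_cost = delta_cost, delta_qalys = delta_qalys,
    icer = icer, dominance = dominance,
    nmb = wtp * delta_qalys - delta_cost
  )
  class(out) <- c("incremental_comparison", class(out))
  out
}
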