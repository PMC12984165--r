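#' Classify a screening round into TP/FP/TN/FN expectations
#'
#' Screen-eligible states are Healthy and the preclinical Undiagnosed
#' stages; women under treatment, in remission or in recurrence follow
#' annual surveillance rather than programme screening. A fraction
#' `compliance` of the eligible occupancy attends; attendees with
#' preclinical cancer split into true positives and false negatives by the
#' strategy's sensitivity, cancer-free attendees into false positives and
#' true negatives by its specificity.
#'
#' @param occupancy Named occupancy vector over the 23 health states
#'   (expected persons; fractional values allowed).
#' @param compliance Per-round attendance probability.
#' @param strategy A one-row [strategy_profile()].
#' @return A one-row tibble of class `screen_outcome` with columns
#'   `attendees`, `tp`, `fp`, `tn`, `fn` and `tp_stage_0` ... `tp_stage_IV`.
#' @examples
#' occ <- setNames(numeric(23), health_states())
#' occ["healthy"] <- 1000
#' classify_screen(occ, compliance = 1, strategy_profile("conv", 0.691, 0.954, 110))
#' @export
classify_screen <- function(occupancy, compliance, strategy) {
  check_prob(compliance, "compliance")
  if (length(occupancy) != N_STATES) {
    abort("occupancy must cover all 23 health states", class = "mammocea_validation_error")
  }
  if (any(occupancy < -1e-9)) {
    abort("occupancy must be non-negative", class = "mammocea_validation_error")
  }
  sens <- strategy$sensitivity
  spec <- strategy$specificity

  healthy_att <- compliance * unname(occupancy[S_HEALTHY])
  undx_att <- compliance * unname(occupancy[S_UNDX])

  tp_stage <- sens * undx_att
  out <- tibble::tibble(
    attendees = healthy_att + sum(undx_att),
    tp = sum(tp_stage),
    fp = (1 - spec) * healthy_att,
    tn = spec * healthy_att,
    fn = (1 - sens) * sum(undx_att)
  )
  out[paste0("tp_stage_", STAGE_LABELS)] <- as.list(unname(tp_stage))
  class(out) <- c("screen_outcome", class(out))
  out
}

#' Price the diagnostic work-up of a screening round
#'
#' Every recall (true or false positive) undergoes diagnostic ultrasound; a
#' configurable fraction of recalls additionally proceeds to biopsy. True
#' and false positives are priced identically: the recall cascade does not
#' distinguish them until pathology.
#'
#' @param outcome A `screen_outcome` row from [classify_screen()], or any
#'   list with `tp` and `fp` fields.
#' @param costs Cost block of a parameter bundle (needs `ultrasound_cost`,
#'   `biopsy_cost`, `biopsy_fraction_of_recalls`).
#' @return Total undiscounted work-up cost for the round (SGD).
#' @examples
#' workup_cost(list(tp = 4, fp = 6),
#'             list(ultrasound_cost = 150, biopsy_cost = 800,
#'                  biopsy_fraction_of_recalls = 0.5))
#' @export
workup_cost <- function(outcome, costs) {
  recalls <- outcome$tp + outcome$fp
  check_nonneg(recalls, "recalls")
  recalls * (costs$ultrasound_cost +
               costs$biopsy_fraction_of_recalls * costs$biopsy_cost)
}
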