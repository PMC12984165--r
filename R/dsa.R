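# One-way deterministic sensitivity analysis ---------------------------------

#' Parameters varied in the default tornado analysis
#'
#' Accessor paths understood by [one_way_dsa()]: strategy sensitivities and
#' specificities, per-scan costs, compliance, biopsy cost, stage-I
#' treatment cost, and the recurrence and stage-I utilities.
#'
#' @return Character vector of parameter paths.
#' @export
default_dsa_parameters <- function() {
  c("sensitivity.conventional", "sensitivity.companion", "sensitivity.standalone",
    "specificity.conventional", "specificity.companion", "specificity.standalone",
    "cost_per_scan.conventional", "cost_per_scan.companion", "cost_per_scan.standalone",
    "compliance", "biopsy_cost", "treatment_cost.I",
    "utility.recurrence", "utility.stage_I")
}

perturb_bundle <- function(bundle, param, factor) {
  clip <- function(x) pmin(pmax(x, 0), 1)
  parts <- strsplit(param, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  sub <- if (length(parts) > 1) parts[2] else NA_character_
  b <- bundle
  if (head %in% c("sensitivity", "specificity", "cost_per_scan")) {
    i <- match(sub, b$strategies$name)
    if (is.na(i)) abort(sprintf("unknown strategy '%s' in DSA parameter '%s'", sub, param),
                        class = "mammocea_validation_error")
    val <- b$strategies[[head]][i] * factor
    if (head != "cost_per_scan" && (val > 1 || val < 0)) {
      warn(sprintf("DSA: %s perturbed out of [0,1]; clipped", param))
      val <- clip(val)
    }
    b$strategies[[head]][i] <- val
  } else if (head == "compliance") {
    val <- b$policy$compliance * factor
    if (val > 1) {
      warn("DSA: compliance perturbed above 1; clipped")
      val <- 1
    }
    b$policy$compliance <- val
  } else if (head == "treatment_cost") {
    i <- match(sub, STAGE_LABELS)
    if (is.na(i)) abort(sprintf("unknown stage '%s' in '%s'", sub, param),
                        class = "mammocea_validation_error")
    b$costs$treatment_cost[i] <- b$costs$treatment_cost[i] * factor
  } else if (head == "utility") {
    if (startsWith(sub, "stage_")) {
      i <- match(sub("stage_", "", sub), STAGE_LABELS)
      val <- b$utilities$by_stage[i] * factor
      if (val > 1) { warn(sprintf("DSA: %s clipped to 1", param)); val <- 1 }
      b$utilities$by_stage[i] <- val
    } else {
      val <- b$utilities[[sub]] * factor
      if (is.null(val)) abort(sprintf("unknown utility '%s'", sub),
                              class = "mammocea_validation_error")
      if (val > 1) { warn(sprintf("DSA: %s clipped to 1", param)); val <- 1 }
      b$utilities[[sub]] <- val
    }
  } else if (head %in% names(bundle$costs)) {
    b$costs[[head]] <- b$costs[[head]] * factor
  } else {
    abort(sprintf("unknown DSA parameter '%s'", param),
          class = "mammocea_validation_error")
  }
  b
}

evaluate_icer <- function(bundle, candidate, reference = "conventional") {
  res_ref <- accumulate(run_cohort(bundle, reference), bundle)
  res_can <- accumulate(run_cohort(bundle, candidate), bundle)
  inc <- incremental(res_ref, res_can, bundle$economics$wtp_threshold)
  inc$icer
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Re-runs the full pipeline with each parameter in turn at `1 - perturbation`
#' and `1 + perturbation` times its base value (all others at base), records
#' the ICER of `candidate` versus conventional double reading at each end,
#' and sorts parameters by the width of the resulting ICER range.
#' Probabilities pushed outside [0, 1] are clipped with a warning, never
#' silently.
#'
#' @param bundle A validated parameter bundle.
#' @param candidate Strategy compared against conventional double reading.
#' @param parameters Parameter paths (see [default_dsa_parameters()]).
#' @param perturbation Relative perturbation (0.1 = +/-10%).
#' @return A `tornado_table` tibble: `parameter`, `icer_low`, `icer_high`,
#'   `width`, `base_icer`, sorted by decreasing width.
#' @export
one_way_dsa <- function(bundle, candidate = "companion",
                        parameters = default_dsa_parameters(),
                        perturbation = 0.1) {
  check_nonneg(perturbation, "perturbation")
  base_icer <- evaluate_icer(bundle, candidate)
  rows <- purrr::map_dfr(parameters, function(p) {
    icer_low <- evaluate_icer(perturb_bundle(bundle, p, 1 - perturbation), candidate)
    icer_high <- evaluate_icer(perturb_bundle(bundle, p, 1 + perturbation), candidate)
    tibble::tibble(parameter = p, icer_low = icer_low, icer_high = icer_high,
                   width = abs(icer_high - icer_low))
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$width))
  out$base_icer <- base_icer
  out$candidate <- candidate
  # base-case ICER outside the [low, high] envelope signals non-monotone
  # response; reported, not hidden
  out$base_inside <- pmin(out$icer_low, out$icer_high) - 1e-9 <= base_icer &
    base_icer <= pmax(out$icer_low, out$icer_high) + 1e-9
  class(out) <- c("tornado_table", class(out))
  out
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' @param object A `tornado_table` from [one_way_dsa()].
#' @param ... Unused.
#' @return A ggplot object: horizontal ICER ranges per parameter, widest on
#'   top, with the base-case ICER marked.
#' @export
autoplot.tornado_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      parameter = factor(.data$parameter,
                                         levels = rev(.data$parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$base_icer[1], linetype = 2) +
    ggplot2::labs(
      x = sprintf("ICER vs conventional (SGD/QALY), %s strategy",
                  object$candidate[1]),
      y = NULL,
      title = "One-way deterministic sensitivity analysis"
    ) +
    ggplot2::theme_minimal()
}
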