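#' @importFrom rlang abort warn %||%
#' @importFrom stats setNames rgamma rbeta runif
#' @importFrom utils modifyList
NULL

CONFIG_SCHEMA_VERSION <- "1.0"

STAGE_LABELS <- c("0", "I", "II", "III", "IV")
EARLY_STAGES <- 1:3 # stages 0, I, II
LATE_STAGES <- 4:5  # stages III, IV

STRATEGY_NAMES <- c("conventional", "companion", "standalone")

#' Reading-strategy test characteristics and per-scan cost
#'
#' A strategy profile couples a mammography reading strategy's sensitivity
#' and specificity with its per-scan price in 2023 SGD. The three canonical
#' profiles are conventional double reading (0.691 / 0.954 / SGD 110), the
#' AI companion reader replacing the second radiologist (0.715 / 0.968 /
#' SGD 97.50), and standalone AI interpretation (0.805 / 0.893 / SGD 80).
#'
#' @param name Strategy label.
#' @param sensitivity Probability the strategy flags a woman with
#'   preclinical cancer.
#' @param specificity Probability the strategy clears a woman without cancer.
#' @param cost_per_scan Per-scan cost in SGD.
#' @return A one-row tibble of class `strategy_profile`.
#' @examples
#' strategy_profile("conventional", 0.691, 0.954, 110)
#' @export
strategy_profile <- function(name, sensitivity, specificity, cost_per_scan) {
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  check_nonneg(cost_per_scan, "cost_per_scan")
  out <- tibble::tibble(
    name = as.character(name),
    sensitivity = as.numeric(sensitivity),
    specificity = as.numeric(specificity),
    cost_per_scan = as.numeric(cost_per_scan)
  )
  class(out) <- c("strategy_profile", class(out))
  out
}

#' Screening policy for the closed cohort
#'
#' @param start_age,stop_age Ages (years) bounding invitation to screening.
#' @param interval Years between screening rounds.
#' @param compliance Per-round attendance probability.
#' @param horizon Model horizon in years (annual cycles).
#' @param cohort_size Number of women entering at `start_age`.
#' @param attendance_model `"independent"` treats compliance as an
#'   independent per-round attendance fraction (cohort-expectation model);
#'   `"fixed"` splits the cohort into a lifelong attender subgroup of size
#'   `compliance` and never-attenders.
#' @param half_cycle Apply a half-cycle correction to state occupancy when
#'   accumulating costs and QALYs (off by default).
#' @return A validated list of class `screening_policy`.
#' @export
screening_policy <- function(start_age = 50, stop_age = 69, interval = 2,
                             compliance = 0.4, horizon = 50,
                             cohort_size = 10000,
                             attendance_model = c("independent", "fixed"),
                             half_cycle = FALSE) {
  attendance_model <- match.arg(attendance_model)
  for (nm in c("start_age", "stop_age", "interval", "horizon", "cohort_size")) {
    v <- get(nm)
    if (!is.finite(v) || abs(v - round(v)) > 1e-9) {
      abort(sprintf("screening_policy: %s must be a whole number of years/persons", nm),
            class = "mammocea_validation_error")
    }
    assign(nm, as.integer(round(v)))
  }
  if (start_age > stop_age) {
    abort("screening_policy: start_age must be <= stop_age", class = "mammocea_validation_error")
  }
  if (interval < 1) {
    abort("screening_policy: interval must be >= 1 year", class = "mammocea_validation_error")
  }
  check_prob(compliance, "compliance")
  if (horizon < stop_age - start_age) {
    abort("screening_policy: horizon must cover the screening window", class = "mammocea_validation_error")
  }
  structure(
    list(
      start_age = start_age, stop_age = stop_age, interval = interval,
      compliance = compliance, horizon = horizon, cohort_size = cohort_size,
      attendance_model = attendance_model, half_cycle = isTRUE(half_cycle)
    ),
    class = "screening_policy"
  )
}

#' Economic evaluation settings
#'
#' @param discount_rate Annual discount rate applied to both costs and QALYs.
#' @param wtp_threshold Willingness-to-pay threshold (SGD per QALY).
#' @param currency_year Calendar year of the price level.
#' @return A validated list of class `economic_settings`.
#' @export
economic_settings <- function(discount_rate = 0.03, wtp_threshold = 50000,
                              currency_year = 2023) {
  if (discount_rate < 0) {
    abort("economic_settings: discount_rate must be >= 0", class = "mammocea_validation_error")
  }
  if (wtp_threshold <= 0) {
    abort("economic_settings: wtp_threshold must be > 0", class = "mammocea_validation_error")
  }
  structure(
    list(discount_rate = discount_rate, wtp_threshold = wtp_threshold,
         currency_year = currency_year),
    class = "economic_settings"
  )
}

#' Derive per-scan costs by fee substitution
#'
#' The conventional double-read price includes image acquisition plus two
#' radiologist reads. The AI companion strategy replaces the second
#' radiologist's fee with the AI service fee; standalone AI replaces both
#' reads. Only the endpoint prices are published; the read fee is the single
#' consistent value linking them.
#'
#' @param base Conventional double-read per-scan cost (SGD).
#' @param read_fee One radiologist's interpretation fee (SGD).
#' @param ai_fee AI service fee per scan (SGD).
#' @return Named numeric vector with elements `conventional`, `companion`,
#'   `standalone`.
#' @examples
#' derive_scan_costs(110, 17.5, 5)
#' @export
derive_scan_costs <- function(base, read_fee, ai_fee) {
  check_nonneg(base, "base")
  check_nonneg(read_fee, "read_fee")
  check_nonneg(ai_fee, "ai_fee")
  if (base < 2 * read_fee) {
    abort("derive_scan_costs: interpretation fees exceed the scan price (base < 2 * read_fee)",
          class = "mammocea_validation_error")
  }
  c(
    conventional = base,
    companion = base - read_fee + ai_fee,
    standalone = base - 2 * read_fee + ai_fee
  )
}

# -- validation helpers -------------------------------------------------------

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("%s must lie in [0, 1] (got %s)", what,
                  paste(format(x), collapse = ", ")),
          class = "mammocea_validation_error")
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("%s must be finite and >= 0", what),
          class = "mammocea_validation_error")
  }
  invisible(x)
}

check_stage_vec <- function(x, what) {
  if (length(x) != 5L) {
    abort(sprintf("%s must have one entry per stage 0-IV (length 5)", what),
          class = "mammocea_schema_error")
  }
  invisible(x)
}

#' Validate a full parameter bundle
#'
#' Enforces every structural invariant: probabilities in range, three
#' canonical strategies present, ordered stage costs and utilities in the
#' reference set, monotone other-cause mortality and clinical detection,
#' and internal consistency of the fee-substitution prices.
#'
#' @param bundle A parameter bundle (see [reference_bundle()]).
#' @param strict Also check the reference-set ordering invariants
#'   (stage costs non-decreasing, stage utilities non-increasing,
#'   healthy >= remission >= recurrence). Probabilistic draws relax these.
#' @return The bundle, invisibly, if valid; otherwise an error naming the
#'   violated rule.
#' @export
validate_bundle <- function(bundle, strict = TRUE) {
  required <- c("schema_version", "strategies", "policy", "economics",
                "natural_history", "costs", "utilities")
  missing <- setdiff(required, names(bundle))
  if (length(missing)) {
    abort(sprintf("bundle is missing section(s): %s", paste(missing, collapse = ", ")),
          class = "mammocea_schema_error")
  }

  st <- bundle$strategies
  if (!all(STRATEGY_NAMES %in% st$name)) {
    abort("strategies must include conventional, companion and standalone profiles",
          class = "mammocea_schema_error")
  }
  check_prob(st$sensitivity, "strategy sensitivity")
  check_prob(st$specificity, "strategy specificity")
  check_nonneg(st$cost_per_scan, "strategy cost_per_scan")

  nh <- bundle$natural_history
  for (f in c("onset_rate", "other_cause_mortality")) {
    if (is.null(nh[[f]]) || is.null(nh$ages)) {
      abort(sprintf("natural_history missing field %s/ages", f), class = "mammocea_schema_error")
    }
    if (length(nh[[f]]) != length(nh$ages)) {
      abort(sprintf("natural_history$%s must align with natural_history$ages", f),
            class = "mammocea_schema_error")
    }
    check_prob(nh[[f]], paste0("natural_history$", f))
  }
  for (f in c("stage_progression", "clinical_detection", "recurrence_rate",
              "bc_mortality")) {
    check_stage_vec(nh[[f]], paste0("natural_history$", f))
    check_prob(nh[[f]], paste0("natural_history$", f))
  }
  check_prob(nh$bc_mortality_recurrence, "natural_history$bc_mortality_recurrence")
  if (is.unsorted(nh$clinical_detection)) {
    abort("natural_history$clinical_detection must be non-decreasing in stage",
          class = "mammocea_validation_error")
  }
  if (is.unsorted(nh$other_cause_mortality)) {
    abort("natural_history$other_cause_mortality must be non-decreasing in age",
          class = "mammocea_validation_error")
  }

  co <- bundle$costs
  check_stage_vec(co$treatment_cost, "costs$treatment_cost")
  for (f in c("treatment_cost", "recurrence_cost", "ultrasound_cost",
              "biopsy_cost", "mammogram_base_cost", "radiologist_read_fee",
              "ai_fee")) {
    check_nonneg(co[[f]], paste0("costs$", f))
  }
  check_prob(co$remission_fraction, "costs$remission_fraction")
  check_prob(co$biopsy_fraction_of_recalls, "costs$biopsy_fraction_of_recalls")
  if (length(co$recurrence_cost) != 1L) {
    abort("costs$recurrence_cost must be a single stage-invariant value",
          class = "mammocea_validation_error")
  }

  ut <- bundle$utilities
  check_stage_vec(ut$by_stage, "utilities$by_stage")
  for (f in c("healthy", "undiagnosed", "by_stage", "remission", "recurrence")) {
    check_prob(ut[[f]], paste0("utilities$", f))
  }

  if (strict) {
    if (is.unsorted(co$treatment_cost)) {
      abort("costs$treatment_cost must be non-decreasing in stage",
            class = "mammocea_validation_error")
    }
    if (is.unsorted(rev(ut$by_stage))) {
      abort("utilities$by_stage must be non-increasing in stage",
            class = "mammocea_validation_error")
    }
    if (!(ut$healthy >= ut$remission && ut$remission >= ut$recurrence)) {
      abort("utilities must satisfy healthy >= remission >= recurrence",
            class = "mammocea_validation_error")
    }
    derived <- derive_scan_costs(co$mammogram_base_cost,
                                 co$radiologist_read_fee, co$ai_fee)
    listed <- setNames(st$cost_per_scan, st$name)[STRATEGY_NAMES]
    if (max(abs(derived - listed)) > 1e-9) {
      abort("strategy cost_per_scan values are inconsistent with the fee-substitution rule",
            class = "mammocea_validation_error")
    }
  }

  if (!inherits(bundle$policy, "screening_policy")) {
    abort("policy must be a screening_policy object", class = "mammocea_schema_error")
  }
  if (!inherits(bundle$economics, "economic_settings")) {
    abort("economics must be an economic_settings object", class = "mammocea_schema_error")
  }
  # natural history must cover every modelled age (burn-in year onwards)
  needed <- (bundle$policy$start_age - 1L):(bundle$policy$start_age + bundle$policy$horizon)
  if (!all(needed %in% nh$ages)) {
    abort("natural_history age grid must cover burn-in through end of horizon",
          class = "mammocea_schema_error")
  }
  invisible(bundle)
}

#' Fetch one strategy profile from a bundle
#'
#' @param bundle A parameter bundle.
#' @param name One of `"conventional"`, `"companion"`, `"standalone"`.
#' @return A one-row `strategy_profile` tibble.
#' @export
get_strategy <- function(bundle, name) {
  name <- match.arg(name, STRATEGY_NAMES)
  row <- bundle$strategies[bundle$strategies$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("strategy '%s' not found in bundle", name),
          class = "mammocea_schema_error")
  }
  row
}

# -- configuration I/O --------------------------------------------------------

KNOWN_TOP_KEYS <- c("schema_version", "strategies", "policy", "economics",
                    "natural_history", "costs", "utilities")

#' Load a parameter bundle from a YAML configuration file
#'
#' The schema mirrors the five parameter blocks (strategies, policy,
#' economics, natural history, costs, utilities) plus a `schema_version`
#' key. Unknown top-level keys are rejected so typos cannot silently drop a
#' parameter. The loaded bundle is fully validated before it is returned.
#'
#' @param path Path to a YAML configuration.
#' @return A validated parameter bundle.
#' @seealso [save_config()], [reference_bundle()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "mammocea_schema_error")
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), KNOWN_TOP_KEYS)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "mammocea_schema_error")
  }
  missing <- setdiff(KNOWN_TOP_KEYS, names(raw))
  if (length(missing)) {
    abort(sprintf("config missing required section(s): %s",
                  paste(missing, collapse = ", ")),
          class = "mammocea_schema_error")
  }

  strategies <- purrr::map_dfr(raw$strategies, function(s) {
    need <- c("name", "sensitivity", "specificity", "cost_per_scan")
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      abort(sprintf("strategy entry missing field(s): %s", paste(miss, collapse = ", ")),
            class = "mammocea_schema_error")
    }
    strategy_profile(s$name, s$sensitivity, s$specificity, s$cost_per_scan)
  })

  pol <- raw$policy
  policy <- screening_policy(
    start_age = pol$start_age, stop_age = pol$stop_age,
    interval = pol$interval, compliance = pol$compliance,
    horizon = pol$horizon, cohort_size = pol$cohort_size,
    attendance_model = pol$attendance_model %||% "independent",
    half_cycle = pol$half_cycle %||% FALSE
  )
  eco <- raw$economics
  economics <- economic_settings(
    discount_rate = eco$discount_rate,
    wtp_threshold = eco$wtp_threshold,
    currency_year = eco$currency_year %||% 2023
  )

  nh_raw <- raw$natural_history
  nh <- list(
    ages = as.integer(nh_raw$ages),
    onset_rate = as.numeric(nh_raw$onset_rate),
    other_cause_mortality = as.numeric(nh_raw$other_cause_mortality),
    stage_progression = as.numeric(nh_raw$stage_progression),
    clinical_detection = as.numeric(nh_raw$clinical_detection),
    recurrence_rate = as.numeric(nh_raw$recurrence_rate),
    bc_mortality = as.numeric(nh_raw$bc_mortality),
    bc_mortality_recurrence = as.numeric(nh_raw$bc_mortality_recurrence)
  )

  bundle <- structure(
    list(
      schema_version = as.character(raw$schema_version),
      strategies = strategies,
      policy = policy,
      economics = economics,
      natural_history = nh,
      costs = lapply(raw$costs, as.numeric),
      utilities = lapply(raw$utilities, as.numeric)
    ),
    class = "cea_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Save a parameter bundle to a YAML configuration file
#'
#' @param bundle A validated parameter bundle.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(bundle, path) {
  validate_bundle(bundle)
  pol <- unclass(bundle$policy)
  out <- list(
    schema_version = bundle$schema_version,
    strategies = purrr::pmap(bundle$strategies, function(name, sensitivity,
                                                         specificity, cost_per_scan) {
      list(name = name, sensitivity = sensitivity, specificity = specificity,
           cost_per_scan = cost_per_scan)
    }),
    policy = pol,
    economics = unclass(bundle$economics),
    natural_history = lapply(bundle$natural_history, function(x) unname(as.numeric(x))),
    costs = lapply(bundle$costs, unname),
    utilities = lapply(bundle$utilities, unname)
  )
  out$natural_history$ages <- as.integer(out$natural_history$ages)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @export
print.cea_bundle <- function(x, ...) {
  cat("<cea_bundle> schema", x$schema_version, "\n")
  cat(sprintf("  cohort: %d women, ages %d-%d screened every %d y, compliance %.0f%%\n",
              x$policy$cohort_size, x$policy$start_age, x$policy$stop_age,
              x$policy$interval, 100 * x$policy$compliance))
  cat(sprintf("  horizon %d y, discount %.1f%%, WTP SGD %s/QALY\n",
              x$policy$horizon, 100 * x$economics$discount_rate,
              format(x$economics$wtp_threshold, big.mark = ",")))
  print(x$strategies)
  invisible(x)
}
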