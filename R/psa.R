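# Probabilistic sensitivity analysis and CEAC --------------------------------

#' Method-of-moments Beta parameters
#'
#' For mean `m` and standard deviation `s`:
#' `nu = m(1-m)/s^2 - 1`, `alpha = m nu`, `beta = (1-m) nu`.
#'
#' @param m Mean in (0, 1).
#' @param s Standard deviation; must satisfy `s^2 < m(1-m)`.
#' @return List with `alpha` and `beta`.
#' @examples
#' beta_moments(0.5, 0.05) # alpha = beta = 49.5
#' @export
beta_moments <- function(m, s) {
  if (s^2 >= m * (1 - m)) {
    abort(sprintf("Beta moment condition violated: s^2 = %.4g >= m(1-m) = %.4g (mean %.3f)",
                  s^2, m * (1 - m), m),
          class = "mammocea_validation_error")
  }
  nu <- m * (1 - m) / s^2 - 1
  list(alpha = m * nu, beta = (1 - m) * nu)
}

#' Method-of-moments Gamma parameters
#'
#' For mean `m` and standard deviation `s`: `shape = (m/s)^2`,
#' `scale = s^2/m`.
#'
#' @param m Mean (> 0).
#' @param s Standard deviation (> 0).
#' @return List with `shape` and `scale`.
#' @examples
#' gamma_moments(110, 5.5) # shape 400, scale 0.275
#' @export
gamma_moments <- function(m, s) {
  check_nonneg(m, "gamma mean")
  list(shape = (m / s)^2, scale = s^2 / m)
}

draw_gamma <- function(m, cv) {
  if (m == 0 || cv == 0) return(m) # degenerate point mass
  g <- gamma_moments(m, cv * m)
  rgamma(1L, shape = g$shape, scale = g$scale)
}

draw_beta <- function(m, s, what) {
  if (s == 0) return(m)
  if (m == 0 || m == 1) {
    abort(sprintf("utility '%s' has mean %g: Beta sampling is degenerate", what, m),
          class = "mammocea_validation_error")
  }
  b <- tryCatch(beta_moments(m, s),
                error = function(e) abort(
                  sprintf("utility '%s': %s", what, conditionMessage(e)),
                  class = "mammocea_validation_error"))
  rbeta(1L, b$alpha, b$beta)
}

#' Draw one probabilistic parameter set
#'
#' Costs are drawn from Gamma distributions with mean equal to the base
#' value and coefficient of variation `cost_cv`; utilities from Beta
#' distributions with mean equal to the base value and absolute standard
#' deviation `utility_sd`. Shapes come from method of moments
#' ([beta_moments()], [gamma_moments()]). Structural parameters — test
#' sensitivities and specificities, compliance, discount rate — are held
#' fixed. Call inside an established RNG state (see [run_psa()]).
#'
#' @param bundle A validated parameter bundle.
#' @param cost_cv Coefficient of variation for cost parameters (default
#'   from the bundle's `psa` block, else 0.05).
#' @param utility_sd Absolute SD for utility parameters (default likewise
#'   0.05).
#' @return A bundle with perturbed `costs`, `utilities` and per-scan costs;
#'   validated with ordering checks relaxed.
#' @export
sample_psa_draw <- function(bundle, cost_cv = NULL, utility_sd = NULL) {
  cost_cv <- cost_cv %||% bundle$psa$cost_cv %||% 0.05
  utility_sd <- utility_sd %||% bundle$psa$utility_sd %||% 0.05
  b <- bundle
  b$costs$treatment_cost <- vapply(bundle$costs$treatment_cost,
                                   draw_gamma, numeric(1), cv = cost_cv)
  for (f in c("recurrence_cost", "ultrasound_cost", "biopsy_cost")) {
    b$costs[[f]] <- draw_gamma(bundle$costs[[f]], cost_cv)
  }
  b$strategies$cost_per_scan <- vapply(bundle$strategies$cost_per_scan,
                                       draw_gamma, numeric(1), cv = cost_cv)

  b$utilities$healthy <- draw_beta(bundle$utilities$healthy, utility_sd, "healthy")
  b$utilities$undiagnosed <- draw_beta(bundle$utilities$undiagnosed, utility_sd, "undiagnosed")
  b$utilities$by_stage <- vapply(seq_along(bundle$utilities$by_stage), function(i) {
    draw_beta(bundle$utilities$by_stage[i], utility_sd,
              paste0("stage_", STAGE_LABELS[i]))
  }, numeric(1))
  b$utilities$remission <- draw_beta(bundle$utilities$remission, utility_sd, "remission")
  b$utilities$recurrence <- draw_beta(bundle$utilities$recurrence, utility_sd, "recurrence")
  validate_bundle(b, strict = FALSE)
  b
}

#' Probabilistic sensitivity analysis with CEAC construction
#'
#' Draws `n_draws` joint parameter sets ([sample_psa_draw()]); within each
#' draw all three strategies are evaluated on the same perturbed parameters
#' (common random numbers). Because the sampled quantities are prices and
#' utilities — which do not enter the transition dynamics — each strategy's
#' cohort trace is computed once and re-priced per draw through the same
#' [accumulate()] path used everywhere else. At every willingness-to-pay
#' value on the grid the strategy with the highest net monetary benefit is
#' counted (ties to the first in strategy order); probabilities are counts
#' over draws. Fully reproducible from `seed` via per-draw child seeds.
#'
#' @param bundle A validated parameter bundle.
#' @param n_draws Number of Monte Carlo draws.
#' @param wtp_grid Ascending willingness-to-pay grid (SGD/QALY); default
#'   0-100,000 in 2,500 steps.
#' @param seed Root integer seed.
#' @param compliance Optional compliance override (scenario label).
#' @return A `ceac_surface` object: `ceac` (long tibble: `compliance`,
#'   `strategy`, `wtp`, `probability`), `draws` (per-draw discounted cost
#'   and QALYs per strategy), `n_draws`, `seed`, `n_rejected`.
#' @export
run_psa <- function(bundle, n_draws = 1000,
                    wtp_grid = seq(0, 100000, by = 2500),
                    seed = 1, compliance = NULL) {
  stopifnot(n_draws >= 1)
  if (length(wtp_grid) == 0 || is.unsorted(wtp_grid, strictly = TRUE)) {
    abort("wtp_grid must be non-empty and strictly ascending",
          class = "mammocea_validation_error")
  }
  compliance <- compliance %||% bundle$policy$compliance

  traces <- lapply(STRATEGY_NAMES, function(s)
    run_cohort(bundle, s, compliance = compliance))
  names(traces) <- STRATEGY_NAMES

  draw_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max, n_draws))

  wins <- matrix(0L, length(wtp_grid), 3L,
                 dimnames = list(NULL, STRATEGY_NAMES))
  draws <- vector("list", n_draws)
  rejected <- integer(0)

  for (i in seq_len(n_draws)) {
    db <- withr::with_seed(draw_seeds[i], sample_psa_draw(bundle))
    res <- purrr::map_dfr(STRATEGY_NAMES, function(s) {
      accumulate(traces[[s]], db,
                 cost_per_scan_override =
                   db$strategies$cost_per_scan[db$strategies$name == s])
    })
    if (any(!is.finite(res$total_cost)) || any(!is.finite(res$total_qalys))) {
      rejected <- c(rejected, i)
      next
    }
    draws[[i]] <- tibble::tibble(draw = i, strategy = res$strategy,
                                 cost = res$total_cost, qalys = res$total_qalys)
    # NMB = wtp * Q - C per strategy; count the argmax at each grid point
    nmb <- outer(wtp_grid, res$total_qalys) -
      matrix(res$total_cost, length(wtp_grid), 3L, byrow = TRUE)
    best <- max.col(nmb, ties.method = "first")
    idx <- cbind(seq_along(wtp_grid), best)
    wins[idx] <- wins[idx] + 1L
  }

  if (length(rejected) > 0.01 * n_draws) {
    abort(sprintf("PSA aborted: %d of %d draws rejected (non-finite results)",
                  length(rejected), n_draws),
          class = "mammocea_internal_error")
  }
  if (length(rejected)) {
    warn(sprintf("PSA: rejected draw(s) %s", paste(rejected, collapse = ", ")))
  }

  n_valid <- n_draws - length(rejected)
  ceac <- tibble::as_tibble(as.data.frame(wins / n_valid))
  ceac$wtp <- wtp_grid
  ceac <- tidyr::pivot_longer(ceac, cols = dplyr::all_of(STRATEGY_NAMES),
                              names_to = "strategy", values_to = "probability")
  ceac$compliance <- compliance
  ceac <- ceac[, c("compliance", "strategy", "wtp", "probability")]

  structure(
    list(ceac = ceac, draws = dplyr::bind_rows(draws),
         n_draws = n_valid, seed = seed, n_rejected = length(rejected)),
    class = "ceac_surface"
  )
}

#' CEAC surfaces across compliance scenarios
#'
#' Runs [run_psa()] at each compliance level (default the 20% / 40% / 80%
#' scenarios) and binds the acceptability curves.
#'
#' @param bundle A validated parameter bundle.
#' @param compliance_levels Attendance scenarios.
#' @inheritParams run_psa
#' @return A `ceac_surface` whose `ceac` tibble spans all scenarios.
#' @export
run_psa_scenarios <- function(bundle, compliance_levels = c(0.2, 0.4, 0.8),
                              n_draws = 1000,
                              wtp_grid = seq(0, 100000, by = 2500), seed = 1) {
  runs <- lapply(compliance_levels, function(cp)
    run_psa(bundle, n_draws = n_draws, wtp_grid = wtp_grid, seed = seed,
            compliance = cp))
  structure(
    list(ceac = dplyr::bind_rows(lapply(runs, `[[`, "ceac")),
         draws = dplyr::bind_rows(lapply(seq_along(runs), function(i) {
           d <- runs[[i]]$draws
           d$compliance <- compliance_levels[i]
           d
         })),
         n_draws = runs[[1]]$n_draws, seed = seed,
         n_rejected = sum(vapply(runs, `[[`, integer(1), "n_rejected"))),
    class = "ceac_surface"
  )
}

#' @export
print.ceac_surface <- function(x, ...) {
  cat(sprintf("<ceac_surface> %d draws, seed %d, %d WTP point(s), scenario(s): %s\n",
              x$n_draws, x$seed, length(unique(x$ceac$wtp)),
              paste(unique(x$ceac$compliance), collapse = ", ")))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' @param object A `ceac_surface` from [run_psa()] or [run_psa_scenarios()].
#' @param ... Unused.
#' @return A ggplot object: probability cost-effective against
#'   willingness-to-pay, one line per strategy, facetted by compliance
#'   scenario.
#' @export
autoplot.ceac_surface <- function(object, ...) {
  df <- object$ceac
  df$scenario <- sprintf("%.0f%% compliance", 100 * df$compliance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                   colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Willingness to pay (SGD per QALY)",
                  y = "Probability cost-effective",
                  colour = "Strategy",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}
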