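# Scenario runner and tabular reporting --------------------------------------

#' Run all strategies through the full pipeline
#'
#' For each requested strategy: cohort trace, discounted economics, and the
#' incremental comparison against conventional double reading at the
#' bundle's willingness-to-pay threshold.
#'
#' @param bundle A validated parameter bundle.
#' @param strategies Strategy names to evaluate.
#' @param compliance Optional compliance override.
#' @return A `cea_results` object: `traces`, `economics` (tibble),
#'   `incremental` (tibble vs conventional), `bundle`.
#' @examples
#' \donttest{
#' res <- run_scenario(reference_bundle())
#' outcomes_table(res)
#' }
#' @export
run_scenario <- function(bundle, strategies = STRATEGY_NAMES,
                         compliance = NULL) {
  validate_bundle(bundle)
  traces <- lapply(strategies, function(s)
    run_cohort(bundle, s, compliance = compliance))
  names(traces) <- strategies
  econ <- purrr::map_dfr(traces, accumulate, bundle = bundle)
  inc <- NULL
  if ("conventional" %in% strategies) {
    ref <- econ[econ$strategy == "conventional", ]
    inc <- purrr::map_dfr(setdiff(strategies, "conventional"), function(s) {
      incremental(ref, econ[econ$strategy == s, ],
                  bundle$economics$wtp_threshold)
    })
  }
  structure(list(traces = traces, economics = econ, incremental = inc,
                 bundle = bundle, compliance = compliance %||% bundle$policy$compliance),
            class = "cea_results")
}

#' Cumulative-outcomes table (one metric per row, one strategy per column)
#'
#' The standard result surface: total mammograms, the TP/TN/FP/FN split,
#' cumulative undiagnosed (onset) cases, early- and late-stage diagnoses,
#' discounted total cost and QALYs, and the ICER versus conventional
#' double reading.
#'
#' @param results A `cea_results` from [run_scenario()].
#' @param digits Round money to this many decimals (`NULL` = full
#'   precision; QALYs are rounded to one decimal when `digits` is set).
#' @return A tibble, `metric` column plus one column per strategy.
#' @export
outcomes_table <- function(results, digits = NULL) {
  stopifnot(inherits(results, "cea_results"))
  cols <- lapply(names(results$traces), function(s) {
    tal <- results$traces[[s]]$tallies
    eco <- results$economics[results$economics$strategy == s, ]
    icer <- NA_real_
    if (!is.null(results$incremental) && s %in% results$incremental$candidate) {
      icer <- results$incremental$icer[results$incremental$candidate == s]
    }
    vals <- c(
      total_mammograms = unname(tal["mammograms"]),
      true_positives = unname(tal["tp"]),
      true_negatives = unname(tal["tn"]),
      false_positives = unname(tal["fp"]),
      false_negatives = unname(tal["fn"]),
      undiagnosed_cancer_cases = unname(tal["undiagnosed_cases"]),
      early_stage_cancer = unname(tal["early_stage"]),
      late_stage_cancer = unname(tal["late_stage"]),
      total_cost = eco$total_cost,
      total_qalys = eco$total_qalys,
      icer_vs_conventional = icer
    )
    if (!is.null(digits)) {
      vals["total_cost"] <- round(vals["total_cost"], digits)
      vals["icer_vs_conventional"] <- round(vals["icer_vs_conventional"], digits)
      vals["total_qalys"] <- round(vals["total_qalys"], 1)
    }
    vals
  })
  out <- tibble::tibble(metric = names(cols[[1]]))
  for (i in seq_along(cols)) out[[names(results$traces)[i]]] <- unname(cols[[i]])
  out
}

#' @export
print.cea_results <- function(x, ...) {
  cat(sprintf("<cea_results> %d strategies, compliance %.0f%%\n",
              length(x$traces), 100 * x$compliance))
  print(outcomes_table(x, digits = 2), n = 11)
  invisible(x)
}

#' Tidy per-strategy economics
#'
#' @param x A `cea_results`.
#' @param ... Unused.
#' @return The economics tibble (one row per strategy with cost breakdown).
#' @export
tidy.cea_results <- function(x, ...) x$economics

#' Incremental summary of a scenario run
#'
#' @param x A `cea_results`.
#' @param ... Unused.
#' @return The incremental-comparison tibble versus conventional reading.
#' @export
glance.cea_results <- function(x, ...) x$incremental

# -- manifest and file output -------------------------------------------------

#' Build a run manifest
#'
#' Captures everything needed to re-derive an output file: a hash of the
#' full parameter bundle, the seed, schema version, scenario labels and a
#' timestamp. Two runs with equal manifests (timestamp aside) produce
#' byte-identical tables.
#'
#' @param bundle The parameter bundle used.
#' @param seed Seed used for any stochastic component (`NA` if none).
#' @param scenario Free-text scenario label(s).
#' @return A named list.
#' @export
run_manifest <- function(bundle, seed = NA_integer_, scenario = "base") {
  list(
    schema_version = bundle$schema_version,
    config_hash = rlang::hash(bundle),
    seed = seed,
    scenario = scenario,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Write scenario outputs to disk
#'
#' Emits the outcomes table (money rounded to 2 d.p., QALYs to 1 d.p.), the
#' incremental block, a full-precision machine-readable JSON companion, and
#' the run manifest.
#'
#' @param results A `cea_results`.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(results, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- run_manifest(results$bundle, seed,
                           sprintf("compliance_%g", results$compliance))
  paths <- c(
    outcomes = file.path(dir, "outcomes.csv"),
    incremental = file.path(dir, "incremental.csv"),
    full = file.path(dir, "outcomes_full.json"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_csv(outcomes_table(results, digits = 2), paths["outcomes"])
  if (!is.null(results$incremental)) {
    readr::write_csv(results$incremental, paths["incremental"])
  }
  jsonlite::write_json(
    list(manifest = manifest,
         outcomes = outcomes_table(results),
         economics = results$economics,
         incremental = results$incremental),
    paths["full"], auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE)
  invisible(paths)
}

#' Write tornado and CEAC tables
#'
#' @param tornado A `tornado_table` from [one_way_dsa()] (or `NULL`).
#' @param ceac A `ceac_surface` from [run_psa_scenarios()] (or `NULL`).
#' @param dir Output directory.
#' @param bundle Bundle for the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_uncertainty_outputs <- function(tornado = NULL, ceac = NULL, dir,
                                      bundle, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (!is.null(tornado)) {
    p <- file.path(dir, "tornado.csv")
    readr::write_csv(tornado, p)
    paths <- c(paths, tornado = p)
  }
  if (!is.null(ceac)) {
    p <- file.path(dir, "ceac.csv")
    readr::write_csv(ceac$ceac, p)
    paths <- c(paths, ceac = p)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(run_manifest(bundle, seed, "uncertainty"), mp,
                       auto_unbox = TRUE)
  invisible(c(paths, manifest = mp))
}
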