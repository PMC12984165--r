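# State space ----------------------------------------------------------------
#
# 23 states: Healthy; Undx(s), Dx(s), Rem(s), Rec(s) for stages 0-IV;
# DeadBC; DeadOther. Dx(s) is the one-cycle treatment state (curative-intent
# treatment, then remission); Rec(s) is one cycle of recurrence treatment
# returning to Remission(s). Recurrence carries a single stage-invariant
# cost and utility, so the stage index only preserves the return path.

S_HEALTHY <- 1L
S_UNDX <- 2:6
S_DX <- 7:11
S_REM <- 12:16
S_REC <- 17:21
S_DEADBC <- 22L
S_DEADOTHER <- 23L
N_STATES <- 23L

#' Names of the Markov health states
#'
#' @return Character vector of the 23 state labels in model order.
#' @export
health_states <- function() {
  c("healthy",
    paste0("undx_", STAGE_LABELS),
    paste0("dx_", STAGE_LABELS),
    paste0("rem_", STAGE_LABELS),
    paste0("rec_", STAGE_LABELS),
    "dead_bc", "dead_other")
}

nh_at_age <- function(nh, age) {
  i <- match(age, nh$ages)
  if (is.na(i)) {
    abort(sprintf("natural history has no entry for age %s", age),
          class = "mammocea_validation_error")
  }
  list(onset = nh$onset_rate[i], oc_mort = nh$other_cause_mortality[i])
}

#' Build the one-cycle transition matrix at a given age
#'
#' Composes, in a fixed order of conditional (competing-risk) events:
#' other-cause death, breast-cancer death by stage, screening detection (if
#' `p_screen > 0`), clinical/interval detection, preclinical stage
#' progression, onset, treatment-to-remission, remission-to-recurrence and
#' recurrence-to-remission flows. Each later event is conditioned on the
#' earlier events not occurring, so every row is a valid probability vector
#' by construction.
#'
#' @param age Age in years; must be on the natural-history age grid.
#' @param nh A `natural_history` parameter block (see [reference_bundle()]).
#' @param p_screen Per-cycle probability that a living woman with
#'   preclinical cancer is screen-detected this cycle
#'   (compliance x sensitivity in screening cycles; 0 otherwise).
#' @return A 23 x 23 row-stochastic matrix with state dimnames.
#' @export
build_transition_matrix <- function(age, nh, p_screen = 0) {
  check_prob(p_screen, "p_screen")
  at <- nh_at_age(nh, age)
  p_oc <- at$oc_mort
  p_onset <- at$onset
  p_bc <- nh$bc_mortality
  p_clin <- nh$clinical_detection
  p_prog <- nh$stage_progression
  p_rec <- nh$recurrence_rate
  p_bc_rec <- nh$bc_mortality_recurrence

  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(health_states(), health_states()))

  # Healthy: other-cause death, then onset into preclinical stage 0
  M[S_HEALTHY, S_DEADOTHER] <- p_oc
  M[S_HEALTHY, S_UNDX[1]] <- (1 - p_oc) * p_onset
  M[S_HEALTHY, S_HEALTHY] <- (1 - p_oc) * (1 - p_onset)

  for (s in 1:5) {
    # Undiagnosed: deaths, screen detection, clinical presentation, progression
    alive <- (1 - p_oc) * (1 - p_bc[s])
    det <- p_screen + (1 - p_screen) * p_clin[s]
    M[S_UNDX[s], S_DEADOTHER] <- p_oc
    M[S_UNDX[s], S_DEADBC] <- (1 - p_oc) * p_bc[s]
    M[S_UNDX[s], S_DX[s]] <- alive * det
    if (s < 5) {
      M[S_UNDX[s], S_UNDX[s + 1]] <- alive * (1 - det) * p_prog[s]
      M[S_UNDX[s], S_UNDX[s]] <- alive * (1 - det) * (1 - p_prog[s])
    } else {
      M[S_UNDX[s], S_UNDX[s]] <- alive * (1 - det)
    }

    # Diagnosed: one cycle of treatment, survivors enter remission
    M[S_DX[s], S_DEADOTHER] <- p_oc
    M[S_DX[s], S_DEADBC] <- (1 - p_oc) * p_bc[s]
    M[S_DX[s], S_REM[s]] <- (1 - p_oc) * (1 - p_bc[s])

    # Remission: surveillance; recurrence hazard by stage at diagnosis
    M[S_REM[s], S_DEADOTHER] <- p_oc
    M[S_REM[s], S_REC[s]] <- (1 - p_oc) * p_rec[s]
    M[S_REM[s], S_REM[s]] <- (1 - p_oc) * (1 - p_rec[s])

    # Recurrence: one cycle of treatment; survivors return to remission
    M[S_REC[s], S_DEADOTHER] <- p_oc
    M[S_REC[s], S_DEADBC] <- (1 - p_oc) * p_bc_rec
    M[S_REC[s], S_REM[s]] <- (1 - p_oc) * (1 - p_bc_rec)
  }

  M[S_DEADBC, S_DEADBC] <- 1
  M[S_DEADOTHER, S_DEADOTHER] <- 1

  bad <- abs(rowSums(M) - 1) > 1e-9
  if (any(bad)) {
    abort(sprintf("transition rows do not sum to 1 at age %s: %s", age,
                  paste(health_states()[bad], collapse = ", ")),
          class = "mammocea_internal_error")
  }
  M
}

#' Seed baseline prevalence by a one-year burn-in at age 49
#'
#' The cohort enters the model free of disease one year before screening
#' begins. One pre-screening cycle (onset, progression, clinical detection
#' and mortality, no screening) generates the preclinical prevalence present
#' at the first invitation; the returned occupancy is the model's t = 0.
#'
#' @param nh Natural-history parameter block.
#' @param cohort_size Number of women in the closed cohort.
#' @param burnin_age Age at which the burn-in cycle runs.
#' @return Named numeric occupancy vector over the 23 states.
#' @export
seed_prevalence <- function(nh, cohort_size = 10000, burnin_age = 49) {
  v0 <- setNames(numeric(N_STATES), health_states())
  v0[S_HEALTHY] <- cohort_size
  M <- build_transition_matrix(burnin_age, nh, p_screen = 0)
  drop(v0 %*% M)
}
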