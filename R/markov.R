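#' Build the one-cycle transition matrix
#'
#' Composes the annual transition probabilities into a row-stochastic
#' matrix over the expanded (tunnel-augmented) state space. The hazard
#' structure assigns each living state a single dominant death risk:
#'
#' * non-cancer states (normal, adenoma, advanced adenoma and the
#'   surveillance tunnels) die from other causes at the crude rate;
#'   disease transitions and tunnel advances apply to the survivors and
#'   the residual mass self-loops;
#' * post-treatment CRC follow-up states die from CRC at the
#'   stage-specific annual mortality (the annualised registry 5-year
#'   survival) and otherwise remain in follow-up;
#' * undiagnosed CRC states progress to the next stage or are
#'   symptomatically diagnosed (moving to the stage's follow-up state);
#'   they carry no death risk of their own -- diagnosis is their only
#'   exit route, and undiagnosed stage IV is diagnosed with certainty.
#'
#' The two death states are absorbing. With
#' `model$post_treatment_progression = FALSE` (the default) the
#' normal-to-adenoma transition is dropped, so members returning to
#' normal after surveillance do not re-enter the adenoma-carcinoma
#' sequence; see the methods vignette for why this is the base case.
#'
#' @param config A `crc_config`.
#' @param arm `"screening"` or `"no_screening"`. The matrix is shared by
#'   both arms (the strategies differ only in their initial
#'   distribution); the argument is accepted for interface symmetry.
#' @return A row-stochastic matrix with expanded-state dimnames and a
#'   `states` attribute holding the [expand_state_space()] table.
#' @examples
#' M <- build_transition_matrix(crc_config())
#' all(abs(rowSums(M) - 1) < 1e-12)
#' @export
build_transition_matrix <- function(config, arm = c("screening",
                                                    "no_screening")) {
  stopifnot(inherits(config, "crc_config"))
  arm <- match.arg(arm)
  ss <- expand_state_space(config)
  states <- ss$state
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  q <- config$model$other_cause_mortality
  tr <- config$transitions
  m_fu <- tr$crc_followup_mortality
  p_na <- if (isTRUE(config$model$post_treatment_progression))
    tr$normal_to_adenoma else 0
  tun <- config$model$tunnel_years

  progression <- list(
    normal = list(adenoma = p_na),
    adenoma = list(advanced_adenoma = tr$adenoma_to_advanced),
    advanced_adenoma = list(crc1_undiag = tr$advanced_to_crc1)
  )
  # expanded name of the first tunnel year (or the plain state when
  # tunnel_years is 0, in which case "follow-up" is instantaneous)
  first_tunnel <- function(parent) {
    if (tun > 0L) paste0(parent, "_y1") else "normal"
  }

  for (i in seq_len(n)) {
    s <- states[i]
    concept <- ss$conceptual[i]
    if (ss$absorbing[i]) {
      M[i, s] <- 1
    } else if (concept %in% paste0(crc_stages(), "_followup")) {
      stage <- sub("_followup$", "", concept)
      m <- m_fu[[stage]]
      M[i, "death_crc"] <- m
      M[i, s] <- 1 - m
    } else if (concept %in% paste0(crc_stages(), "_undiag")) {
      stage <- sub("_undiag$", "", concept)
      k <- as.integer(sub("crc", "", stage))
      p_diag <- tr[[paste0(stage, "_diagnosis")]]
      p_prog <- if (k < 4L) tr[[paste0(stage, "_to_crc", k + 1L)]] else 0
      M[i, paste0(stage, "_followup")] <- p_diag
      if (p_prog > 0) M[i, paste0("crc", k + 1L, "_undiag")] <- p_prog
      M[i, s] <- M[i, s] + 1 - p_diag - p_prog
    } else if (!is.na(ss$tunnel_year[i])) {
      M[i, "death_other"] <- q
      yr <- ss$tunnel_year[i]
      dest <- if (yr == tun) "normal" else paste0(concept, "_y", yr + 1L)
      M[i, dest] <- M[i, dest] + 1 - q
    } else {
      M[i, "death_other"] <- q
      dests <- progression[[concept]]
      out <- 0
      for (d in names(dests)) {
        p <- dests[[d]]
        target <- if (d %in% c("adenoma_followup", "advanced_adenoma_followup"))
          first_tunnel(d) else d
        M[i, target] <- M[i, target] + (1 - q) * p
        out <- out + p
      }
      M[i, s] <- M[i, s] + (1 - q) * (1 - out)
    }
  }
  bad <- abs(rowSums(M) - 1) > 1e-12
  if (any(bad)) {
    rlang::abort(paste0("transition rows do not sum to 1: ",
                        paste(states[bad], collapse = ", ")))
  }
  if (any(M < 0) || any(M > 1)) {
    rlang::abort("transition probabilities out of [0, 1]")
  }
  attr(M, "states") <- ss
  M
}

# initial occupancy over expanded states for one arm: the screening arm
# starts its six diagnosed fractions in the treated/follow-up states, the
# no-screening arm in the untreated/undiagnosed counterparts
initial_occupancy <- function(config, arm, states) {
  v <- stats::setNames(numeric(nrow(states)), states$state)
  fr <- config$initial
  tun <- config$model$tunnel_years
  if (arm == "screening") {
    ad_state <- if (tun > 0L) "adenoma_followup_y1" else "normal"
    aa_state <- if (tun > 0L) "advanced_adenoma_followup_y1" else "normal"
    v[ad_state] <- v[ad_state] + fr$adenoma
    v[aa_state] <- v[aa_state] + fr$advanced_adenoma
    for (stage in crc_stages())
      v[paste0(stage, "_followup")] <- fr[[stage]]
  } else {
    v["adenoma"] <- fr$adenoma
    v["advanced_adenoma"] <- fr$advanced_adenoma
    for (stage in crc_stages())
      v[paste0(stage, "_undiag")] <- fr[[stage]]
  }
  v
}

#' Run the cohort simulation for one strategy arm
#'
#' Applies the one-cycle transition matrix repeatedly to the arm's
#' initial distribution, tracking the full occupancy trajectory and the
#' per-cycle inter-state flows (used to attach one-time treatment costs
#' to symptomatic diagnoses).
#'
#' @param config A `crc_config`.
#' @param arm `"screening"` or `"no_screening"`.
#' @return A `crc_trajectory`: a list with `occupancy`
#'   ((horizon+1) x n-states matrix of cohort fractions, cycle 0 first),
#'   `flows` (horizon x n x n array; `flows[t, i, j]` is the fraction
#'   moving i to j during cycle t), `arm`, `states` and the `config`.
#' @examples
#' traj <- run_cohort(crc_config(), "screening")
#' range(rowSums(traj$occupancy))  # conservation at every cycle
#' @export
run_cohort <- function(config, arm = c("screening", "no_screening")) {
  arm <- match.arg(arm)
  M <- build_transition_matrix(config, arm)
  ss <- attr(M, "states")
  n <- nrow(ss)
  horizon <- config$model$horizon_cycles
  occ <- matrix(0, horizon + 1L, n, dimnames = list(0:horizon, ss$state))
  occ[1L, ] <- initial_occupancy(config, arm, ss)
  flows <- array(0, dim = c(horizon, n, n),
                 dimnames = list(seq_len(horizon), ss$state, ss$state))
  for (t in seq_len(horizon)) {
    flows[t, , ] <- occ[t, ] * M  # row i scaled by occupancy of i
    occ[t + 1L, ] <- colSums(flows[t, , ])
  }
  structure(
    list(occupancy = occ, flows = flows, arm = arm, states = ss,
         config = config),
    class = "crc_trajectory"
  )
}

#' @export
print.crc_trajectory <- function(x, ...) {
  cat(sprintf("<crc_trajectory: %s arm, %d cycles, %d expanded states>\n",
              x$arm, nrow(x$occupancy) - 1L, ncol(x$occupancy)))
  invisible(x)
}

#' Tidy a cohort trajectory
#'
#' @param x A `crc_trajectory`.
#' @param conceptual If `TRUE` (default), aggregate tunnel sub-states to
#'   their conceptual parent state.
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `state`, `occupancy`.
#' @method tidy crc_trajectory
#' @export
tidy.crc_trajectory <- function(x, conceptual = TRUE, ...) {
  occ <- x$occupancy
  out <- tibble::as_tibble(occ) |>
    dplyr::mutate(cycle = 0:(nrow(occ) - 1L), .before = 1L) |>
    tidyr::pivot_longer(-"cycle", names_to = "state",
                        values_to = "occupancy")
  if (conceptual) {
    map <- stats::setNames(x$states$conceptual, x$states$state)
    out <- out |>
      dplyr::mutate(state = unname(map[.data$state])) |>
      dplyr::summarise(occupancy = sum(.data$occupancy),
                       .by = c("cycle", "state"))
  }
  out
}

# per-expanded-state utility vector implied by the configuration
state_utilities <- function(config, states) {
  u <- config$utilities
  su <- stats::setNames(numeric(nrow(states)), states$state)
  for (i in seq_len(nrow(states))) {
    concept <- states$conceptual[i]
    su[i] <- switch(concept,
      normal = u$normal,
      adenoma = u$adenoma,
      advanced_adenoma = u$advanced_adenoma,
      adenoma_followup = u$adenoma_followup,
      advanced_adenoma_followup = u$advanced_adenoma_followup,
      death_crc = 0,
      death_other = 0,
      {
        stage <- sub("_(undiag|followup)$", "", concept)
        if (grepl("_undiag$", concept) &&
            isTRUE(u$undiagnosed_full_health)) u$normal else u$crc[[stage]]
      }
    )
  }
  su
}

# discount-and-half-cycle weight vector for state-membership rewards at
# cycles 0..horizon
reward_weights <- function(horizon, rate, half_cycle) {
  if (horizon == 0L) return(0)  # no cycles, no person-time
  w <- (1 + rate)^-(0:horizon)
  if (half_cycle) {
    w[1L] <- w[1L] / 2
    w[horizon + 1L] <- w[horizon + 1L] / 2
  } else {
    w[1L] <- 0  # membership counted at cycle ends only
  }
  w
}

#' Accrue costs, life years and QALYs along a trajectory
#'
#' State-membership rewards (1 life year per alive person-year, utility
#' weighted for QALYs) are accumulated over cycles 0..horizon with the
#' half-cycle correction (half weight at the first and final cycle) and
#' discounted at the effect rate. One-time costs comprise the screening
#' arm's upfront programme and initial treatment costs (cycle 0,
#' undiscounted) and, in both arms, the stage treatment cost attached to
#' every flow into a CRC follow-up state at the cycle of that flow,
#' discounted at the cost rate. Death tallies are the absorbing-state
#' occupancy at the horizon scaled to persons.
#'
#' @param trajectory A `crc_trajectory` from [run_cohort()].
#' @param config The same `crc_config` the trajectory was built with.
#' @param arm Arm label; defaults to the trajectory's own.
#' @return A one-row `crc_arm_result` tibble: `arm`, discounted `cost`,
#'   `ly`, `qaly`, undiscounted counterparts, and person counts
#'   `deaths_crc`, `deaths_other`.
#' @examples
#' accrue(run_cohort(crc_config(), "no_screening"), crc_config())
#' @export
accrue <- function(trajectory, config = trajectory$config,
                   arm = trajectory$arm) {
  stopifnot(inherits(trajectory, "crc_trajectory"))
  if (!isTRUE(all.equal(config, trajectory$config))) {
    rlang::abort("config does not match the one the trajectory was run with")
  }
  m <- config$model
  ss <- trajectory$states
  occ <- trajectory$occupancy
  horizon <- nrow(occ) - 1L
  cohort <- m$cohort_size
  alive <- !ss$absorbing
  util <- state_utilities(config, ss)

  accrue_effects <- function(rate) {
    w <- reward_weights(horizon, rate, isTRUE(m$half_cycle_correction))
    ly <- cohort * sum(w * rowSums(occ[, alive, drop = FALSE]))
    qaly <- cohort * sum(w * as.numeric(occ %*% util))
    c(ly = ly, qaly = qaly)
  }
  eff <- accrue_effects(m$discount_rate_effects)
  eff0 <- accrue_effects(0)

  upfront <- 0
  if (arm == "screening") {
    fr <- config$initial
    treat <- config$costs$treatment
    upfront <- cohort * (screening_oneoff(config) +
      fr$adenoma * config$costs$adenoma_treatment +
      fr$advanced_adenoma * treat$advanced_adenoma +
      sum(vapply(crc_stages(), function(s) fr[[s]] * treat[[s]], numeric(1L))))
  }
  accrue_flow_costs <- function(rate) {
    if (horizon == 0L) return(0)
    total <- 0
    treat <- config$costs$treatment
    for (stage in crc_stages()) {
      fu <- paste0(stage, "_followup")
      sources <- setdiff(ss$state, fu)
      inflow <- apply(trajectory$flows[, sources, fu, drop = FALSE], 1L, sum)
      total <- total +
        sum(inflow * treat[[stage]] * (1 + rate)^-(seq_len(horizon)))
    }
    cohort * total
  }
  cost <- upfront + accrue_flow_costs(m$discount_rate_costs)
  cost0 <- upfront + accrue_flow_costs(0)

  tibble::new_tibble(
    tibble::tibble(
      arm = arm,
      cost = cost, ly = eff[["ly"]], qaly = eff[["qaly"]],
      cost_undiscounted = cost0, ly_undiscounted = eff0[["ly"]],
      qaly_undiscounted = eff0[["qaly"]],
      deaths_crc = cohort * occ[horizon + 1L, "death_crc"],
      deaths_other = cohort * occ[horizon + 1L, "death_other"]
    ),
    class = "crc_arm_result"
  )
}

#' Run one strategy arm end to end
#'
#' Convenience composition of [run_cohort()] and [accrue()].
#'
#' @inheritParams run_cohort
#' @return A one-row `crc_arm_result` tibble (see [accrue()]).
#' @examples
#' run_arm(crc_config(), "screening")
#' @export
run_arm <- function(config, arm = c("screening", "no_screening")) {
  arm <- match.arg(arm)
  accrue(run_cohort(config, arm))
}
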