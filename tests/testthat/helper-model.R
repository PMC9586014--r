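# shared fixtures and independent oracles for the test suite

# a tiny hand-written registry: 20 participants, 8 colonoscopies,
# 6 diagnosed (one per category)
fixture_registry <- function() {
  tibble::tibble(
    id = 1:20,
    screen_result = c(rep("positive", 10), rep("negative", 10)),
    colonoscopy_done = c(rep(TRUE, 8), rep(FALSE, 12)),
    diagnosis = c("adenoma", "advanced_adenoma", "crc1", "crc2", "crc3",
                  "crc4", "none", "none", rep(NA_character_, 12)),
    inpatient_cost_usd = c(NA, 1200, 8000, 11000, 13000, 12000,
                           rep(NA_real_, 14)),
    followup_years = c(5, 5, 5, 3, 2, 1, rep(NA_real_, 14)),
    vital_status = c("alive", "alive", "alive", "dead_other", "dead_crc",
                     "dead_crc", rep(NA_character_, 14))
  )
}

# count-level Monte-Carlo microsimulation of one arm: individuals are
# carried through the transition matrix by multinomial draws, and costs,
# life years and QALYs are accumulated from the sampled counts with the
# same reward rules as the cohort engine. Independent of run_cohort() and
# accrue(): occupancy comes from sampling, rewards are re-derived here.
microsim_arm <- function(config, arm, n_individuals, seed) {
  set.seed(seed)
  M <- build_transition_matrix(config, arm)
  ss <- attr(M, "states")
  horizon <- config$model$horizon_cycles
  m <- config$model
  util <- crcscreen:::state_utilities(config, ss)
  alive <- !ss$absorbing

  init <- crcscreen:::initial_occupancy(config, arm, ss)
  counts <- as.vector(stats::rmultinom(1, n_individuals, init))
  occ <- matrix(0, horizon + 1L, nrow(ss))
  occ[1L, ] <- counts
  flow_cost <- numeric(horizon)
  treat <- config$costs$treatment
  for (t in seq_len(horizon)) {
    nxt <- numeric(nrow(ss))
    for (i in which(occ[t, ] > 0)) {
      moved <- as.vector(stats::rmultinom(1, occ[t, i], M[i, ]))
      nxt <- nxt + moved
      for (stage in crc_stages()) {
        j <- match(paste0(stage, "_followup"), ss$state)
        if (i != j) flow_cost[t] <- flow_cost[t] + moved[j] * treat[[stage]]
      }
    }
    occ[t + 1L, ] <- nxt
  }
  w <- (1 + m$discount_rate_effects)^-(0:horizon)
  if (isTRUE(m$half_cycle_correction)) {
    w[1L] <- w[1L] / 2
    w[horizon + 1L] <- w[horizon + 1L] / 2
  } else w[1L] <- 0
  scale <- m$cohort_size / n_individuals
  upfront <- 0
  if (arm == "screening") {
    fr <- config$initial
    upfront <- m$cohort_size * (screening_oneoff(config) +
      fr$adenoma * config$costs$adenoma_treatment +
      fr$advanced_adenoma * treat$advanced_adenoma +
      sum(vapply(crc_stages(), function(s) fr[[s]] * treat[[s]], numeric(1))))
  }
  list(
    ly = scale * sum(w * rowSums(occ[, alive, drop = FALSE])),
    qaly = scale * sum(w * as.numeric(occ %*% util)),
    cost = upfront + scale *
      sum(flow_cost * (1 + m$discount_rate_costs)^-(seq_len(horizon)))
  )
}

# small config for microsimulation checks: short horizon, no tunnels, so
# only 13 states are active
toy_config <- function() {
  crc_config(
    model = list(horizon_cycles = 5L, tunnel_years = 1L, cohort_size = 1000)
  )
}
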