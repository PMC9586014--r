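test_that("transition rows are probability distributions", {
  for (cfg in list(crc_config(),
                   crc_config(model = list(post_treatment_progression = TRUE)),
                   crc_config(model = list(tunnel_years = 2L)))) {
    M <- build_transition_matrix(cfg)
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
    # death rows are identity
    expect_equal(unname(M["death_crc", "death_crc"]), 1)
    expect_equal(unname(M["death_other", "death_other"]), 1)
  }
})

test_that("hand-computed rows match the hazard composition", {
  M <- build_transition_matrix(crc_config())
  # undiagnosed stage IV is symptomatically diagnosed with certainty
  expect_equal(unname(M["crc4_undiag", "crc4_followup"]), 1)
  # stage I follow-up: stage mortality only, remainder stays in follow-up
  expect_equal(unname(M["crc1_followup", "death_crc"]), 0.0218)
  expect_equal(unname(M["crc1_followup", "crc1_followup"]), 1 - 0.0218)
  expect_equal(unname(M["crc1_followup", "death_other"]), 0)
  # undiagnosed stage I: competing progression and diagnosis, no death
  expect_equal(unname(M["crc1_undiag", "crc2_undiag"]), 0.24)
  expect_equal(unname(M["crc1_undiag", "crc1_followup"]), 0.20)
  expect_equal(unname(M["crc1_undiag", "crc1_undiag"]), 1 - 0.24 - 0.20)
  # adenoma: other-cause death, then progression among survivors
  expect_equal(unname(M["adenoma", "death_other"]), 0.0175)
  expect_equal(unname(M["adenoma", "advanced_adenoma"]), 0.9825 * 0.02)
  # no re-progression from normal in the base case ...
  expect_equal(unname(M["normal", "adenoma"]), 0)
  # ... unless switched on
  M2 <- build_transition_matrix(
    crc_config(model = list(post_treatment_progression = TRUE)))
  expect_equal(unname(M2["normal", "adenoma"]), 0.9825 * 0.016)
})

test_that("occupancy is conserved at every cycle in both arms", {
  for (arm in c("screening", "no_screening")) {
    for (cfg in list(crc_config(),
                     crc_config(model = list(post_treatment_progression = TRUE,
                                             tunnel_years = 3L)))) {
      traj <- run_cohort(cfg, arm)
      expect_true(all(abs(rowSums(traj$occupancy) - 1) < 1e-9))
      # flows are consistent with consecutive occupancy rows
      for (t in c(1L, 10L, 25L)) {
        expect_equal(colSums(traj$flows[t, , ]),
                     traj$occupancy[t + 1L, ], tolerance = 1e-12)
        expect_equal(rowSums(traj$flows[t, , ]),
                     traj$occupancy[t, ], tolerance = 1e-12)
      }
    }
  }
})

test_that("an absorbed cohort stays put and accrues nothing", {
  cfg <- crc_config(validate = FALSE,
                    model = list(horizon_cycles = 5L))
  traj <- run_cohort(cfg, "no_screening")
  # overwrite the start: all mass already dead from other causes
  traj$occupancy[, ] <- 0
  traj$occupancy[, "death_other"] <- 1
  traj$flows[, , ] <- 0
  for (t in 1:5) traj$flows[t, "death_other", "death_other"] <- 1
  res <- accrue(traj)
  expect_equal(res$ly, 0)
  expect_equal(res$qaly, 0)
  expect_equal(res$cost, 0)
  expect_equal(res$deaths_other, cfg$model$cohort_size)
})

test_that("a pure death process decays geometrically", {
  # everyone starts in stage I follow-up with annual cancer mortality 1/2:
  # alive fractions 1, 0.5, 0.25
  cfg <- crc_config(
    model = list(horizon_cycles = 2L),
    initial = list(adenoma = 0, advanced_adenoma = 0,
                   crc1 = 1, crc2 = 0, crc3 = 0, crc4 = 0),
    transitions = list(crc_followup_mortality = list(
      crc1 = 0.5, crc2 = 0.0458, crc3 = 0.0994, crc4 = 0.2028))
  )
  traj <- run_cohort(cfg, "screening")
  expect_equal(unname(traj$occupancy[, "crc1_followup"]), c(1, 0.5, 0.25))
  expect_equal(unname(traj$occupancy[, "death_crc"]), c(0, 0.5, 0.75))
})

test_that("half-cycle-corrected accrual matches the trapezoid by hand", {
  # one person alive through cycles 0..2 and dead afterwards, r = 0:
  # weights (1/2, 1, 1/2) give 1.5 life years over the first two cycles
  cfg <- crc_config(model = list(horizon_cycles = 2L, cohort_size = 1,
                                 discount_rate_costs = 0,
                                 discount_rate_effects = 0))
  traj <- run_cohort(cfg, "screening")
  traj$occupancy[, ] <- 0
  traj$occupancy[1:2, "normal"] <- 1
  traj$occupancy[3, "death_other"] <- 1
  traj$flows[, , ] <- 0
  traj$flows[1, "normal", "normal"] <- 1
  traj$flows[2, "normal", "death_other"] <- 1
  res <- accrue(traj)
  expect_equal(res$ly, 0.5 * 1 + 1 * 1 + 0.5 * 0)
  expect_equal(res$qaly, res$ly)  # normal state has utility 1
})

test_that("with r = 0 and no half-cycle correction, life years equal the raw occupancy sum", {
  cfg <- crc_config(model = list(discount_rate_costs = 0,
                                 discount_rate_effects = 0,
                                 half_cycle_correction = FALSE))
  for (arm in c("screening", "no_screening")) {
    traj <- run_cohort(cfg, arm)
    alive <- !traj$states$absorbing
    raw <- sum(traj$occupancy[-1L, alive]) * cfg$model$cohort_size
    expect_equal(accrue(traj)$ly, raw, tolerance = 1e-12)
  }
})

test_that("accrued totals are exactly linear in cohort size", {
  base <- run_arm(crc_config(), "screening")
  scaled <- run_arm(crc_config(model = list(cohort_size = 13250 * 7)),
                    "screening")
  for (col in c("cost", "ly", "qaly", "deaths_crc", "deaths_other")) {
    expect_equal(scaled[[col]], 7 * base[[col]])
  }
})

test_that("raising a follow-up mortality weakly decreases life years", {
  ly_at <- function(m1) {
    cfg <- crc_config(transitions = list(crc_followup_mortality = list(
      crc1 = m1, crc2 = 0.0458, crc3 = 0.0994, crc4 = 0.2028)))
    run_arm(cfg, "screening")$ly
  }
  lys <- vapply(c(0.0218, 0.10, 0.30, 0.60), ly_at, numeric(1))
  expect_true(all(diff(lys) <= 0))
})

test_that("a zero-cycle horizon accrues only the upfront costs", {
  cfg <- crc_config(model = list(horizon_cycles = 0L))
  s <- run_arm(cfg, "screening")
  expect_equal(s$ly, 0)
  expect_equal(s$qaly, 0)
  fr <- cfg$initial
  upfront <- cfg$model$cohort_size * (screening_oneoff(cfg) +
    fr$advanced_adenoma * cfg$costs$treatment$advanced_adenoma +
    fr$crc1 * cfg$costs$treatment$crc1 + fr$crc2 * cfg$costs$treatment$crc2 +
    fr$crc3 * cfg$costs$treatment$crc3 + fr$crc4 * cfg$costs$treatment$crc4)
  expect_equal(s$cost, upfront)
  ns <- run_arm(cfg, "no_screening")
  expect_equal(ns$cost, 0)
})

test_that("qaly never exceeds ly and death counts never exceed the cohort", {
  for (arm in c("screening", "no_screening")) {
    res <- run_arm(crc_config(), arm)
    expect_lte(res$qaly, res$ly)
    expect_lte(res$deaths_crc + res$deaths_other, crc_config()$model$cohort_size)
    expect_true(all(unlist(res[c("cost", "ly", "qaly", "deaths_crc",
                                 "deaths_other")]) >= 0))
  }
})

test_that("accrue rejects a mismatched configuration", {
  traj <- run_cohort(crc_config(), "screening")
  other <- crc_config(model = list(cohort_size = 10))
  expect_error(accrue(traj, config = other), "does not match")
})

test_that("the cohort engine agrees with a Monte-Carlo microsimulation", {
  cfg <- toy_config()
  for (arm in c("screening", "no_screening")) {
    exact <- run_arm(cfg, arm)
    sims <- lapply(1:20, function(s) microsim_arm(cfg, arm, 50000L, seed = s))
    for (col in c("ly", "qaly", "cost")) {
      vals <- vapply(sims, `[[`, numeric(1), col)
      se <- stats::sd(vals) / sqrt(length(vals))
      expect_lt(abs(mean(vals) - exact[[col]]), 3 * se + 1e-9)
    }
  }
})
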