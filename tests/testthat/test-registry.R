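test_that("registry generation is deterministic given a seed", {
  p <- registry_params(n_participants = 5000L, seed = 11L)
  expect_identical(generate_registry(p), generate_registry(p))
  p2 <- registry_params(n_participants = 5000L, seed = 12L)
  expect_false(identical(generate_registry(p), generate_registry(p2)))
})

test_that("the cascade is monotone and structurally consistent", {
  set.seed(99)
  for (i in 1:5) {
    p <- registry_params(
      n_participants = 2000L,
      p_positive = stats::runif(1), p_colonoscopy = stats::runif(1),
      p_diagnosis = stats::runif(1), seed = i
    )
    reg <- generate_registry(p)
    cs <- cascade_summary(reg)
    n <- function(step) cs$count[cs$step == step]
    expect_true(n("screened") >= n("positive"))
    expect_true(n("positive") >= n("colonoscopy"))
    expect_true(n("colonoscopy") >= n("diagnosed"))
    # diagnosis only with colonoscopy; costs only for treated categories;
    # follow-up fields only for diagnosed rows
    expect_true(all(reg$colonoscopy_done[!is.na(reg$diagnosis)]))
    expect_true(all(is.na(reg$inpatient_cost_usd[
      is.na(reg$diagnosis) | reg$diagnosis %in% c("none", "adenoma")])))
    diagnosed <- !is.na(reg$diagnosis) & reg$diagnosis != "none"
    expect_true(all(!is.na(reg$vital_status[diagnosed])))
    expect_true(all(is.na(reg$vital_status[!diagnosed])))
  }
})

test_that("degenerate cascades produce empty downstream steps", {
  p <- registry_params(n_participants = 500L, p_positive = 0, seed = 3L)
  cs <- cascade_summary(generate_registry(p))
  expect_equal(cs$count[cs$step != "screened"], rep(0, 9))
  cs0 <- cascade_summary(generate_registry(
    registry_params(n_participants = 0L)))
  expect_equal(cs0$count, rep(0, 10))
})

test_that("cascade_summary counts a hand-written registry correctly", {
  cs <- cascade_summary(fixture_registry())
  expect_equal(cs$count[cs$step == "screened"], 20)
  expect_equal(cs$count[cs$step == "positive"], 10)
  expect_equal(cs$count[cs$step == "colonoscopy"], 8)
  expect_equal(cs$count[cs$step == "diagnosed"], 6)
  expect_equal(cs$count[cs$step %in% c("adenoma", "advanced_adenoma",
                                       "crc1", "crc2", "crc3", "crc4")],
               rep(1, 6))
})

test_that("quota mode reproduces the published cascade totals exactly", {
  reg <- generate_registry(
    registry_params(n_participants = 1097656L, seed = 1L), quota = TRUE)
  cs <- cascade_summary(reg)
  expect_equal(cs$count[match(c("screened", "positive", "colonoscopy",
                                "diagnosed"), cs$step)],
               c(1097656, 284287, 82729, 13250))
  expect_equal(cs$count[match(c("adenoma", "advanced_adenoma", "crc1",
                                "crc2", "crc3", "crc4"), cs$step)],
               c(10653, 745, 766, 478, 492, 116))
})

test_that("sampled rates land within binomial noise of their parameters", {
  n <- 200000L
  p <- registry_params(n_participants = n, seed = 2026L)
  reg <- generate_registry(p)
  # positive fraction within 3 binomial SDs
  phat <- mean(reg$screen_result == "positive")
  se <- sqrt(p$p_positive * (1 - p$p_positive) / n)
  expect_lt(abs(phat - p$p_positive), 3 * se)
  # stage IV five-year cancer survival: alive fraction among stage IV
  # rows, excluding other-cause deaths, within 3 SDs of the parameter
  iv <- reg[!is.na(reg$diagnosis) & reg$diagnosis == "crc4", ]
  iv <- iv[iv$vital_status != "dead_other", ]
  s5 <- p$survival_5yr$crc4
  # the competing other-cause risk thins each annual at-risk set but the
  # conditional alive fraction stays close to the cause-specific survival
  phat_iv <- mean(iv$vital_status == "alive")
  expect_lt(abs(phat_iv - s5), 3 * sqrt(s5 * (1 - s5) / nrow(iv)) + 0.01)
})

test_that("out-of-range registry parameters are rejected", {
  expect_error(registry_params(p_positive = 1.4), "out of \\[0,1\\]")
  expect_error(registry_params(cost_medians = list(
    advanced_adenoma = -5, crc1 = 1, crc2 = 1, crc3 = 1, crc4 = 1)),
    "cost_medians")
  expect_error(registry_params(diagnosis_mix = list(
    adenoma = 0.5, advanced_adenoma = 0.1, crc1 = 0.1, crc2 = 0.1,
    crc3 = 0.1, crc4 = 0.0)), "sum to 1")
})

test_that("registries round-trip through CSV", {
  reg <- generate_registry(registry_params(n_participants = 300L, seed = 8L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  # numeric columns survive to CSV text precision (15 significant digits)
  expect_equal(back, reg, tolerance = 1e-12)
  expect_identical(cascade_summary(back), cascade_summary(reg))
  expect_error(suppressWarnings(
    read_registry(withr::local_tempfile(fileext = ".csv"))))
})
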