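#' Convert a 5-year survival rate to an annual transition probability
#'
#' Stage-specific cancer survival is registered as a 5-year rate; the
#' annual-cycle model needs an annual mortality. Under a constant annual
#' hazard the annual survival is the fifth root of the 5-year survival,
#' and the annual mortality its complement:
#' \deqn{S_a = S_5^{1/5}, \qquad M = 1 - S_a.}
#' Values are exact to floating precision; round only at report time
#' (4 decimals by convention).
#'
#' @param survival_5yr 5-year survival rate(s) in \[0, 1\] (vectorised).
#' @param years Compounding period in years (default 5).
#' @return A tibble with columns `survival_5yr`, `survival_annual`,
#'   `annual_mortality`.
#' @examples
#' survival_to_mortality(c(0.8957, 0.7912, 0.5924, 0.3220))
#' @export
survival_to_mortality <- function(survival_5yr, years = 5) {
  if (!is.numeric(survival_5yr) || any(!is.finite(survival_5yr)) ||
      any(survival_5yr < 0 | survival_5yr > 1)) {
    rlang::abort("survival_5yr must be in [0, 1]")
  }
  sa <- survival_5yr^(1 / years)
  tibble::tibble(
    survival_5yr = survival_5yr,
    survival_annual = sa,
    annual_mortality = 1 - sa
  )
}

#' Allocate a total cost over a denominator population
#'
#' Programme-level totals (initial screening, colonoscopy) enter the
#' model as average costs per member of a reference population (per
#' colonoscopy, or per diagnosed resident). The quotient is exact; the
#' reported value is rounded half-up to 2 decimals as is conventional for
#' USD amounts.
#'
#' @param total Total cost (USD).
#' @param denominator Positive population count.
#' @return A tibble with columns `total`, `denominator`, `per_capita`
#'   (exact) and `per_capita_reported` (2-decimal, half-up).
#' @examples
#' per_capita_cost(13131574, 82729)$per_capita_reported  # 158.73
#' per_capita_cost(3721054, 13250)$per_capita_reported   # 280.83
#' @export
per_capita_cost <- function(total, denominator) {
  if (!is.numeric(denominator) || any(denominator <= 0)) {
    rlang::abort("denominator must be > 0")
  }
  pc <- total / denominator
  tibble::tibble(
    total = total, denominator = denominator,
    per_capita = pc, per_capita_reported = round_half_up(pc, 2L)
  )
}

# round half away from zero (printed tables use commercial rounding,
# not banker's rounding)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Initial state distribution from diagnosis counts
#'
#' Converts the six diagnosed-category counts of a screening round into
#' the initial state fractions of the cohort model. Exact fractions are
#' retained; `fraction_reported` is the 4-decimal (half-up) value used in
#' printed tables.
#'
#' @param counts Named numeric vector (or tibble with `category` and
#'   `count`) over the categories `adenoma`, `advanced_adenoma`,
#'   `crc1`..`crc4`. All counts must be non-negative with a positive sum.
#' @return A tibble with columns `category`, `count`, `fraction`,
#'   `fraction_reported`. Fractions sum to exactly 1 before rounding.
#' @examples
#' initial_distribution(c(adenoma = 10653, advanced_adenoma = 745,
#'                        crc1 = 766, crc2 = 478, crc3 = 492, crc4 = 116))
#' @export
initial_distribution <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$category)
  }
  if (!setequal(names(counts), initial_categories())) {
    rlang::abort(paste0("counts must be named over: ",
                        paste(initial_categories(), collapse = ", ")))
  }
  counts <- counts[initial_categories()]
  if (any(counts < 0)) rlang::abort("counts must be >= 0")
  total <- sum(counts)
  if (total <= 0) rlang::abort("total count must be > 0")
  fr <- counts / total
  tibble::tibble(
    category = names(counts), count = as.numeric(counts),
    fraction = as.numeric(fr),
    fraction_reported = round_half_up(as.numeric(fr), 4L)
  )
}

#' Median treatment cost after outlier removal
#'
#' Hospitalisation costs are right-skewed with occasional gross outliers,
#' so treatment costs enter the model as medians of outlier-cleaned data.
#' The default rule works on the log scale (appropriate for
#' multiplicative cost variation) and drops values outside the Tukey
#' fences, i.e. outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] of the log costs.
#'
#' @param costs Numeric vector of positive costs (USD); `NA`s dropped.
#' @param outlier_rule `"log_iqr"` (default) or `"none"`.
#' @param k Fence multiplier (default 1.5).
#' @return The median of the surviving values (a single number).
#' @examples
#' median_treatment_cost(c(1, 2, 3, 4, 1000))  # 1000 fenced out -> 2.5
#' median_treatment_cost(c(100, 100, 100))     # 100
#' @export
median_treatment_cost <- function(costs, outlier_rule = c("log_iqr", "none"),
                                  k = 1.5) {
  outlier_rule <- match.arg(outlier_rule)
  costs <- costs[!is.na(costs)]
  if (!length(costs)) rlang::abort("no costs supplied")
  if (any(costs <= 0)) rlang::abort("costs must be positive")
  keep <- costs
  if (outlier_rule == "log_iqr") {
    lx <- log(costs)
    q <- stats::quantile(lx, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    keep <- costs[lx >= q[1L] - k * iqr & lx <= q[2L] + k * iqr]
    if (!length(keep)) rlang::abort("all values removed as outliers")
  }
  stats::median(keep)
}

#' Convert Renminbi amounts to US dollars
#'
#' @param amount_rmb Amount(s) in RMB.
#' @param rate RMB per USD (default 6.3743, the 2014-2016 mean rate).
#' @return Amount(s) in USD.
#' @examples
#' convert_currency(6.3743)   # 1
#' convert_currency(63743)    # 10000
#' @export
convert_currency <- function(amount_rmb, rate = 6.3743) {
  if (any(!is.finite(amount_rmb))) rlang::abort("amount must be finite")
  if (!is.numeric(rate) || rate <= 0) rlang::abort("rate must be > 0")
  amount_rmb / rate
}

#' Derive model parameters from a participant-level registry
#'
#' Composes the estimation stage: the initial state distribution from
#' diagnosis counts, the one-off screening and colonoscopy allocation per
#' diagnosed resident, outlier-cleaned median treatment costs per treated
#' category, and stage-specific annual cancer mortality from the 5-year
#' follow-up outcomes (other-cause deaths treated as censoring, so the
#' estimate is cause-specific). Everything the registry cannot inform
#' (transition probabilities between disease states, utilities, discount
#' rates) is retained from `base`.
#'
#' @param registry A registry tibble (see [generate_registry()]).
#' @param base A `crc_config` supplying non-estimated parameters.
#' @param screening_cost_per_participant Initial-screening cost per
#'   screened participant (USD; default 3,721,054 / 1,097,656).
#' @param colonoscopy_unit_cost Cost per colonoscopy (USD).
#' @return A list with the updated `config` (a `crc_config`) and an
#'   `estimates` tibble (one row per derived quantity: `parameter`,
#'   `value`, `n`).
#' @examples
#' reg <- generate_registry(registry_params(n_participants = 50000, seed = 1))
#' fit <- estimate_from_registry(reg)
#' fit$config$initial$adenoma
#' @export
estimate_from_registry <- function(registry, base = crc_config(),
                                   screening_cost_per_participant =
                                     3721054 / 1097656,
                                   colonoscopy_unit_cost = 158.73) {
  diag <- registry$diagnosis
  diagnosed <- !is.na(diag) & diag != "none"
  counts <- vapply(initial_categories(),
                   function(cat) sum(diagnosed & diag == cat), numeric(1L))
  missing <- names(counts)[counts == 0L]
  if (length(missing)) {
    rlang::abort(paste0("registry has no diagnosed rows in categor",
                        if (length(missing) > 1L) "ies: " else "y: ",
                        paste(missing, collapse = ", ")))
  }
  dist <- initial_distribution(counts)

  n_screened <- nrow(registry)
  n_colo <- sum(registry$colonoscopy_done)
  n_diag <- sum(diagnosed)
  alloc <- (n_screened * screening_cost_per_participant +
              n_colo * colonoscopy_unit_cost) / n_diag

  medians <- purrr::map_dbl(treated_categories(), function(cat) {
    median_treatment_cost(registry$inpatient_cost_usd[diagnosed & diag == cat])
  })
  names(medians) <- treated_categories()

  surv <- purrr::map_dbl(crc_stages(), function(stage) {
    estimate_stage_survival(registry[diagnosed & diag == stage, ])
  })
  names(surv) <- crc_stages()
  mort <- 1 - surv^(1 / 5)

  cfg <- base
  cfg$initial <- as.list(stats::setNames(dist$fraction, dist$category))
  cfg$costs$screening_component_per_diagnosed <-
    n_screened * screening_cost_per_participant / n_diag
  cfg$costs$colonoscopy_unit <- colonoscopy_unit_cost
  cfg$costs$n_colonoscopies <- n_colo
  cfg$costs$n_diagnosed <- n_diag
  cfg$costs$treatment <- utils::modifyList(cfg$costs$treatment,
                                           as.list(medians))
  cfg$transitions$crc_followup_mortality <- as.list(mort)
  v <- validate_config(cfg)
  if (nrow(v)) {
    rlang::abort(c("estimated configuration is invalid",
                   stats::setNames(v$message, rep("x", nrow(v)))))
  }

  estimates <- dplyr::bind_rows(
    tibble::tibble(parameter = paste0("initial.", dist$category),
                   value = dist$fraction, n = n_diag),
    tibble::tibble(parameter = "costs.screening_oneoff_per_diagnosed",
                   value = alloc, n = n_diag),
    tibble::tibble(parameter = paste0("costs.treatment.", names(medians)),
                   value = unname(medians),
                   n = as.numeric(counts[names(medians)])),
    tibble::tibble(
      parameter = paste0("transitions.crc_followup_mortality.", names(mort)),
      value = unname(mort), n = as.numeric(counts[names(mort)]))
  )
  list(config = cfg, estimates = estimates)
}

# cause-specific 5-year survival by discrete product-limit over annual
# intervals; other-cause deaths leave the risk set as censored
estimate_stage_survival <- function(rows, horizon = 5L) {
  s <- 1
  for (yr in seq_len(horizon)) {
    at_risk <- sum(rows$followup_years >= yr)
    d_crc <- sum(rows$followup_years == yr & rows$vital_status == "dead_crc")
    if (at_risk > 0L) s <- s * (1 - d_crc / at_risk)
  }
  s
}
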