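#' Parameters of the synthetic screening registry
#'
#' The generator emulates a participant-level database from a one-off
#' community screening round: an initial screen (stool test and/or risk
#' questionnaire), colonoscopy referral of positives, diagnosis of a
#' fraction of colonoscopies, a six-category diagnosis mix, right-skewed
#' per-patient hospitalisation costs with known medians, and five years of
#' survival follow-up with stage-specific cancer mortality competing with
#' crude other-cause mortality. Default rates reproduce the published
#' cascade (1,097,656 screened; 284,287 positive; 82,729 colonoscopies;
#' 13,250 diagnosed) and the published cost medians and 5-year survival by
#' stage; the default cohort is scaled down to 10,000 participants.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Fields: `n_participants`; cascade probabilities `p_positive`,
#'   `p_colonoscopy`, `p_diagnosis`; `diagnosis_mix` (named six-category
#'   distribution); `cost_medians` (USD, per treated category);
#'   `cost_dispersion` (log-scale standard deviation of the cost law);
#'   `outlier_fraction` and `outlier_multiplier_range` (a small
#'   contaminating fraction of gross cost outliers, so outlier-removal
#'   rules have work to do); `missing_cost_fraction` (costs lost to
#'   follow-up); `survival_5yr` (named per-stage 5-year survival);
#'   `other_cause_mortality`; `followup_horizon` (years); `seed`.
#' @return A validated `registry_params` list.
#' @examples
#' registry_params()$p_positive
#' registry_params(n_participants = 500, seed = 7)
#' @export
registry_params <- function(...) {
  p <- registry_params_defaults()
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) {
    rlang::abort(paste0("unknown registry parameter(s): ",
                        paste(bad, collapse = ", ")))
  }
  p[names(overrides)] <- overrides
  for (nm in c("p_positive", "p_colonoscopy", "p_diagnosis",
               "outlier_fraction", "missing_cost_fraction",
               "other_cause_mortality")) {
    x <- p[[nm]]
    if (!is.numeric(x) || !is.finite(x) || x < 0 || x > 1)
      rlang::abort(paste0("registry parameter ", nm, " out of [0,1]"))
  }
  if (abs(sum(unlist(p$diagnosis_mix)) - 1) > 1e-8)
    rlang::abort("diagnosis_mix must sum to 1")
  if (any(unlist(p$cost_medians) <= 0))
    rlang::abort("cost_medians must be > 0")
  if (any(unlist(p$survival_5yr) < 0 | unlist(p$survival_5yr) > 1))
    rlang::abort("survival_5yr out of [0,1]")
  if (p$n_participants < 0) rlang::abort("n_participants must be >= 0")
  structure(p, class = "registry_params")
}

registry_params_defaults <- function() {
  list(
    n_participants = 10000L,
    p_positive = 284287 / 1097656,
    p_colonoscopy = 82729 / 284287,
    p_diagnosis = 13250 / 82729,
    diagnosis_mix = list(
      adenoma = 10653 / 13250, advanced_adenoma = 745 / 13250,
      crc1 = 766 / 13250, crc2 = 478 / 13250,
      crc3 = 492 / 13250, crc4 = 116 / 13250
    ),
    cost_medians = list(
      advanced_adenoma = 1108.82, crc1 = 8566.63, crc2 = 10554.70,
      crc3 = 13395.73, crc4 = 11177.51
    ),
    cost_dispersion = 0.6,
    outlier_fraction = 0.02,
    outlier_multiplier_range = c(10, 30),
    missing_cost_fraction = 0,
    survival_5yr = list(
      crc1 = 0.8957, crc2 = 0.7912, crc3 = 0.5924, crc4 = 0.3220
    ),
    other_cause_mortality = 0.0175,
    followup_horizon = 5L,
    seed = 1L
  )
}

treated_categories <- function() c("advanced_adenoma", crc_stages())

#' Generate a synthetic participant-level screening registry
#'
#' Draws one row per participant through the screening cascade
#' (positive screen, colonoscopy, diagnosis, diagnosed category), then
#' per-patient hospitalisation costs for treated categories from a
#' log-normal law whose median equals the configured median (with a small
#' fraction of gross outliers injected), and five-year survival outcomes
#' for diagnosed rows with stage-specific cancer mortality competing with
#' crude other-cause mortality. Fully reproducible given `params$seed`.
#'
#' In quota mode the cascade counts are fixed at their expected values
#' (largest-remainder rounding) instead of sampled, so that with the
#' full-scale default parameters (`n_participants = 1097656`) the cascade
#' reproduces the published counts exactly; costs and survival are still
#' sampled.
#'
#' @param params A [registry_params()] list.
#' @param quota If `TRUE`, fix cascade counts at expected values.
#' @return A tibble with one row per participant: `id`, `screen_result`
#'   (`"positive"`/`"negative"`), `colonoscopy_done`, `diagnosis`
#'   (`NA` if no colonoscopy, otherwise `"none"`, `"adenoma"`,
#'   `"advanced_adenoma"`, `"crc1"`..`"crc4"`), `inpatient_cost_usd`
#'   (treated categories only), `followup_years` and `vital_status`
#'   (`"alive"`, `"dead_crc"`, `"dead_other"`; diagnosed rows only).
#' @examples
#' reg <- generate_registry(registry_params(n_participants = 2000, seed = 42))
#' cascade_summary(reg)
#' @export
generate_registry <- function(params = registry_params(), quota = FALSE) {
  stopifnot(inherits(params, "registry_params"))
  n <- as.integer(params$n_participants)
  out <- with_seed(params$seed, {
    if (n == 0L) {
      positive <- logical(0L)
    } else if (quota) {
      positive <- quota_flags(n, params$p_positive)
    } else {
      positive <- stats::runif(n) < params$p_positive
    }
    colo <- logical(n)
    n_pos <- sum(positive)
    colo[positive] <- if (quota) quota_flags(n_pos, params$p_colonoscopy) else
      stats::runif(n_pos) < params$p_colonoscopy
    diagnosis <- rep(NA_character_, n)
    n_colo <- sum(colo)
    mix <- unlist(params$diagnosis_mix)
    if (n_colo > 0L) {
      if (quota) {
        n_diag <- sum(quota_flags(n_colo, params$p_diagnosis))
        cats <- quota_categories(n_diag, mix)
        diagnosis[colo] <- sample(c(cats, rep("none", n_colo - n_diag)))
      } else {
        diagnosed <- stats::runif(n_colo) < params$p_diagnosis
        d <- rep("none", n_colo)
        d[diagnosed] <- sample(names(mix), sum(diagnosed),
                               replace = TRUE, prob = mix)
        diagnosis[colo] <- d
      }
    }
    cost <- rep(NA_real_, n)
    for (cat in treated_categories()) {
      rows <- which(!is.na(diagnosis) & diagnosis == cat)
      if (length(rows)) {
        cost[rows] <- draw_costs(length(rows), params$cost_medians[[cat]],
                                 params)
      }
    }
    if (params$missing_cost_fraction > 0) {
      has_cost <- which(!is.na(cost))
      drop <- has_cost[stats::runif(length(has_cost)) <
                         params$missing_cost_fraction]
      cost[drop] <- NA_real_
    }
    fu <- simulate_followup(diagnosis, params)
    tibble::tibble(
      id = seq_len(n),
      screen_result = ifelse(positive, "positive", "negative"),
      colonoscopy_done = colo,
      diagnosis = diagnosis,
      inpatient_cost_usd = cost,
      followup_years = fu$years,
      vital_status = fu$status
    )
  })
  out
}

# log-normal around the stated median (median-preserving under the log
# transform), with a contaminating fraction of gross multiplicative outliers
draw_costs <- function(k, median_usd, params) {
  x <- stats::rlnorm(k, meanlog = log(median_usd),
                     sdlog = params$cost_dispersion)
  contaminated <- stats::runif(k) < params$outlier_fraction
  if (any(contaminated)) {
    r <- params$outlier_multiplier_range
    x[contaminated] <- x[contaminated] *
      stats::runif(sum(contaminated), r[1L], r[2L])
  }
  x
}

# discrete annual competing risks over the follow-up horizon: cancer death
# at the stage-specific annual rate first, then other-cause death among
# survivors at the crude rate
simulate_followup <- function(diagnosis, params) {
  n <- length(diagnosis)
  years <- rep(NA_real_, n)
  status <- rep(NA_character_, n)
  diagnosed <- which(!is.na(diagnosis) & diagnosis != "none")
  if (length(diagnosed)) {
    years[diagnosed] <- params$followup_horizon
    status[diagnosed] <- "alive"
    q_other <- params$other_cause_mortality
    for (cat in unique(diagnosis[diagnosed])) {
      rows <- diagnosed[diagnosis[diagnosed] == cat]
      m_crc <- if (cat %in% crc_stages())
        1 - params$survival_5yr[[cat]]^(1 / params$followup_horizon) else 0
      at_risk <- rows
      for (yr in seq_len(params$followup_horizon)) {
        if (!length(at_risk)) break
        u <- stats::runif(length(at_risk))
        died_crc <- u < m_crc
        died_other <- !died_crc & (u < m_crc + (1 - m_crc) * q_other)
        if (any(died_crc)) {
          years[at_risk[died_crc]] <- yr
          status[at_risk[died_crc]] <- "dead_crc"
        }
        if (any(died_other)) {
          years[at_risk[died_other]] <- yr
          status[at_risk[died_other]] <- "dead_other"
        }
        at_risk <- at_risk[!(died_crc | died_other)]
      }
    }
  }
  list(years = years, status = status)
}

# deterministic largest-remainder allocation of successes among n slots,
# randomly placed
quota_flags <- function(n, p) {
  k <- round(n * p)
  sample(c(rep(TRUE, k), rep(FALSE, n - k)))
}

quota_categories <- function(n_diag, mix) {
  k <- floor(n_diag * mix)
  rem <- n_diag - sum(k)
  if (rem > 0) {
    frac <- n_diag * mix - k
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    k[top] <- k[top] + 1
  }
  rep(names(mix), times = k)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Summarise the screening cascade of a registry
#'
#' Counts participants at each step of the screening cascade and per
#' diagnosed category, in the layout used to report a screening round
#' (screened, positive, colonoscopy, diagnosed, then the six categories).
#'
#' @param registry A registry tibble from [generate_registry()] (or read
#'   from CSV with the same columns).
#' @return A tibble with columns `step` and `count`.
#' @examples
#' cascade_summary(generate_registry(registry_params(n_participants = 1000)))
#' @export
cascade_summary <- function(registry) {
  diag <- registry$diagnosis
  diagnosed <- !is.na(diag) & diag != "none"
  cats <- c("adenoma", "advanced_adenoma", crc_stages())
  tibble::tibble(
    step = c("screened", "positive", "colonoscopy", "diagnosed", cats),
    count = unname(c(
      nrow(registry),
      sum(registry$screen_result == "positive"),
      sum(registry$colonoscopy_done),
      sum(diagnosed),
      vapply(cats, function(cat) sum(diagnosed & diag == cat), numeric(1L))
    ))
  )
}

#' Write or read a registry as CSV
#'
#' Plain-CSV persistence for participant-level registries, with the
#' documented column set (`id`, `screen_result`, `colonoscopy_done`,
#' `diagnosis`, `inpatient_cost_usd`, `followup_years`, `vital_status`).
#'
#' @param registry A registry tibble.
#' @param path File path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns the registry tibble with the documented column types.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' reg <- generate_registry(registry_params(n_participants = 100))
#' write_registry(reg, f)
#' all.equal(read_registry(f), reg)
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  cols <- c(id = "integer", screen_result = "character",
            colonoscopy_done = "logical", diagnosis = "character",
            inpatient_cost_usd = "numeric", followup_years = "numeric",
            vital_status = "character")
  df <- utils::read.csv(path, na.strings = "", colClasses = cols)
  missing <- setdiff(names(cols), names(df))
  if (length(missing)) {
    rlang::abort(paste0("registry CSV is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(df[, names(cols)])
}
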