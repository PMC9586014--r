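#' Build a model configuration
#'
#' Returns the full parameter set of the cost-effectiveness model as a
#' validated `crc_config` object. Defaults encode the base case of the
#' Shanghai community screening programme evaluation: a cohort of 13,250
#' diagnosed residents followed over 25 annual cycles, 3% discounting of
#' both costs and effects, half-cycle correction, and the published
#' transition probabilities, per-capita costs (USD) and health-state
#' utilities. Any element can be overridden through `...` using the same
#' nesting as the configuration file (see [load_config()]).
#'
#' @param ... Named sections (`model`, `initial`, `transitions`, `costs`,
#'   `utilities`, `registry`) whose entries override the defaults. Each
#'   must be a named list; omitted entries keep their default.
#' @param validate If `TRUE` (default), abort when the resulting
#'   configuration violates an invariant (see [validate_config()]).
#' @return A `crc_config` object: a named list of sections.
#' @examples
#' cfg <- crc_config()
#' cfg$model$cohort_size
#' low_discount <- crc_config(model = list(discount_rate_costs = 0,
#'                                         discount_rate_effects = 0))
#' @export
crc_config <- function(..., validate = TRUE) {
  cfg <- default_config()
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      rlang::abort(paste0("unknown configuration section(s): ",
                          paste(bad, collapse = ", ")))
    }
    for (sec in names(overrides)) {
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], overrides[[sec]])
    }
  }
  cfg <- structure(cfg, class = "crc_config")
  if (validate) {
    v <- validate_config(cfg)
    if (nrow(v)) {
      rlang::abort(c("invalid model configuration",
                     stats::setNames(v$message, rep("x", nrow(v)))))
    }
  }
  cfg
}

default_config <- function() {
  list(
    model = list(
      horizon_cycles = 25L,
      cycle_length_years = 1,
      cohort_size = 13250,
      discount_rate_costs = 0.03,
      discount_rate_effects = 0.03,
      half_cycle_correction = TRUE,
      # members returning to normal after surveillance do not re-enter the
      # adenoma-carcinoma sequence by default; see the methods vignette
      post_treatment_progression = FALSE,
      other_cause_mortality = 0.0175,
      tunnel_years = 5L,
      gdp_per_capita = 19866,
      wtp_threshold = 59598
    ),
    initial = list(
      adenoma = 0.8040, advanced_adenoma = 0.0562,
      crc1 = 0.0578, crc2 = 0.0361, crc3 = 0.0371, crc4 = 0.0088
    ),
    transitions = list(
      normal_to_adenoma = 0.016,
      adenoma_to_advanced = 0.020,
      advanced_to_crc1 = 0.0326,
      crc1_to_crc2 = 0.24,
      crc2_to_crc3 = 0.36,
      crc3_to_crc4 = 0.175,
      crc1_diagnosis = 0.20,
      crc2_diagnosis = 0.20,
      crc3_diagnosis = 0.65,
      crc4_diagnosis = 1.0,
      crc_followup_mortality = list(
        crc1 = 0.0218, crc2 = 0.0458, crc3 = 0.0994, crc4 = 0.2028
      )
    ),
    costs = list(
      # per diagnosed resident, the one-off programme cost splits into the
      # initial-screening share and the colonoscopy share; the latter is the
      # unit colonoscopy cost scaled by colonoscopies per diagnosis
      screening_component_per_diagnosed = 3721054 / 13250,
      colonoscopy_unit = 158.73,
      n_colonoscopies = 82729,
      n_diagnosed = 13250,
      screening_oneoff_per_diagnosed = NA,  # NA = derive from components
      adenoma_treatment = 0,
      treatment = list(
        advanced_adenoma = 1108.82, crc1 = 8566.63, crc2 = 10554.70,
        crc3 = 13395.73, crc4 = 11177.51
      ),
      exchange_rate_rmb_per_usd = 6.3743
    ),
    utilities = list(
      normal = 1.000, adenoma = 0.871, advanced_adenoma = 0.827,
      crc = list(crc1 = 0.829, crc2 = 0.860, crc3 = 0.814, crc4 = 0.738),
      adenoma_followup = 0.871, advanced_adenoma_followup = 0.827,
      # undiagnosed, asymptomatic cancers carry full health-related quality
      # of life until symptomatic diagnosis; set FALSE for stage utilities
      undiagnosed_full_health = TRUE
    ),
    registry = registry_params_defaults()
  )
}

#' One-off screening cost per diagnosed resident
#'
#' The programme cost charged once at model entry for every diagnosed
#' member of the screening arm: the initial-screening share plus the unit
#' colonoscopy cost scaled by the number of colonoscopies per diagnosis.
#' An explicit `costs$screening_oneoff_per_diagnosed` overrides the
#' composition (used, e.g., when loading a configuration that states only
#' the total).
#'
#' @param config A `crc_config`.
#' @return A single USD amount (about 1,271.90 in the base case).
#' @examples
#' round(screening_oneoff(crc_config()), 2)
#' @export
screening_oneoff <- function(config) {
  cc <- config$costs
  oneoff <- cc$screening_oneoff_per_diagnosed
  if (!is.null(oneoff) && !is.na(oneoff)) {
    return(oneoff)
  }
  cc$screening_component_per_diagnosed +
    cc$colonoscopy_unit * cc$n_colonoscopies / cc$n_diagnosed
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the parameter set and returns the
#' violations as data rather than raising: probabilities and utilities in
#' \[0, 1\], non-negative costs, initial fractions summing to one (within
#' 5e-4, allowing for 4-decimal rounding of registry-derived fractions),
#' per-state outgoing transition mass not exceeding one, a positive cohort
#' and horizon, and the willingness-to-pay threshold equal to three times
#' GDP per capita when both are supplied.
#'
#' @param config A `crc_config`.
#' @return A tibble with columns `field` and `message`; zero rows when the
#'   configuration is valid.
#' @examples
#' validate_config(crc_config())            # 0 rows
#' bad <- crc_config(validate = FALSE)
#' bad$initial$adenoma <- 0.9
#' bad$transitions$normal_to_adenoma <- 1.2
#' validate_config(bad)
#' @export
validate_config <- function(config) {
  v <- list()
  note <- function(field, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(field = field, message = message)
  }
  prob_in_01 <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      note(field, paste0(field, ": probability ", format(x),
                         " out of [0,1]"))
  }
  m <- config$model
  if (!is.numeric(m$horizon_cycles) || m$horizon_cycles < 0)
    note("model.horizon_cycles", "model.horizon_cycles: horizon must be >= 0")
  if (!is.numeric(m$cohort_size) || m$cohort_size <= 0)
    note("model.cohort_size", "model.cohort_size: cohort size must be > 0")
  if (!is.numeric(m$tunnel_years) || m$tunnel_years < 0)
    note("model.tunnel_years", "model.tunnel_years: must be >= 0")
  prob_in_01(m$discount_rate_costs, "model.discount_rate_costs")
  prob_in_01(m$discount_rate_effects, "model.discount_rate_effects")
  prob_in_01(m$other_cause_mortality, "model.other_cause_mortality")
  if (!is.null(m$wtp_threshold) && !is.null(m$gdp_per_capita) &&
      abs(m$wtp_threshold - 3 * m$gdp_per_capita) > 0.5)
    note("model.wtp_threshold",
         sprintf("model.wtp_threshold: %s != 3 x GDP per capita (%s)",
                 format(m$wtp_threshold), format(3 * m$gdp_per_capita)))

  fr <- unlist(config$initial)
  if (length(fr) != 6L || !setequal(names(fr), initial_categories()))
    note("initial", "initial: exactly six diagnosed-category fractions required")
  for (nm in names(fr)) prob_in_01(fr[[nm]], paste0("initial.", nm))
  if (abs(sum(fr) - 1) > 5e-4)
    note("initial", sprintf("initial: fractions sum %s != 1 (tolerance 5e-4)",
                            format(sum(fr))))

  tr <- config$transitions
  flat <- tr[setdiff(names(tr), "crc_followup_mortality")]
  for (nm in names(flat)) prob_in_01(flat[[nm]], paste0("transitions.", nm))
  for (nm in names(tr$crc_followup_mortality))
    prob_in_01(tr$crc_followup_mortality[[nm]],
               paste0("transitions.crc_followup_mortality.", nm))
  # per-source outgoing mass (residual is a self-loop, so must be <= 1)
  out_by_source <- list(
    normal = tr$normal_to_adenoma,
    adenoma = tr$adenoma_to_advanced,
    advanced_adenoma = tr$advanced_to_crc1,
    crc1_undiag = tr$crc1_to_crc2 + tr$crc1_diagnosis,
    crc2_undiag = tr$crc2_to_crc3 + tr$crc2_diagnosis,
    crc3_undiag = tr$crc3_to_crc4 + tr$crc3_diagnosis,
    crc4_undiag = tr$crc4_diagnosis
  )
  for (nm in names(out_by_source)) {
    if (is.numeric(out_by_source[[nm]]) && isTRUE(out_by_source[[nm]] > 1 + 1e-12))
      note(paste0("transitions.", nm),
           sprintf("transitions: outgoing mass from %s is %s > 1",
                   nm, format(out_by_source[[nm]])))
  }

  cc <- config$costs
  for (nm in c("screening_component_per_diagnosed", "colonoscopy_unit",
               "adenoma_treatment")) {
    if (!is.numeric(cc[[nm]]) || cc[[nm]] < 0)
      note(paste0("costs.", nm), paste0("costs.", nm, ": must be >= 0"))
  }
  for (nm in names(cc$treatment)) {
    if (!is.numeric(cc$treatment[[nm]]) || cc$treatment[[nm]] < 0)
      note(paste0("costs.treatment.", nm),
           paste0("costs.treatment.", nm, ": must be >= 0"))
  }
  if (!is.numeric(cc$exchange_rate_rmb_per_usd) ||
      cc$exchange_rate_rmb_per_usd <= 0)
    note("costs.exchange_rate_rmb_per_usd",
         "costs.exchange_rate_rmb_per_usd: must be > 0")

  u <- config$utilities
  for (nm in c("normal", "adenoma", "advanced_adenoma",
               "adenoma_followup", "advanced_adenoma_followup"))
    prob_in_01(u[[nm]], paste0("utilities.", nm))
  for (nm in names(u$crc)) prob_in_01(u$crc[[nm]], paste0("utilities.crc.", nm))
  if (is.numeric(u$normal) && u$normal != 1)
    note("utilities.normal", "utilities.normal: must equal 1")

  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(field = character(), message = character())
}

initial_categories <- function() {
  c("adenoma", "advanced_adenoma", crc_stages())
}

#' Read a model configuration from a YAML file
#'
#' The file holds the sections `model`, `initial`, `transitions`, `costs`
#' and `utilities` (plus optional `registry`), with the same keys as
#' [crc_config()]. All five core sections must be present; keys omitted
#' within a section fall back to the base-case defaults. The shipped
#' base-case file is
#' `system.file("extdata", "shcsp_base.yaml", package = "crcscreen")`.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `crc_config`.
#' @examples
#' path <- system.file("extdata", "shcsp_base.yaml", package = "crcscreen")
#' cfg <- load_config(path)
#' cfg$initial$adenoma
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw)) {
    rlang::abort(paste0(
      "configuration file is empty or not a mapping; required sections ",
      "missing: ", paste(required_sections(), collapse = ", ")))
  }
  missing <- setdiff(required_sections(), names(raw))
  if (length(missing)) {
    rlang::abort(paste0("configuration is missing required section(s): ",
                        paste(missing, collapse = ", ")))
  }
  known <- c(required_sections(), "registry")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    rlang::abort(paste0("unknown configuration section(s): ",
                        paste(unknown, collapse = ", ")))
  }
  do.call(crc_config, raw[intersect(names(raw), known)])
}

required_sections <- function() {
  c("model", "initial", "transitions", "costs", "utilities")
}

#' Write a model configuration to a YAML file
#'
#' Emits the configuration in a stable form (keys sorted within each
#' section, full numeric precision) so that writing and re-reading a
#' configuration round-trips to an equal object.
#'
#' @param config A `crc_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_config(crc_config(), f)
#' identical(load_config(f), crc_config())
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "crc_config"))
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sort_rec)
    } else x
  }
  out <- lapply(unclass(config), sort_rec)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.crc_config <- function(x, ...) {
  m <- x$model
  cat("<crc_config>\n")
  cat(sprintf("  cohort %s over %d annual cycles; discounting %s%% / %s%%%s\n",
              format(m$cohort_size, big.mark = ","), m$horizon_cycles,
              format(100 * m$discount_rate_costs),
              format(100 * m$discount_rate_effects),
              if (isTRUE(m$half_cycle_correction)) ", half-cycle corrected" else ""))
  cat(sprintf("  one-off screening cost per diagnosed: $%.2f; WTP threshold $%s\n",
              screening_oneoff(x), format(m$wtp_threshold, big.mark = ",")))
  cat(sprintf("  initial fractions: %s\n",
              paste(sprintf("%s %.4f", names(x$initial), unlist(x$initial)),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy a model configuration into a parameter table
#'
#' Flattens the configuration into one row per scalar parameter with a
#' dotted path (e.g. `transitions.crc1_to_crc2`), the representation used
#' by the sensitivity-analysis sweeps.
#'
#' @param x A `crc_config`.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @method tidy crc_config
#' @export
tidy.crc_config <- function(x, ...) {
  flat <- rapply(unclass(x), identity, classes = "ANY", how = "unlist")
  flat <- flat[vapply(flat, is.numeric, logical(1L)) |
                 vapply(flat, is.logical, logical(1L))]
  tibble::tibble(parameter = names(flat), value = as.numeric(unlist(flat)))
}

# fetch / replace a scalar parameter by dotted path (used by the OWSA)
config_get <- function(config, path) {
  purrr::pluck(config, !!!as.list(strsplit(path, ".", fixed = TRUE)[[1L]]))
}

config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  purrr::pluck(config, !!!as.list(keys)) <- value
  config
}
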