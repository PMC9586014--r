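#' Default one-way sensitivity-analysis sweeps
#'
#' The 12 standard sweeps: the discount rate (both cost and effect rates
#' moved together, with explicit bounds 0% and 5% rather than +/-25%),
#' the unit colonoscopy cost (the per-diagnosed allocation is recomputed
#' from the varied unit cost, leaving the initial-screening share fixed),
#' the five treatment costs, and five transition probabilities (normal to
#' adenoma, adenoma to advanced adenoma, and the three stage-progression
#' probabilities), each varied +/-25% from its base value with
#' probabilities clamped to \[0, 1\].
#'
#' @param config A `crc_config`.
#' @param rel Relative half-width of the default sweeps (0.25).
#' @return A tibble of sweep specifications: `parameter` (dotted
#'   configuration path, or `"discount_rate"` for the paired rates),
#'   `label`, `base`, `low`, `high`, `mode`.
#' @examples
#' default_sweeps(crc_config())
#' @export
default_sweeps <- function(config, rel = 0.25) {
  rel_sweep <- function(parameter, label, clamp = FALSE) {
    base <- config_get(config, parameter)
    lo <- base * (1 - rel)
    hi <- base * (1 + rel)
    if (clamp) {
      lo <- max(0, lo)
      hi <- min(1, hi)
    }
    tibble::tibble(parameter = parameter, label = label, base = base,
                   low = lo, high = hi, mode = "relative")
  }
  dplyr::bind_rows(
    tibble::tibble(parameter = "discount_rate", label = "Discount rate",
                   base = config$model$discount_rate_costs,
                   low = 0, high = 0.05, mode = "explicit"),
    rel_sweep("costs.colonoscopy_unit", "Colonoscopy per diagnosed patient"),
    rel_sweep("costs.treatment.advanced_adenoma",
              "Treatment: advanced adenoma"),
    rel_sweep("costs.treatment.crc1", "Treatment: CRC I"),
    rel_sweep("costs.treatment.crc2", "Treatment: CRC II"),
    rel_sweep("costs.treatment.crc3", "Treatment: CRC III"),
    rel_sweep("costs.treatment.crc4", "Treatment: CRC IV"),
    rel_sweep("transitions.normal_to_adenoma", "Normal - adenoma",
              clamp = TRUE),
    rel_sweep("transitions.adenoma_to_advanced",
              "Adenoma - advanced adenoma", clamp = TRUE),
    rel_sweep("transitions.crc1_to_crc2", "CRC I - CRC II", clamp = TRUE),
    rel_sweep("transitions.crc2_to_crc3", "CRC II - CRC III", clamp = TRUE),
    rel_sweep("transitions.crc3_to_crc4", "CRC III - CRC IV", clamp = TRUE)
  )
}

# substitute one swept value into the configuration and revalidate
apply_sweep <- function(config, parameter, value) {
  if (parameter == "discount_rate") {
    config$model$discount_rate_costs <- value
    config$model$discount_rate_effects <- value
  } else {
    config <- config_set(config, parameter, value)
  }
  v <- validate_config(config)
  if (nrow(v)) {
    rlang::abort(paste0("sweep of ", parameter, " at ", format(value),
                        " produces an invalid configuration: ",
                        paste(v$message, collapse = "; ")))
  }
  config
}

#' One-way sensitivity analysis
#'
#' Re-runs the full two-arm model once per sweep bound with the single
#' substituted value (all other parameters at base case) and records the
#' ICER per life year at the low and high bound. Rows are ordered by
#' descending ICER range, the tornado-diagram ordering.
#'
#' @param config A `crc_config` (the base case).
#' @param sweeps A sweep table from [default_sweeps()] (or a compatible
#'   tibble with `parameter`, `label`, `base`, `low`, `high`).
#' @return A `crc_owsa` tibble: `parameter`, `label`, `base`, `low`,
#'   `high`, `icer_base`, `icer_low`, `icer_high`, `range`, plus an
#'   attribute `threshold`.
#' @examples
#' cfg <- crc_config(model = list(horizon_cycles = 5L))
#' run_owsa(cfg, default_sweeps(cfg)[1:2, ])
#' @export
run_owsa <- function(config, sweeps = default_sweeps(config)) {
  base_icer <- glance(run_cea(config))$icer_ly
  icer_at <- function(parameter, value) {
    glance(run_cea(apply_sweep(config, parameter, value)))$icer_ly
  }
  out <- sweeps |>
    dplyr::mutate(
      icer_base = base_icer,
      icer_low = purrr::map2_dbl(.data$parameter, .data$low, icer_at),
      icer_high = purrr::map2_dbl(.data$parameter, .data$high, icer_at),
      range = abs(.data$icer_high - .data$icer_low)
    ) |>
    dplyr::arrange(dplyr::desc(.data$range))
  tibble::new_tibble(out, class = "crc_owsa",
                     threshold = config$model$wtp_threshold)
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars span the ICER at the low and high bound of each
#' parameter, ordered by range; the dashed line marks the base-case ICER
#' and the dotted line the willingness-to-pay threshold (drawn only when
#' it falls inside the plotted range).
#'
#' @param object A `crc_owsa` from [run_owsa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_owsa
#' @export
autoplot.crc_owsa <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(label = factor(.data$label, levels = rev(.data$label)))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$label, yend = .data$label),
      linewidth = 5, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = df$icer_base[1L], linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD per life year gained)", y = NULL,
                  title = "One-way sensitivity analysis")
  thr <- attr(object, "threshold")
  if (!is.null(thr) &&
      isTRUE(thr <= 1.2 * max(df$icer_low, df$icer_high, na.rm = TRUE))) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dotted")
  }
  p
}

#' Occupancy plot of a cohort trajectory
#'
#' Stacked-area view of the cohort fractions in each conceptual health
#' state over the model cycles.
#'
#' @param object A `crc_trajectory` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_trajectory
#' @export
autoplot.crc_trajectory <- function(object, ...) {
  df <- tidy(object, conceptual = TRUE) |>
    dplyr::mutate(state = factor(.data$state,
                                 levels = health_states()$state))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "cycle (years)", y = "cohort fraction",
                  title = paste0(object$arm, " arm"))
}
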