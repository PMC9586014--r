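#' Incremental cost-effectiveness ratio
#'
#' The plain quotient of incremental cost over incremental effect,
#' computed on unrounded arm totals. A (near-)zero incremental effect is
#' a dominance situation, not a division: the function returns `NA` and
#' comparison logic is handled by [cea_compare()].
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_effect Incremental effect (LYs or QALYs).
#' @return USD per effect unit, or `NA` when `delta_effect` is 0.
#' @examples
#' icer(10, 5)
#' @export
icer <- function(delta_cost, delta_effect) {
  ifelse(delta_effect == 0, NA_real_, delta_cost / delta_effect)
}

#' Compare the screening and no-screening arms
#'
#' Computes incremental cost, life years and QALYs (screening minus no
#' screening), the ICERs per LY and per QALY from the unrounded totals,
#' the dominance classification, and the verdict against the
#' willingness-to-pay threshold (cost-effective iff the ICER does not
#' exceed the threshold, in the standard costlier-and-better quadrant).
#'
#' @param screening,no_screening One-row `crc_arm_result` tibbles from
#'   [run_arm()], produced under the same configuration.
#' @param config The `crc_config` both arms were run with (supplies the
#'   threshold).
#' @return A `crc_cea` object; see [tidy.crc_cea()] and
#'   [glance.crc_cea()] for tabular views.
#' @examples
#' cfg <- crc_config()
#' cea <- cea_compare(run_arm(cfg, "screening"),
#'                    run_arm(cfg, "no_screening"), cfg)
#' glance(cea)
#' @export
cea_compare <- function(screening, no_screening, config) {
  stopifnot(inherits(screening, "crc_arm_result"),
            inherits(no_screening, "crc_arm_result"))
  if (identical(screening$arm, no_screening$arm)) {
    rlang::abort("the two results come from the same arm")
  }
  delta_cost <- screening$cost - no_screening$cost
  delta_ly <- screening$ly - no_screening$ly
  delta_qaly <- screening$qaly - no_screening$qaly
  threshold <- config$model$wtp_threshold

  flag <- dominance_flag(delta_cost, delta_ly)
  res <- list(
    screening = screening, no_screening = no_screening,
    delta_cost = delta_cost, delta_ly = delta_ly, delta_qaly = delta_qaly,
    icer_ly = if (flag == "tradeoff") icer(delta_cost, delta_ly) else NA_real_,
    icer_qaly = if (dominance_flag(delta_cost, delta_qaly) == "tradeoff")
      icer(delta_cost, delta_qaly) else NA_real_,
    dominance_flag = flag,
    threshold = threshold
  )
  res$verdict_ly <- verdict(flag, res$icer_ly, threshold)
  res$verdict_qaly <- verdict(dominance_flag(delta_cost, delta_qaly),
                              res$icer_qaly, threshold)
  structure(res, class = "crc_cea")
}

dominance_flag <- function(delta_cost, delta_effect) {
  if (delta_cost == 0 && delta_effect == 0) return("identical")
  if (delta_cost <= 0 && delta_effect >= 0) return("dominant")
  if (delta_cost >= 0 && delta_effect <= 0) return("dominated")
  "tradeoff"
}

verdict <- function(flag, icer_value, threshold) {
  switch(flag,
    identical = "identical",
    dominant = "dominant",
    dominated = "dominated",
    if (icer_value <= threshold) "cost-effective" else "not cost-effective"
  )
}

#' @export
print.crc_cea <- function(x, ...) {
  cat("<crc_cea>\n")
  if (x$dominance_flag == "tradeoff") {
    cat(sprintf(
      "  incremental cost $%.2fM for %.1f LYs and %.1f QALYs gained\n",
      x$delta_cost / 1e6, x$delta_ly, x$delta_qaly))
    cat(sprintf("  ICER $%.2f/LY, $%.2f/QALY vs threshold $%s: %s\n",
                x$icer_ly, x$icer_qaly,
                format(x$threshold, big.mark = ","), x$verdict_ly))
  } else {
    cat(sprintf("  %s (delta cost $%.2f, delta LY %.2f)\n",
                x$dominance_flag, x$delta_cost, x$delta_ly))
  }
  invisible(x)
}

#' Tidy a cost-effectiveness comparison into a report table
#'
#' One row per reported quantity with both arms side by side:
#' effectiveness block (deaths, LYs, QALYs, incremental LYs/QALYs),
#' costs block (totals and incremental, million USD), and the ICER block.
#' Rounding follows reporting practice: LYs/QALYs to 1 decimal, million
#' USD to 2 decimals, ICERs to 2 decimals, deaths to whole persons;
#' unrounded values stay in the `screening`/`no_screening` columns.
#'
#' @param x A `crc_cea`.
#' @param ... Unused.
#' @return A tibble with columns `block`, `quantity`, `screening`,
#'   `no_screening`, `screening_reported`, `no_screening_reported`.
#' @method tidy crc_cea
#' @export
tidy.crc_cea <- function(x, ...) {
  s <- x$screening
  ns <- x$no_screening
  row <- function(block, quantity, sv, nsv, digits) {
    tibble::tibble(
      block = block, quantity = quantity,
      screening = sv, no_screening = nsv,
      screening_reported = round_half_up(sv, digits),
      no_screening_reported = round_half_up(nsv, digits)
    )
  }
  dplyr::bind_rows(
    row("effectiveness", "deaths_crc", s$deaths_crc, ns$deaths_crc, 0L),
    row("effectiveness", "deaths_other", s$deaths_other, ns$deaths_other, 0L),
    row("effectiveness", "life_years", s$ly, ns$ly, 1L),
    row("effectiveness", "qalys", s$qaly, ns$qaly, 1L),
    row("effectiveness", "incremental_life_years", x$delta_ly, NA_real_, 1L),
    row("effectiveness", "incremental_qalys", x$delta_qaly, NA_real_, 1L),
    row("costs", "total_cost_musd", s$cost / 1e6, ns$cost / 1e6, 2L),
    row("costs", "incremental_cost_musd", x$delta_cost / 1e6, NA_real_, 2L),
    row("icer", "cost_per_ly_gained", x$icer_ly, NA_real_, 2L),
    row("icer", "cost_per_qaly_gained", x$icer_qaly, NA_real_, 2L)
  )
}

#' One-line summary of a cost-effectiveness comparison
#'
#' @param x A `crc_cea`.
#' @param ... Unused.
#' @return A one-row tibble: incremental quantities, ICERs, dominance
#'   flag, threshold and verdicts.
#' @method glance crc_cea
#' @export
glance.crc_cea <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost, delta_ly = x$delta_ly,
    delta_qaly = x$delta_qaly,
    icer_ly = x$icer_ly, icer_qaly = x$icer_qaly,
    dominance = x$dominance_flag, threshold = x$threshold,
    verdict_ly = x$verdict_ly, verdict_qaly = x$verdict_qaly
  )
}

#' Format a comparison as human-readable report lines
#'
#' @param x A `crc_cea`.
#' @return A character vector of report lines (also printed by
#'   `print`ing the result of this function via `cat`); write the
#'   [tidy.crc_cea()] table to CSV for the machine-readable form.
#' @examples
#' cfg <- crc_config(model = list(horizon_cycles = 5L))
#' cea <- cea_compare(run_arm(cfg, "screening"),
#'                    run_arm(cfg, "no_screening"), cfg)
#' cat(format_report(cea), sep = "\n")
#' @export
format_report <- function(x) {
  stopifnot(inherits(x, "crc_cea"))
  tab <- tidy(x)
  fmt <- function(v) ifelse(is.na(v), "-", format(v, big.mark = ","))
  lines <- c(
    "Cost-effectiveness of screening vs no screening",
    sprintf("%-28s %14s %14s", "", "screening", "no screening"),
    sprintf("%-28s %14s %14s", tab$quantity,
            fmt(tab$screening_reported), fmt(tab$no_screening_reported))
  )
  if (x$dominance_flag == "tradeoff") {
    lines <- c(lines, sprintf(
      "verdict: %s (ICER $%.2f/LY vs threshold $%s = 3 x GDP per capita)",
      x$verdict_ly, x$icer_ly, format(x$threshold, big.mark = ",")))
  } else {
    lines <- c(lines, sprintf("verdict: arms are %s; no ICER reported",
                              x$dominance_flag))
  }
  lines
}

#' Run both arms and compare them
#'
#' @param config A `crc_config`.
#' @return A `crc_cea` (see [cea_compare()]).
#' @examples
#' glance(run_cea(crc_config()))
#' @export
run_cea <- function(config = crc_config()) {
  cea_compare(run_arm(config, "screening"),
              run_arm(config, "no_screening"), config)
}
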