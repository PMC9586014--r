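#' Health states of the screening natural-history model
#'
#' The cohort model distinguishes 15 conceptual health states: normal
#' colorectal mucosa, low-risk adenoma, advanced adenoma (>= 10 mm),
#' the two post-polypectomy surveillance states ("follow-up", a 5-year
#' tunnel after endoscopic removal), undiagnosed colorectal cancer (CRC)
#' stages I-IV, post-treatment CRC follow-up stages I-IV, and the two
#' absorbing death states (CRC death, death from other causes).
#'
#' @return A tibble with one row per conceptual state and columns
#'   `state` (name), `tunnel_years` (0 for plain states, 5 for the two
#'   adenoma follow-up states by default), `absorbing`, and `group`
#'   (one of `"precancer"`, `"surveillance"`, `"crc_undiagnosed"`,
#'   `"crc_followup"`, `"death"`).
#' @examples
#' health_states()
#' @export
health_states <- function() {
  tibble::tibble(
    state = c(
      "normal", "adenoma", "advanced_adenoma",
      "adenoma_followup", "advanced_adenoma_followup",
      "crc1_undiag", "crc2_undiag", "crc3_undiag", "crc4_undiag",
      "crc1_followup", "crc2_followup", "crc3_followup", "crc4_followup",
      "death_crc", "death_other"
    ),
    tunnel_years = c(0L, 0L, 0L, 5L, 5L, rep(0L, 8L), 0L, 0L),
    absorbing = c(rep(FALSE, 13L), TRUE, TRUE),
    group = c(
      "precancer", "precancer", "precancer",
      "surveillance", "surveillance",
      rep("crc_undiagnosed", 4L), rep("crc_followup", 4L),
      "death", "death"
    )
  )
}

# stage label helpers used throughout the package
crc_stages <- function() paste0("crc", 1:4)

#' Expand tunnel states into a computable state space
#'
#' The two post-polypectomy follow-up states are tunnels: a member spends
#' a fixed number of annual cycles under surveillance and then returns to
#' the normal state. For matrix computation each tunnel is replaced by
#' `tunnel_years` sequential year-indexed sub-states; a surviving member
#' advances one sub-state per cycle and exits to `normal` after completing
#' the final year. Sub-states inherit the parent state's utility and
#' mortality.
#'
#' @param config A model configuration from [crc_config()] or
#'   [load_config()].
#' @return A tibble with one row per expanded state: `state` (expanded
#'   name, e.g. `"adenoma_followup_y3"`), `conceptual` (the parent among
#'   the 15 conceptual states), `tunnel_year` (NA for plain states), and
#'   `absorbing`. Every expanded state maps to exactly one conceptual
#'   state.
#' @examples
#' nrow(expand_state_space(crc_config()))  # 23 = 15 - 2 + 2 * 5
#' @export
expand_state_space <- function(config) {
  stopifnot(inherits(config, "crc_config"))
  tun <- config$model$tunnel_years
  hs <- health_states()
  rows <- purrr::pmap(hs, function(state, tunnel_years, absorbing, group) {
    if (tunnel_years == 0L) {
      tibble::tibble(
        state = state, conceptual = state,
        tunnel_year = NA_integer_, absorbing = absorbing
      )
    } else {
      yrs <- seq_len(tun)
      expanded <- paste0(state, "_y", yrs)
      parent <- rep(state, length(yrs))
      abs_flag <- rep(absorbing, length(yrs))
      tibble::tibble(
        state = expanded, conceptual = parent,
        tunnel_year = yrs, absorbing = abs_flag
      )
    }
  })
  dplyr::bind_rows(rows)
}
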