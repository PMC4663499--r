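# Protectiveness screening of guideline ecotoxicity threshold values (ETVs).

#' Flag guideline thresholds that do not protect a measured ICx
#'
#' An ecotoxicity threshold value (ETV) is protective of the assayed endpoint
#' only when it sits strictly below the ICx: `protective = etv < icx_value`.
#' An ETV equal to the ICx is flagged non-protective (the boundary is included
#' on the non-protective side). Missing ETVs propagate as `NA`
#' (not assessable). The rule is monotone: if a larger ETV is protective, any
#' smaller one for the same comparison is too.
#'
#' @param ic Data frame of ICx estimates with columns `herbicide`,
#'   `icx_level` (e.g. 10) and `icx_value` (µg/L).
#' @param guidelines Data frame of guideline sets in long format with columns
#'   `herbicide`, `source`, `protection_pct`, `etv_ugL`; defaults to the
#'   shipped guideline table.
#' @return A tibble with one row per (herbicide, source, protection level):
#'   the ETV, the ICx it is compared against, and `protective`.
#' @examples
#' ic <- tibble::tibble(herbicide = "diuron", icx_level = 10, icx_value = 1.2)
#' flag_protectiveness(ic)
#' @export
flag_protectiveness <- function(ic, guidelines = reference_guidelines()) {
  assert_df_has(ic, c("herbicide", "icx_level", "icx_value"), "ic")
  assert_df_has(guidelines, c("herbicide", "source", "protection_pct", "etv_ugL"),
                "guidelines")
  if (any(ic$icx_value <= 0, na.rm = TRUE)) {
    abort("ICx values must be positive (µg/L).", class = "seagrasstox_input_error")
  }
  tibble::as_tibble(guidelines) |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(ic),
                    dplyr::all_of(c("herbicide", "icx_level", "icx_value"))),
      by = "herbicide"
    ) |>
    dplyr::mutate(protective = .data$etv_ugL < .data$icx_value) |>
    dplyr::select(dplyr::all_of(c("herbicide", "source", "protection_pct",
                                  "etv_ugL", "icx_level", "icx_value", "protective")))
}
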