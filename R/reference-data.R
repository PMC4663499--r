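#' Reference tables shipped with the package
#'
#' Plain-text copies of the published acute-phytotoxicity compilation for the
#' seagrass *Halophila ovalis* leaf assay and the guideline threshold sets used
#' to assess them:
#'
#' * `"endpoints"` — fitted IC10/IC50 values (with 95% confidence intervals,
#'   R-squared and printed relative potency) per herbicide at 24 and 48 h.
#' * `"mixture_endpoints"` — IC10/IC50 of binary and 10-herbicide mixtures on
#'   the Toxic-Unit (TU) scale, with post-hoc letter groupings.
#' * `"guidelines"` — ecotoxicity threshold values (ETVs, µg/L) protecting
#'   99/95/90% of species under three guideline sets, in long format, with the
#'   printed protectiveness flag (`NA` where no ETV exists).
#' * `"properties"` — herbicide chemical class, log Kow, water solubility, CAS.
#' * `"cross_species"` — a literature compilation of comparable endpoints in
#'   other taxa; shipped for reference only, no computation uses it.
#'
#' @param table One of `"endpoints"`, `"mixture_endpoints"`, `"guidelines"`,
#'   `"properties"`, `"cross_species"`.
#' @return A tibble.
#' @examples
#' reference_endpoints()
#' reference_table("guidelines")
#' @export
reference_table <- function(table = c("endpoints", "mixture_endpoints", "guidelines",
                                      "properties", "cross_species")) {
  table <- match.arg(table)
  file <- switch(table,
    endpoints = "halophila_endpoints.csv",
    mixture_endpoints = "mixture_endpoints.csv",
    guidelines = "guideline_etvs.csv",
    properties = "herbicide_properties.csv",
    cross_species = "cross_species_endpoints.csv"
  )
  path <- system.file("extdata", file, package = "seagrasstox", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname reference_table
#' @export
reference_endpoints <- function() reference_table("endpoints")

#' @rdname reference_table
#' @export
reference_mixture_endpoints <- function() reference_table("mixture_endpoints")

#' @rdname reference_table
#' @export
reference_guidelines <- function() reference_table("guidelines")
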