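# Toxic Units, Concentration Addition, and mixture joint-action classification.
#
# A component's Toxic Unit is its concentration divided by its own IC50, so
# 1 TU is the concentration halving the endpoint for that component alone.
# The mixture dose scale is TU_sum = sum_i C_i / IC50_i; under Concentration
# Addition a mixture of same-mode-of-action toxicants reaches 50% inhibition
# at TU_sum = 1 regardless of composition.

#' Toxic-Unit basis table
#'
#' Builds the herbicide -> IC50 lookup defining 1 TU per component at a stated
#' exposure duration (24 h by default, the basis used to design the mixture
#' experiments even for slower-acting herbicides).
#'
#' @param endpoints Data frame with `herbicide`, `duration_h`, `ic50` columns;
#'   defaults to the shipped endpoint table.
#' @param duration Exposure duration (h) whose IC50s define 1 TU.
#' @param basis_note Free-text note recorded with the table.
#' @return A tibble of class `tu_table` with one row per herbicide.
#' @examples
#' tu_table()
#' @export
tu_table <- function(endpoints = reference_endpoints(), duration = 24,
                     basis_note = sprintf("1 TU = IC50 at %s h", duration)) {
  assert_df_has(endpoints, c("herbicide", "duration_h", "ic50"), "endpoints")
  out <- tibble::as_tibble(endpoints) |>
    dplyr::filter(.data$duration_h == duration) |>
    dplyr::select(dplyr::all_of(c("herbicide", "ic50", "duration_h")))
  if (nrow(out) == 0) {
    abort(sprintf("No IC50 entries at %s h.", duration), class = "seagrasstox_input_error")
  }
  if (anyDuplicated(out$herbicide)) {
    abort("One IC50 entry per herbicide per duration is required.",
          class = "seagrasstox_input_error")
  }
  if (any(out$ic50 <= 0)) {
    abort("All IC50 values must be positive.", class = "seagrasstox_input_error")
  }
  attr(out, "basis_note") <- basis_note
  class(out) <- c("tu_table", class(out))
  out
}

tu_lookup <- function(table, herbicides) {
  pos <- match(herbicides, table$herbicide)
  if (anyNA(pos)) {
    abort(sprintf("Herbicide(s) missing from the Toxic-Unit table: %s.",
                  paste(unique(herbicides[is.na(pos)]), collapse = ", ")),
          class = "seagrasstox_lookup_error")
  }
  table$ic50[pos]
}

#' Convert a concentration to Toxic Units
#'
#' TU = concentration / IC50, so a component at its own IC50 contributes 1 TU.
#'
#' @param concentration Concentration(s), µg/L.
#' @param ic50 The component's IC50 defining 1 TU, µg/L.
#' @return Numeric TU value(s).
#' @examples
#' toxic_units(4.3, 4.3) # 1
#' toxic_units(11, 22)   # 0.5
#' @export
toxic_units <- function(concentration, ic50) {
  if (any(!is.finite(ic50) | ic50 <= 0)) {
    abort("IC50 defining 1 TU must be positive.", class = "seagrasstox_input_error")
  }
  if (any(!is.finite(concentration) | concentration < 0)) {
    abort("Concentrations must be non-negative.", class = "seagrasstox_input_error")
  }
  concentration / ic50
}

#' Total Toxic Units of a mixture
#'
#' TU_sum = sum_i C_i / IC50_i over the mixture's components. Linear over
#' disjoint component lists and 0 for an empty mixture.
#'
#' @param components Data frame with columns `herbicide` and `concentration`
#'   (µg/L).
#' @param table A [tu_table()] supplying each component's IC50.
#' @return A single TU_sum value.
#' @examples
#' tab <- tu_table()
#' tu_sum(tibble::tibble(herbicide = c("diuron", "atrazine"),
#'                       concentration = c(2.15, 11)), tab)
#' @export
tu_sum <- function(components, table) {
  assert_df_has(components, c("herbicide", "concentration"), "components")
  if (nrow(components) == 0) return(0)
  sum(toxic_units(components$concentration, tu_lookup(table, components$herbicide)))
}

#' Specify a TU-space mixture design
#'
#' @param components Character vector of herbicide names.
#' @param proportions Each component's share of the Toxic-Unit contribution
#'   (not of mass concentration); defaults to equal shares. Must be positive
#'   and sum to 1.
#' @param tu_levels TU_sum dilution series; default the assay design
#'   `c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 4)`.
#' @param duration TU-basis exposure duration (h).
#' @param mixture_id Label; defaults to the components joined with `+`.
#' @return A `mixture_spec` object.
#' @examples
#' mixture_spec(c("diuron", "atrazine"))
#' @export
mixture_spec <- function(components, proportions = NULL,
                         tu_levels = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 4),
                         duration = 24, mixture_id = NULL) {
  stopifnot(is.character(components), length(components) >= 1)
  if (is.null(proportions)) proportions <- rep(1 / length(components), length(components))
  if (length(proportions) != length(components) || any(proportions <= 0) ||
      abs(sum(proportions) - 1) > 1e-8) {
    abort("Proportions must be positive, one per component, and sum to 1.",
          class = "seagrasstox_input_error")
  }
  pos <- tu_levels[tu_levels > 0]
  if (any(tu_levels < 0) || is.unsorted(pos, strictly = TRUE)) {
    abort("TU levels must be non-negative and strictly increasing after the 0 control.",
          class = "seagrasstox_input_error")
  }
  structure(
    list(components = components, proportions = proportions,
         tu_levels = tu_levels, duration = duration,
         mixture_id = mixture_id %||% paste(components, collapse = "+")),
    class = "mixture_spec"
  )
}

#' Per-component dosing table for a TU dilution series
#'
#' At TU_sum level L, component i with TU proportion p_i is dosed at
#' C_i = L * p_i * IC50_i, so that recomputing [tu_sum()] on any row group
#' returns L exactly.
#'
#' @param spec A [mixture_spec()].
#' @param table A [tu_table()] on the same duration basis.
#' @return A tibble: `mixture_id`, `tu_level`, `component`,
#'   `concentration_ugL`, `tu_component`.
#' @examples
#' design_mixture_series(mixture_spec(c("diuron", "atrazine")), tu_table())
#' @export
design_mixture_series <- function(spec, table) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(table$duration_h) && any(table$duration_h != spec$duration)) {
    abort("Toxic-Unit basis duration does not match the mixture specification.",
          class = "seagrasstox_basis_error")
  }
  ic50 <- tu_lookup(table, spec$components)
  tidyr::expand_grid(tu_level = spec$tu_levels,
                     component = spec$components) |>
    dplyr::mutate(
      mixture_id = spec$mixture_id,
      prop = spec$proportions[match(.data$component, spec$components)],
      ic50 = ic50[match(.data$component, spec$components)],
      tu_component = .data$tu_level * .data$prop,
      concentration_ugL = .data$tu_component * .data$ic50
    ) |>
    dplyr::select(dplyr::all_of(c("mixture_id", "tu_level", "component",
                                  "concentration_ugL", "tu_component")))
}

#' Concentration-Addition expectation for a mixture
#'
#' Under Concentration Addition the expected mixture response at TU_sum = s is
#' the reference single-compound response evaluated at s on the TU scale; with
#' bottom 0 and top 100 the expectation at s = 1 is exactly 50%.
#'
#' @param reference_fit A `logistic_fit` whose `dose_scale` is `"TU"`.
#' @return A function mapping TU_sum values to expected percent inhibition.
#' @export
ca_expected_curve <- function(reference_fit) {
  stopifnot(inherits(reference_fit, "logistic_fit"))
  if (!identical(reference_fit$dose_scale, "TU")) {
    abort("The reference fit must be on the Toxic-Unit scale.",
          class = "seagrasstox_basis_error")
  }
  function(tu_sum) predict(reference_fit, tu_sum)
}

#' Percent by which one mixture IC50 sits below a reference's
#'
#' 100 * (reference - value) / reference, the figure used when reporting that
#' one mixture's IC50 (TU_sum) is x% lower than a sham reference's.
#'
#' @param value,reference IC50s on a common scale.
#' @return Percent difference (positive when `value < reference`).
#' @examples
#' percent_below(0.85, 0.90) # ~5.6
#' @export
percent_below <- function(value, reference) {
  100 * (reference - value) / reference
}

#' Classify mixture joint action against sham reference mixtures
#'
#' The mixture's TU-scale IC50 is compared with sham reference mixtures
#' (compounds "mixed" with themselves, whose TU response anchors additivity)
#' by pairwise extra-sum-of-squares F-tests. The significance test dominates
#' the point estimate: the mixture is `additive` unless its IC50 differs
#' significantly from every supplied reference, in which case it is
#' `synergistic` when IC50 (TU_sum) < 1 and `antagonistic` when > 1. With no
#' references the fallback rule classifies by whether the IC50's confidence
#' interval contains 1 (flagged in the result).
#'
#' @param mixture_fit A `logistic_fit` of the mixture on the TU scale.
#' @param references A list of TU-scale `logistic_fit` reference mixtures
#'   (may be empty).
#' @param alpha Significance level for the pairwise comparisons.
#' @param conf Confidence level for the reported ICx intervals.
#' @return An `additivity_result`: `mixture_id`, `ic50_tu` with CI, `ic10_tu`,
#'   a `comparisons` tibble of the pairwise tests, `classification`, and
#'   whether the CI fallback was used. `tidy()` returns a one-row summary.
#' @export
classify_additivity <- function(mixture_fit, references = list(), alpha = 0.05,
                                conf = 0.95) {
  stopifnot(inherits(mixture_fit, "logistic_fit"))
  if (!identical(mixture_fit$dose_scale, "TU")) {
    abort("Mixture fit must be on the Toxic-Unit scale.", class = "seagrasstox_basis_error")
  }
  for (r in references) {
    stopifnot(inherits(r, "logistic_fit"))
    if (!identical(r$dose_scale, "TU")) {
      abort("Reference fits must share the Toxic-Unit basis.",
            class = "seagrasstox_basis_error")
    }
  }
  ic50 <- invert_icx(mixture_fit, 50, conf = conf)
  ic10 <- tryCatch(invert_icx(mixture_fit, 10, conf = conf),
                   error = function(e) NULL)
  mixture_id <- mixture_fit$treatment_id %||% "mixture"

  fallback <- length(references) == 0
  if (fallback) {
    comparisons <- tibble::tibble(curve1 = character(), curve2 = character(),
                                  statistic = numeric(), df1 = integer(),
                                  df2 = integer(), p.value = numeric(),
                                  significant = logical())
    not_additive <- !(ic50$ci_low <= 1 && 1 <= ic50$ci_high)
  } else {
    ref_names <- purrr::imap_chr(references, function(r, i) {
      if (!is.na(r$treatment_id)) r$treatment_id else paste0("reference", i)
    })
    comparisons <- purrr::map2_dfr(references, ref_names, function(r, nm) {
      pr <- ess_ftest(setNames(list(mixture_fit$data, r$data), c(mixture_id, nm)),
                      sharing = "shared_bth")
      tibble::tibble(curve1 = mixture_id, curve2 = nm,
                     statistic = pr$statistic, df1 = pr$df1, df2 = pr$df2,
                     p.value = pr$p.value, significant = pr$p.value < alpha)
    })
    not_additive <- all(comparisons$significant)
  }
  classification <- if (!not_additive) {
    "additive"
  } else if (ic50$estimate < 1) "synergistic" else "antagonistic"

  structure(
    list(mixture_id = mixture_id,
         ic50_tu = ic50$estimate, ic50_ci = c(ic50$ci_low, ic50$ci_high),
         ic10_tu = if (is.null(ic10)) NA_real_ else ic10$estimate,
         ic10_ci = if (is.null(ic10)) c(NA_real_, NA_real_) else c(ic10$ci_low, ic10$ci_high),
         comparisons = comparisons, classification = classification,
         alpha = alpha, ci_fallback = fallback,
         tu_basis = mixture_fit$duration),
    class = "additivity_result"
  )
}

#' @export
print.additivity_result <- function(x, ...) {
  cat("Mixture joint-action classification:", x$mixture_id, "\n")
  cat(sprintf("  IC50 = %.3f TU_sum (%.3f-%.3f), IC10 = %.3f TU_sum\n",
              x$ic50_tu, x$ic50_ci[1], x$ic50_ci[2], x$ic10_tu))
  cat("  classification:", x$classification,
      if (x$ci_fallback) "(CI-contains-1 fallback; no references supplied)" else "", "\n")
  if (nrow(x$comparisons) > 0) {
    cat(sprintf("  vs %s: p = %.3g%s\n", x$comparisons$curve2, x$comparisons$p.value,
                ifelse(x$comparisons$significant, " *", "")))
  }
  invisible(x)
}

#' @method tidy additivity_result
#' @export
tidy.additivity_result <- function(x, ...) {
  tibble::tibble(
    mixture_id = x$mixture_id,
    ic10_tu = x$ic10_tu,
    ic50_tu = x$ic50_tu,
    ic50_lo = x$ic50_ci[1],
    ic50_hi = x$ic50_ci[2],
    classification = x$classification,
    n_references = nrow(x$comparisons),
    min_p = if (nrow(x$comparisons) > 0) min(x$comparisons$p.value) else NA_real_,
    ci_fallback = x$ci_fallback
  )
}
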