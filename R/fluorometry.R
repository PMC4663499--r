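# PAM-fluorometry endpoints and QC for the miniature leaf assay.

#' Quantum-yield endpoints from chlorophyll fluorescence
#'
#' `effective_quantum_yield()` computes the light-adapted effective quantum
#' yield of photosystem II, dF/Fm' = (Fm' - F)/Fm'. `maximum_quantum_yield()`
#' computes the dark-adapted maximum quantum yield Fv/Fm = (Fm - F0)/Fm.
#' Both are dimensionless fractions in \[0, 1\] and scale-invariant: rescaling
#' both fluorescence readings by the same positive constant leaves the yield
#' unchanged.
#'
#' @param f Minimum fluorescence under illumination (`F`), arbitrary units.
#' @param fm_prime Light-adapted maximum fluorescence (`Fm'`), same units.
#' @param f0 Dark-adapted minimum fluorescence (`F0`).
#' @param fm Dark-adapted maximum fluorescence (`Fm`).
#' @param well Optional well/leaf labels used in error messages.
#' @return A numeric vector of yields.
#' @examples
#' effective_quantum_yield(0.35, 0.50) # 0.30
#' maximum_quantum_yield(0.105, 0.300) # 0.65, the screening threshold
#' @export
effective_quantum_yield <- function(f, fm_prime, well = NULL) {
  check_fluorescence_pair(f, fm_prime, c("F", "Fm'"), well)
  (fm_prime - f) / fm_prime
}

#' @rdname effective_quantum_yield
#' @export
maximum_quantum_yield <- function(f0, fm, well = NULL) {
  check_fluorescence_pair(f0, fm, c("F0", "Fm"), well)
  (fm - f0) / fm
}

check_fluorescence_pair <- function(lo, hi, labels, well) {
  bad <- !is.finite(hi) | hi <= 0 | !is.finite(lo) | lo < 0 | lo > hi
  if (any(bad)) {
    where <- if (!is.null(well)) paste0(" (well ", paste(well[bad], collapse = ", "), ")") else ""
    abort(
      sprintf("Invalid fluorescence pair: need %s > 0 and 0 <= %s <= %s%s.",
              labels[2], labels[1], labels[2], where),
      class = "seagrasstox_measurement_error"
    )
  }
  invisible(NULL)
}

#' Percent inhibition of a quantum yield relative to the solvent control
#'
#' Inhibition (%) = 100 * (Y_control - Y_sample) / Y_control. Stimulation
#' (sample yield above the control) yields a negative value which is preserved,
#' not clipped — truncating at zero would bias the lower asymptote of a
#' subsequent logistic fit.
#'
#' @param y_sample Sample yield(s), a fraction in \[0, 1\].
#' @param y_control Control yield, a positive fraction (typically the mean
#'   solvent-control yield of the same batch and timepoint).
#' @return Numeric percent inhibition, possibly negative.
#' @examples
#' percent_inhibition(0.35, 0.70) # 50
#' percent_inhibition(0.77, 0.70) # -10, stimulation
#' @export
percent_inhibition <- function(y_sample, y_control) {
  if (any(!is.finite(y_control) | y_control <= 0)) {
    abort("Control yield must be positive; the control batch is unusable.",
          class = "seagrasstox_qc_error")
  }
  100 * (y_control - y_sample) / y_control
}

#' Screen leaves on dark-adapted maximum quantum yield
#'
#' Leaves enter an assay only when their dark-adapted Fv/Fm strictly exceeds
#' `threshold` (default 0.65), indicating an intact and efficient photosystem
#' II apparatus. Records lacking dark-adapted readings cannot be screened and
#' are rejected with reason `"unscreened"`. The two pieces of the result
#' partition the input: every row appears exactly once.
#'
#' @param records A data frame of well records with columns `F0` and `Fm`
#'   (plus any identifying columns, passed through).
#' @param threshold Strict lower bound on Fv/Fm; default 0.65.
#' @return The input tibble with columns `fvfm`, `screen_pass` (logical) and
#'   `screen_reason` (`NA` for accepted leaves) appended.
#' @examples
#' leaves <- tibble::tibble(leaf_id = c("a", "b"), F0 = c(0.09, 0.14), Fm = c(0.3, 0.3))
#' screen_leaves(leaves)
#' @export
screen_leaves <- function(records, threshold = 0.65) {
  assert_df_has(records, c("F0", "Fm"), "records")
  assert_scalar_number(threshold, "threshold", 0, 1)
  out <- tibble::as_tibble(records)
  screenable <- is.finite(out$F0) & is.finite(out$Fm) & out$Fm > 0 & out$F0 >= 0 & out$F0 <= out$Fm
  fvfm <- rep(NA_real_, nrow(out))
  fvfm[screenable] <- (out$Fm[screenable] - out$F0[screenable]) / out$Fm[screenable]
  pass <- !is.na(fvfm) & fvfm > threshold
  reason <- dplyr::case_when(
    pass ~ NA_character_,
    !screenable ~ "unscreened",
    .default = sprintf("Fv/Fm %.3f <= %.2f", fvfm, threshold)
  )
  out$fvfm <- fvfm
  out$screen_pass <- pass
  out$screen_reason <- reason
  out
}

#' Control-drift quality control over the assay duration
#'
#' Solvent-control leaves are re-measured at 0, 24 and 48 h; the assay is valid
#' only while the mean Fv/Fm has declined by less than `max_drop` percent
#' (default 8.5) from the 0 h baseline at every later timepoint.
#'
#' @param control_records Data frame of solvent-control wells with columns
#'   `timepoint_h`, `F0`, `Fm`.
#' @param max_drop Maximum tolerated percent decline from baseline.
#' @return A tibble with one row per timepoint: `timepoint_h`, `mean_fvfm`,
#'   `drop_pct` (decline from baseline, %) and `pass`. The overall verdict is
#'   attached as attribute `"pass"`.
#' @export
control_drift_qc <- function(control_records, max_drop = 8.5) {
  assert_df_has(control_records, c("timepoint_h", "F0", "Fm"), "control_records")
  assert_scalar_number(max_drop, "max_drop", 0, 100)
  out <- tibble::as_tibble(control_records) |>
    dplyr::mutate(fvfm = maximum_quantum_yield(.data$F0, .data$Fm)) |>
    dplyr::summarise(mean_fvfm = mean(.data$fvfm), n = dplyr::n(),
                     .by = "timepoint_h") |>
    dplyr::arrange(.data$timepoint_h)
  if (!any(out$timepoint_h == 0)) {
    abort("Control-drift QC needs a 0 h baseline measurement.",
          class = "seagrasstox_qc_error")
  }
  baseline <- out$mean_fvfm[out$timepoint_h == 0][1]
  if (!is.finite(baseline) || baseline <= 0) {
    abort("Baseline control Fv/Fm must be positive.", class = "seagrasstox_qc_error")
  }
  out$drop_pct <- 100 * (baseline - out$mean_fvfm) / baseline
  out$pass <- out$timepoint_h == 0 | out$drop_pct < max_drop
  attr(out, "pass") <- all(out$pass)
  attr(out, "max_drop") <- max_drop
  out
}

#' Tidy endpoint table from a raw plate table
#'
#' Converts well-level fluorescence to quantum yields and percent inhibition of
#' dF/Fm' relative to the mean solvent-control yield of the same group
#' (by default the same plate and timepoint; readings within ±1 h of a nominal
#' 0/24/48 h timepoint are binned to the nominal value first).
#'
#' @param plate Data frame in the plate schema: `plate_id`, `well_id`,
#'   `leaf_id`, `treatment_id`, `timepoint_h`, `F`, `Fm_prime`, optional `F0`,
#'   `Fm`, and `is_control` (0/1 or logical).
#' @param control_by Grouping columns within which the solvent-control mean is
#'   taken. Default `c("plate_id", "timepoint_h")`.
#' @param nominal_timepoints Nominal reading times (h) used for binning.
#' @return A tibble with `leaf_id`, `treatment_id`, `timepoint_h`, `dY`
#'   (dF/Fm'), `FvFm` (NA when dark-adapted readings are absent) and
#'   `inhibition_pct`.
#' @export
plate_endpoints <- function(plate, control_by = c("plate_id", "timepoint_h"),
                            nominal_timepoints = c(0, 24, 48)) {
  assert_df_has(plate, c("plate_id", "well_id", "leaf_id", "treatment_id",
                         "timepoint_h", "F", "Fm_prime", "is_control"), "plate")
  out <- tibble::as_tibble(plate) |>
    dplyr::mutate(
      timepoint_h = bin_timepoints(.data$timepoint_h, nominal_timepoints),
      dY = effective_quantum_yield(.data$F, .data$Fm_prime, well = .data$well_id),
      FvFm = if (all(c("F0", "Fm") %in% names(plate))) {
        ifelse(is.finite(.data$F0) & is.finite(.data$Fm) & .data$Fm > 0,
               (.data$Fm - .data$F0) / .data$Fm, NA_real_)
      } else NA_real_,
      is_control = as.logical(.data$is_control)
    )
  controls <- out |>
    dplyr::filter(.data$is_control) |>
    dplyr::summarise(control_dY = mean(.data$dY), .by = dplyr::all_of(control_by))
  if (nrow(controls) == 0) {
    abort("No solvent-control wells found; cannot normalise inhibition.",
          class = "seagrasstox_qc_error")
  }
  out <- dplyr::left_join(out, controls, by = control_by)
  if (any(is.na(out$control_dY))) {
    abort("Some groups have no solvent control; adjust `control_by`.",
          class = "seagrasstox_qc_error")
  }
  out |>
    dplyr::mutate(inhibition_pct = percent_inhibition(.data$dY, .data$control_dY)) |>
    dplyr::select(dplyr::all_of(c("leaf_id", "treatment_id", "timepoint_h",
                                  "dY", "FvFm", "inhibition_pct", "is_control")))
}

bin_timepoints <- function(t, nominal, tol = 1) {
  for (n in nominal) t[abs(t - n) <= tol] <- n
  t
}
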