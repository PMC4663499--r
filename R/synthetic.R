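# Synthetic bioassay generator reproducing the study design: 12-well plates,
# nine replicate leaves per concentration, solvent controls, a geometric
# dilution series per herbicide and a Toxic-Unit series for mixtures.

#' Define a synthetic assay scenario
#'
#' Collects the design and statistical structure of a simulated leaf assay:
#' the true four-parameter logistic curve per herbicide, the dilution series,
#' replication, replicate noise and the solvent-control yield. Defaults follow
#' the assay design: nine replicate leaves per concentration, a 7-point
#' geometric dose ladder spanning IC50/30 to 30*IC50 plus a solvent control,
#' Gaussian replicate noise of 5 inhibition points (which reproduces the
#' R-squared ~0.98-0.99 typical of these assays) and a healthy-leaf control
#' yield of 0.70.
#'
#' @param truths Data frame with columns `herbicide`, `bottom`, `top`, `hill`,
#'   `ic50`, `duration_h`. Defaults to the shipped endpoint table's IC50s with
#'   bottom 0, top 100 and hill 1.
#' @param dose_series Optional named list of per-herbicide dose vectors (µg/L,
#'   excluding the control); `NULL` means the automatic geometric ladder.
#' @param n_replicates Replicate leaves per concentration (default 9).
#' @param noise_sd Replicate noise, sd in inhibition points, for the
#'   `"inhibition"` noise model (default 5).
#' @param noise_model `"inhibition"` (homoscedastic Gaussian on the inhibition
#'   scale, default) or `"yield"` (Gaussian on the yield scale, sd `yield_sd`,
#'   inducing heteroscedastic inhibition noise).
#' @param yield_sd Yield-scale noise sd for `noise_model = "yield"`.
#' @param control_yield Solvent-control effective quantum yield (default 0.70).
#' @param deviation_factor Departure from Concentration Addition in mixture
#'   simulations: each nominal TU acts as `deviation_factor` TU (1 = exact CA).
#' @param seed Default seed used when a simulation call supplies none.
#' @return An `assay_scenario` object.
#' @export
assay_scenario <- function(truths = default_truths(), dose_series = NULL,
                           n_replicates = 9, noise_sd = 5,
                           noise_model = c("inhibition", "yield"),
                           yield_sd = 0.03, control_yield = 0.70,
                           deviation_factor = 1, seed = NULL) {
  assert_df_has(truths, c("herbicide", "bottom", "top", "hill", "ic50", "duration_h"),
                "truths")
  noise_model <- match.arg(noise_model)
  stopifnot(n_replicates >= 1)
  assert_scalar_number(noise_sd, "noise_sd", 0, Inf, strict = TRUE)
  assert_scalar_number(yield_sd, "yield_sd", 0, Inf, strict = TRUE)
  assert_scalar_number(control_yield, "control_yield", 0, 1)
  if (control_yield <= 0) abort("`control_yield` must be positive.",
                                class = "seagrasstox_input_error")
  assert_scalar_number(deviation_factor, "deviation_factor", 0, Inf, strict = TRUE)
  structure(
    list(truths = tibble::as_tibble(truths), dose_series = dose_series,
         n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
         noise_model = noise_model, yield_sd = yield_sd,
         control_yield = control_yield, deviation_factor = deviation_factor,
         seed = seed),
    class = "assay_scenario"
  )
}

#' @rdname assay_scenario
#' @param duration_h Durations (h) to keep from the endpoint table.
#' @param endpoints Endpoint table supplying the true IC50s.
#' @export
default_truths <- function(duration_h = c(24, 48), endpoints = reference_endpoints()) {
  tibble::as_tibble(endpoints) |>
    dplyr::filter(.data$duration_h %in% !!duration_h) |>
    dplyr::transmute(
      herbicide = .data$herbicide,
      bottom = 0, top = 100, hill = 1,
      ic50 = .data$ic50,
      duration_h = .data$duration_h
    )
}

scenario_truth <- function(scenario, herbicide, duration) {
  row <- scenario$truths[scenario$truths$herbicide == herbicide &
                           scenario$truths$duration_h == duration, , drop = FALSE]
  if (nrow(row) == 0) {
    abort(sprintf("No truth curve for '%s' at %s h in the scenario.", herbicide, duration),
          class = "seagrasstox_lookup_error")
  }
  row[1, , drop = FALSE]
}

auto_dose_series <- function(ic50, n = 7, span = 30) {
  10^seq(log10(ic50 / span), log10(ic50 * span), length.out = n)
}

add_noise <- function(mean_inhibition, scenario) {
  if (scenario$noise_model == "inhibition") {
    mean_inhibition + rnorm(length(mean_inhibition), 0, scenario$noise_sd)
  } else {
    yc <- scenario$control_yield
    y <- yc * (1 - mean_inhibition / 100) + rnorm(length(mean_inhibition), 0, scenario$yield_sd)
    y <- pmin(pmax(y, 0), 1)
    100 * (yc - y) / yc
  }
}

#' Simulate a single-herbicide concentration-response assay
#'
#' Draws per-replicate percent inhibition as the scenario's true logistic
#' curve plus independent Gaussian noise; controls (dose 0) have mean 0.
#' Identical scenario and seed give identical output.
#'
#' @param scenario An [assay_scenario()].
#' @param herbicide Herbicide name present in `scenario$truths`.
#' @param duration Exposure duration (h); must match a truth row.
#' @param seed Seed for this draw; defaults to the scenario seed.
#' @return A tibble of observations: `treatment_id`, `dose` (µg/L),
#'   `replicate`, `duration`, `inhibition`, `dose_scale`.
#' @examples
#' sc <- assay_scenario(seed = 1)
#' sim <- simulate_single_assay(sc, "diuron")
#' head(sim)
#' @export
simulate_single_assay <- function(scenario, herbicide, duration = 24,
                                  seed = scenario$seed) {
  stopifnot(inherits(scenario, "assay_scenario"))
  truth <- scenario_truth(scenario, herbicide, duration)
  doses <- scenario$dose_series[[herbicide]] %||% auto_dose_series(truth$ic50)
  grid <- tidyr::expand_grid(dose = c(0, doses),
                             replicate = seq_len(scenario$n_replicates))
  mean_i <- ifelse(
    grid$dose == 0, 0,
    fourpl_mean(log10(pmax(grid$dose, .Machine$double.xmin)),
                truth$bottom, truth$top, truth$hill, log10(truth$ic50))
  )
  with_seed_if(seed, {
    tibble::tibble(
      treatment_id = herbicide,
      dose = grid$dose,
      replicate = grid$replicate,
      duration = duration,
      inhibition = add_noise(mean_i, scenario),
      dose_scale = "concentration"
    )
  })
}

#' Simulate raw well-level plate records
#'
#' Converts simulated yields into raw fluorescence pairs so the fluorometry
#' stage can be exercised end-to-end: the effective yield is the control yield
#' scaled down by the simulated inhibition (clipped to \[0, 1\]; clip events are
#' counted in attribute `"n_clipped"`), `Fm'` carries an arbitrary positive
#' instrument scale, and `F = Fm' * (1 - yield)`. Dark-adapted pairs are built
#' the same way from `fvfm` so screening behaves as configured. Wells are laid
#' out on 12-well plates with solvent controls included.
#'
#' @inheritParams simulate_single_assay
#' @param fvfm Dark-adapted Fv/Fm given to every leaf (default 0.70, which
#'   passes the 0.65 screen); supply a lower value to simulate screen failures.
#' @param fm_prime_scale Instrument scale of the light-adapted maximum
#'   fluorescence.
#' @return A tibble of well records in the plate schema (`plate_id`,
#'   `well_id`, `leaf_id`, `treatment_id`, `timepoint_h`, `F`, `Fm_prime`,
#'   `F0`, `Fm`, `is_control`, plus `dose`).
#' @export
simulate_raw_plate <- function(scenario, herbicide, duration = 24,
                               seed = scenario$seed, fvfm = 0.70,
                               fm_prime_scale = 0.5) {
  obs <- simulate_single_assay(scenario, herbicide, duration, seed)
  yc <- scenario$control_yield
  y_raw <- yc * (1 - obs$inhibition / 100)
  y <- pmin(pmax(y_raw, 0), 1)
  n_clipped <- sum(y != y_raw)
  n <- nrow(obs)
  fm <- fm_prime_scale * 1.2   # dark-adapted maximum sits above the light-adapted one
  out <- tibble::tibble(
    plate_id = sprintf("plate%02d", (seq_len(n) - 1) %/% 12 + 1),
    well_id = sprintf("%s%d", LETTERS[(seq_len(n) - 1) %% 3 + 1], (seq_len(n) - 1) %% 4 + 1),
    leaf_id = sprintf("%s_leaf%03d", herbicide, seq_len(n)),
    treatment_id = ifelse(obs$dose == 0, "solvent_control", herbicide),
    timepoint_h = duration,
    F = fm_prime_scale * (1 - y),
    Fm_prime = fm_prime_scale,
    F0 = fm * (1 - fvfm),
    Fm = fm,
    is_control = obs$dose == 0,
    dose = obs$dose
  )
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Simulate a mixture assay on the Toxic-Unit scale
#'
#' The effective dose at nominal TU_sum level s is `deviation_factor * s`; the
#' response mean comes from a reference TU-scale truth curve (bottom 0, top
#' 100, hill as given, IC50 = 1 TU under exact Concentration Addition), with
#' replicate noise as in [simulate_single_assay()]. `deviation_factor = 2`
#' makes each nominal TU act as 2 TU, i.e. a synergistic mixture with a true
#' IC50 of 0.5 TU_sum.
#'
#' @param scenario An [assay_scenario()]; `deviation_factor` and the noise
#'   settings are taken from it.
#' @param spec A [mixture_spec()].
#' @param table A [tu_table()] on the same duration basis as `spec`.
#' @param reference_hill Hill slope of the reference TU-scale truth curve.
#' @param seed Seed for this draw.
#' @return A tibble of observations with `dose` = nominal TU_sum and
#'   `dose_scale = "TU"`.
#' @export
simulate_mixture_assay <- function(scenario, spec, table, reference_hill = 1,
                                   seed = scenario$seed) {
  stopifnot(inherits(scenario, "assay_scenario"), inherits(spec, "mixture_spec"))
  # Validates component membership and the duration basis.
  design <- design_mixture_series(spec, table)
  levels <- unique(design$tu_level)
  grid <- tidyr::expand_grid(dose = levels,
                             replicate = seq_len(scenario$n_replicates))
  eff <- scenario$deviation_factor * grid$dose
  mean_i <- ifelse(eff == 0, 0,
                   fourpl_mean(log10(pmax(eff, .Machine$double.xmin)),
                               0, 100, reference_hill, 0))
  with_seed_if(seed, {
    tibble::tibble(
      treatment_id = spec$mixture_id,
      dose = grid$dose,
      replicate = grid$replicate,
      duration = spec$duration,
      inhibition = add_noise(mean_i, scenario),
      dose_scale = "TU"
    )
  })
}
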