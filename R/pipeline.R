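# End-to-end analysis pipeline and CSV ingest/emit.

plate_schema <- c("plate_id", "well_id", "leaf_id", "treatment_id",
                  "timepoint_h", "F", "Fm_prime", "is_control")
observation_schema <- c("treatment_id", "dose", "replicate", "duration", "inhibition")

#' Read a bioassay CSV, dispatching on its schema
#'
#' Recognises two schemas by their headers: the raw plate schema (`plate_id`,
#' `well_id`, `leaf_id`, `treatment_id`, `timepoint_h`, `F`, `Fm_prime`,
#' optional `F0`/`Fm`, `is_control`) and the tidy observation schema
#' (`treatment_id`, `dose`, `replicate`, `duration`, `inhibition`). Rows
#' violating row-level constraints (negative doses, non-finite measurements)
#' are dropped and reported in the `"row_errors"` attribute; a missing
#' required column is a hard error naming the column. The CSV dialect is
#' fixed: comma separator, `.` decimal, UTF-8, header mandatory.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble with attributes `"schema"` (`"plate"` or
#'   `"observations"`) and `"row_errors"` (a tibble of rejected rows and
#'   reasons).
#' @export
read_observations <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "#", locale = readr::locale(decimal_mark = "."))
  is_plate <- all(c("F", "Fm_prime") %in% names(raw))
  schema <- if (is_plate) "plate" else "observations"
  required <- if (is_plate) plate_schema else observation_schema
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Input CSV is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "seagrasstox_schema_error")
  }
  bad_reason <- if (is_plate) {
    dplyr::case_when(
      !is.finite(raw$F) | !is.finite(raw$Fm_prime) ~ "non-numeric fluorescence",
      raw$Fm_prime <= 0 ~ "non-positive Fm'",
      raw$F < 0 | raw$F > raw$Fm_prime ~ "F outside [0, Fm']",
      .default = NA_character_
    )
  } else {
    dplyr::case_when(
      !is.finite(raw$dose) ~ "non-numeric dose",
      raw$dose < 0 ~ "negative dose",
      !is.finite(raw$inhibition) ~ "non-numeric inhibition",
      !raw$duration %in% c(24, 48) ~ "duration not 24 or 48 h",
      .default = NA_character_
    )
  }
  errors <- tibble::tibble(row = which(!is.na(bad_reason)),
                           reason = bad_reason[!is.na(bad_reason)])
  out <- raw[is.na(bad_reason), , drop = FALSE]
  attr(out, "schema") <- schema
  attr(out, "row_errors") <- errors
  out
}

#' Pipeline configuration
#'
#' Assembles and validates the options controlling [run_pipeline()]. Any field
#' can be overridden; the rest take the documented defaults.
#'
#' @param seed Integer seed; required, and the single source of randomness for
#'   the whole run (fanned out deterministically per stage).
#' @param herbicides Herbicides to assay; default all with a 24 h endpoint.
#' @param duration Exposure duration of the single-herbicide stage (h).
#' @param icx_levels Inhibition levels to invert to (default 10 and 50).
#' @param constrain_4pl Fix bottom = 0 / top = 100 in the fits.
#' @param icx_mode `"absolute"` or `"relative"` ICx definition.
#' @param ci_method `"delta"` or `"bootstrap"` confidence intervals.
#' @param bootstrap_n Bootstrap draws when `ci_method = "bootstrap"`.
#' @param ftest_sharing Parameter-sharing scheme for curve comparisons.
#' @param alpha Significance level for mixture comparisons.
#' @param tu_basis_duration Duration (h) whose IC50s define 1 TU.
#' @param mixtures Character vectors of mixture components; default the binary
#'   diuron + atrazine mixture and the 10-herbicide mixture.
#' @param references Character vectors of sham reference mixtures; default
#'   `[diuron+diuron]` and `[atrazine+atrazine]`.
#' @param scenario Optional [assay_scenario()] overriding the synthetic-data
#'   defaults (its seed is ignored in favour of `seed`).
#' @param input Optional path to an observation CSV or a data frame of
#'   observations; `NULL` (default) simulates the assay instead.
#' @param out_dir Optional directory to write the result CSVs into.
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(seed, herbicides = NULL, duration = 24,
                            icx_levels = c(10, 50), constrain_4pl = FALSE,
                            icx_mode = c("absolute", "relative"),
                            ci_method = c("delta", "bootstrap"),
                            bootstrap_n = 1000,
                            ftest_sharing = c("shared_bth", "separate_all"),
                            alpha = 0.05, tu_basis_duration = 24,
                            mixtures = NULL, references = NULL,
                            scenario = NULL, input = NULL, out_dir = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` is required for every stochastic stage.",
          class = "seagrasstox_config_error")
  }
  assert_scalar_number(alpha, "alpha", 0, 1, strict = TRUE)
  cfg <- list(
    seed = as.integer(seed),
    herbicides = herbicides,
    duration = duration,
    icx_levels = icx_levels,
    constrain_4pl = isTRUE(constrain_4pl),
    icx_mode = match.arg(icx_mode),
    ci_method = match.arg(ci_method),
    bootstrap_n = bootstrap_n,
    ftest_sharing = match.arg(ftest_sharing),
    alpha = alpha,
    tu_basis_duration = tu_basis_duration,
    mixtures = mixtures %||% list(c("diuron", "atrazine"),
                                  reference_endpoints()$herbicide[reference_endpoints()$duration_h == 24]),
    references = references %||% list(c("diuron", "diuron"), c("atrazine", "atrazine")),
    scenario = scenario,
    input = input,
    out_dir = out_dir
  )
  for (m in c(cfg$mixtures, cfg$references)) {
    if (!is.character(m) || length(m) < 1) {
      abort("Mixtures must be character vectors of component herbicides.",
            class = "seagrasstox_config_error")
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full bioassay analysis pipeline
#'
#' Sequences the assay stages: (optionally simulated) single-herbicide
#' concentration-response data, 4PL fits, ICx inversion, relative potencies
#' against diuron, TU-space mixture design/simulation/classification against
#' sham references, and guideline protectiveness flags. The run is
#' deterministic given the config (all randomness fans out from `config$seed`),
#' and stage failures are caught and reported in the run log without aborting
#' independent stages. When `out_dir` is set every table is written as CSV
#' with a provenance header carrying the config hash and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `fits`, `icx_table`, `rep_table`,
#'   `mixture_report`, `guideline_flags`, `log` (tibble of stage statuses) and
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # Mixture designs are dosed from the TU basis table; a basis at a different
  # duration than the mixture design is a configuration error, not a data one.
  if (config$duration != config$tu_basis_duration && is.null(config$input)) {
    abort(sprintf("TU basis (%s h) does not match the mixture design duration (%s h).",
                  config$tu_basis_duration, config$duration),
          class = "seagrasstox_config_error")
  }
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  log <- list()
  note <- function(stage, status, detail = "") {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, status = status,
                                              detail = detail)
  }
  stage <- function(name, expr) {
    tryCatch({
      out <- force(expr)
      note(name, "ok")
      out
    }, error = function(e) {
      note(name, "error", conditionMessage(e))
      NULL
    })
  }

  scenario <- config$scenario %||% assay_scenario(seed = config$seed)
  endpoints <- reference_endpoints()
  herbicides <- config$herbicides %||%
    unique(endpoints$herbicide[endpoints$duration_h == config$duration])

  # Stage 1: observations (ingest or simulate; one derived seed per herbicide).
  observations <- stage("observations", {
    if (!is.null(config$input)) {
      obs <- if (is.data.frame(config$input)) {
        assert_df_has(config$input, observation_schema, "config$input")
        tibble::as_tibble(config$input)
      } else {
        read_observations(config$input)
      }
      obs
    } else {
      purrr::imap_dfr(setNames(herbicides, herbicides), function(h, nm) {
        simulate_single_assay(scenario, h, config$duration,
                              seed = config$seed + match(h, herbicides))
      })
    }
  })

  # Stage 2: per-herbicide 4PL fits and ICx estimates.
  fit_bundle <- stage("dose_response", {
    if (is.null(observations)) abort("no observations available")
    split(observations, observations$treatment_id) |>
      purrr::map(~ fit_4pl(.x, constrain = config$constrain_4pl))
  })

  icx_table <- stage("icx", {
    if (is.null(fit_bundle)) abort("no fits available")
    purrr::imap_dfr(fit_bundle, function(f, id) {
      purrr::map_dfr(config$icx_levels, function(lv) {
        est <- tryCatch(
          invert_icx(f, lv, mode = config$icx_mode, ci_method = config$ci_method,
                     bootstrap_n = config$bootstrap_n, seed = config$seed),
          seagrasstox_icx_not_reached = function(e) {
            tibble::tibble(level = lv, estimate = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, mode = config$icx_mode,
                           ci_method = config$ci_method, dose_scale = f$dose_scale)
          })
        dplyr::mutate(est, treatment_id = id, duration_h = f$duration,
                      note = ifelse(is.na(.data$estimate), "> max dose tested", ""))
      })
    })
  })

  fits_table <- stage("fit_table", {
    if (is.null(fit_bundle) || is.null(icx_table)) abort("no fits available")
    wide_ic <- icx_table |>
      dplyr::filter(.data$level %in% c(10, 50)) |>
      dplyr::select(dplyr::all_of(c("treatment_id", "level", "estimate",
                                    "ci_low", "ci_high"))) |>
      tidyr::pivot_wider(names_from = "level",
                         values_from = c("estimate", "ci_low", "ci_high"),
                         names_glue = "ic{level}_{.value}")
    purrr::imap_dfr(fit_bundle, function(f, id) {
      tibble::tibble(
        treatment_id = id, duration_h = f$duration, dose_scale = f$dose_scale,
        bottom = f$coefficients[["bottom"]], top = f$coefficients[["top"]],
        hill = f$coefficients[["hill"]], ic50 = f$ic50,
        r2 = f$r2, n_obs = f$n_obs, convergence_flag = f$convergence
      )
    }) |>
      dplyr::left_join(wide_ic, by = "treatment_id") |>
      dplyr::rename(ic50_fit = "ic50",
                    ic10 = "ic10_estimate", ic10_lo = "ic10_ci_low", ic10_hi = "ic10_ci_high",
                    ic50 = "ic50_estimate", ic50_lo = "ic50_ci_low", ic50_hi = "ic50_ci_high")
  })

  rep_tbl <- stage("relative_potency", {
    if (is.null(fits_table)) abort("no fit table available")
    fits_table |>
      dplyr::transmute(herbicide = .data$treatment_id,
                       duration_h = .data$duration_h, ic50 = .data$ic50_fit) |>
      rep_table(reference = "diuron")
  })

  mixture_report <- stage("mixture", {
    basis <- tu_table(endpoints, duration = config$tu_basis_duration)
    ref_fits <- purrr::imap(config$references, function(comp, i) {
      sp <- mixture_spec(comp, duration = config$tu_basis_duration)
      sim <- simulate_mixture_assay(scenario, sp, basis,
                                    seed = config$seed + 1000L + as.integer(i))
      fit_4pl(sim, constrain = config$constrain_4pl)
    })
    purrr::map_dfr(config$mixtures, function(comp) {
      sp <- mixture_spec(comp, duration = config$tu_basis_duration,
                         mixture_id = if (length(comp) > 4) {
                           sprintf("%d-herbicide-mix", length(comp))
                         } else NULL)
      sim <- simulate_mixture_assay(scenario, sp, basis,
                                    seed = config$seed + 2000 + length(comp))
      fit <- fit_4pl(sim, constrain = config$constrain_4pl)
      res <- classify_additivity(fit, ref_fits, alpha = config$alpha)
      dplyr::mutate(tidy(res), tu_basis_h = config$tu_basis_duration)
    })
  })

  guideline_flags <- stage("guidelines", {
    if (is.null(fits_table)) abort("no fit table available")
    ic <- fits_table |>
      dplyr::transmute(herbicide = .data$treatment_id, icx_level = 10,
                       icx_value = .data$ic10) |>
      dplyr::filter(is.finite(.data$icx_value))
    flag_protectiveness(ic)
  })

  result <- structure(
    list(fits = fits_table, icx_table = icx_table, rep_table = rep_tbl,
         mixture_report = mixture_report, guideline_flags = guideline_flags,
         observations = observations,
         log = dplyr::bind_rows(log), config_hash = hash, seed = config$seed),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_result_tables(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("seagrasstox pipeline run", x$config_hash, "(seed", x$seed, ")\n")
  print(x$log)
  invisible(x)
}

#' Write pipeline result tables as CSV with a provenance header
#'
#' Each file starts with a `#`-prefixed provenance line (config hash and
#' seed); [read_result_table()] reads it back losslessly (numeric fields round
#' trip at full precision).
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_result_tables <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("fits", "icx_table", "rep_table", "mixture_report",
              "guideline_flags", "log")
  paths <- purrr::map_chr(tables, function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    tbl <- result[[nm]]
    if (is.null(tbl)) tbl <- tibble::tibble()
    header <- sprintf("# seagrasstox run %s seed %d", result$config_hash, result$seed)
    writeLines(header, path)
    readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
    path
  })
  invisible(paths)
}

#' @rdname write_result_tables
#' @param path Path to a CSV written by [write_result_tables()].
#' @export
read_result_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
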