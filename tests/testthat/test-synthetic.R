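test_that("simulation is deterministic given scenario and seed", {
  sc <- assay_scenario(seed = 42)
  a <- simulate_single_assay(sc, "diuron")
  b <- simulate_single_assay(sc, "diuron")
  expect_identical(a, b)
  c2 <- simulate_single_assay(sc, "diuron", seed = 43)
  expect_false(identical(a, c2))

  tab <- tu_table()
  m1 <- simulate_mixture_assay(sc, mixture_spec(c("diuron", "atrazine")), tab)
  m2 <- simulate_mixture_assay(sc, mixture_spec(c("diuron", "atrazine")), tab)
  expect_identical(m1, m2)
})

test_that("the noise-free limit returns the truth curve exactly", {
  sc <- assay_scenario(noise_sd = 1e-12, seed = 1)
  sim <- simulate_single_assay(sc, "diuron")
  truth <- 100 / (1 + (4.3 / sim$dose[sim$dose > 0]))
  expect_equal(sim$inhibition[sim$dose > 0], truth, tolerance = 1e-9)
  expect_equal(sim$inhibition[sim$dose == 0], rep(0, 9), tolerance = 1e-9)
  expect_equal(fit_4pl(sim)$ic50, 4.3, tolerance = 1e-5)
})

test_that("replicate mean at the true IC50 approaches (B+T)/2", {
  sc <- assay_scenario(seed = 8, n_replicates = 1,
                       dose_series = list(diuron = c(0.1, 0.5, 1, 4.3, 20, 50, 100)))
  set.seed(2024)
  draws <- replicate(400, {
    s <- simulate_single_assay(sc, "diuron", seed = NULL)
    s$inhibition[s$dose == 4.3]
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 50), 3 * se + 1e-9)
})

test_that("replicate noise is calibrated to small mid-curve standard errors", {
  # With sd = 5 points and n = 9 leaves, the SE of a dose mean is ~5/3 points.
  sc <- assay_scenario(seed = 15)
  set.seed(99)
  ses <- replicate(100, {
    s <- simulate_single_assay(sc, "diuron", seed = NULL)
    mid <- s[s$dose > 0, ]
    mid <- mid[abs(log10(mid$dose / 4.3)) < 0.4, ]
    sd(mid$inhibition) / sqrt(length(mid$inhibition))
  })
  expect_equal(mean(ses), 5 / 3, tolerance = 0.15)
})

test_that("raw plates invert through the fluorometry pipeline", {
  sc <- assay_scenario(seed = 4)
  plate <- simulate_raw_plate(sc, "diuron")
  expect_true(all(c("plate_id", "well_id", "F", "Fm_prime", "F0", "Fm") %in% names(plate)))
  # effective_quantum_yield recovers the simulated yield, and the pipeline
  # reproduces the simulated inhibition for unclipped wells.
  endpoints <- plate_endpoints(plate, control_by = "timepoint_h")
  expect_equal(nrow(endpoints), nrow(plate))

  sc0 <- assay_scenario(noise_sd = 1e-12, seed = 4)
  plate0 <- simulate_raw_plate(sc0, "diuron")
  endpoints0 <- plate_endpoints(plate0, control_by = "timepoint_h")
  expect_equal(endpoints0$inhibition_pct[endpoints0$treatment_id == "solvent_control"],
               rep(0, 9), tolerance = 1e-6)
  obs0 <- endpoints0 |>
    dplyr::filter(!.data$treatment_id == "solvent_control") |>
    dplyr::mutate(dose = plate0$dose[!plate0$is_control], inhibition = .data$inhibition_pct)
  expect_equal(fit_4pl(obs0)$ic50, 4.3, tolerance = 1e-4)
})

test_that("configured low Fv/Fm leaves fail screening; clipping is counted", {
  sc <- assay_scenario(seed = 4)
  weak <- simulate_raw_plate(sc, "diuron", fvfm = 0.60)
  expect_true(all(!screen_leaves(weak)$screen_pass))
  strong <- simulate_raw_plate(sc, "diuron", fvfm = 0.70)
  expect_true(all(screen_leaves(strong)$screen_pass))

  noisy <- assay_scenario(seed = 6, noise_sd = 40)
  plate <- simulate_raw_plate(noisy, "diuron")
  expect_gt(attr(plate, "n_clipped"), 0)
  y <- effective_quantum_yield(plate$F, plate$Fm_prime)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("yield-scale noise induces heteroscedastic inhibition noise", {
  sc <- assay_scenario(seed = 30, noise_model = "yield", yield_sd = 0.03,
                       n_replicates = 9)
  sim <- simulate_single_assay(sc, "diuron")
  expect_true(all(sim$inhibition <= 100 + 1e-9))  # yields clipped at 0
  fit <- fit_4pl(sim)
  expect_equal(fit$ic50, 4.3, tolerance = 0.5)
})

test_that("scenario validation rejects unusable designs", {
  expect_error(assay_scenario(noise_sd = 0), class = "seagrasstox_input_error")
  expect_error(assay_scenario(control_yield = 0), class = "seagrasstox_input_error")
  expect_error(assay_scenario(deviation_factor = 0), class = "seagrasstox_input_error")
  sc <- assay_scenario(seed = 1)
  expect_error(simulate_single_assay(sc, "nonesuch"), class = "seagrasstox_lookup_error")
})
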