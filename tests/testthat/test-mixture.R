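test_that("Toxic-Unit conversion and TU_sum follow their definitions", {
  expect_equal(toxic_units(4.3, 4.3), 1)
  expect_equal(toxic_units(0, 4.3), 0)
  expect_equal(toxic_units(11, 22), 0.5)
  expect_error(toxic_units(1, 0), class = "seagrasstox_input_error")

  tab <- tu_table()
  expect_equal(tu_sum(tibble::tibble(herbicide = c("diuron", "atrazine"),
                                     concentration = c(2.15, 11)), tab), 1)
  expect_equal(tu_sum(tibble::tibble(herbicide = character(),
                                     concentration = numeric()), tab), 0)
  expect_error(
    tu_sum(tibble::tibble(herbicide = "glyphosate", concentration = 1), tab),
    class = "seagrasstox_lookup_error"
  )
})

test_that("TU_sum is linear over disjoint component lists", {
  tab <- tu_table()
  herbs <- tab$herbicide
  set.seed(13)
  for (i in 1:20) {
    pick <- sample(herbs, 6)
    conc <- runif(6, 0, 50)
    all6 <- tibble::tibble(herbicide = pick, concentration = conc)
    expect_equal(tu_sum(all6, tab),
                 tu_sum(all6[1:3, ], tab) + tu_sum(all6[4:6, ], tab))
  }
})

test_that("mixture designs reproduce their nominal TU level exactly", {
  tab <- tu_table()
  sp <- mixture_spec(c("diuron", "atrazine"))
  design <- design_mixture_series(sp, tab)
  # Equal TU proportions at level 1: each component at half its own IC50.
  lvl1 <- design[design$tu_level == 1, ]
  expect_equal(lvl1$concentration_ugL[lvl1$component == "diuron"], 4.3 / 2)
  expect_equal(lvl1$concentration_ugL[lvl1$component == "atrazine"], 22 / 2)
  expect_equal(design$concentration_ugL[design$tu_level == 0], c(0, 0))

  # Every row group recomputes to its nominal level to machine precision.
  for (sp2 in list(sp, mixture_spec(tab$herbicide),
                   mixture_spec(c("diuron", "ametryn"), proportions = c(0.8, 0.2)))) {
    d <- design_mixture_series(sp2, tab)
    recomputed <- d |>
      dplyr::summarise(
        tu = tu_sum(tibble::tibble(herbicide = component,
                                   concentration = concentration_ugL), tab),
        .by = tu_level
      )
    expect_equal(recomputed$tu, recomputed$tu_level, tolerance = 1e-12)
  }

  # 10-herbicide equal mix at 1 TU doses diuron at a tenth of its IC50.
  d10 <- design_mixture_series(mixture_spec(tab$herbicide), tab)
  expect_equal(
    d10$concentration_ugL[d10$tu_level == 1 & d10$component == "diuron"],
    0.1 * 4.3
  )
})

test_that("mixture specs validate proportions and TU ladders", {
  expect_error(mixture_spec("diuron", proportions = c(0.4, 0.6)),
               class = "seagrasstox_input_error")
  expect_error(mixture_spec(c("a", "b"), proportions = c(0.7, 0.7)),
               class = "seagrasstox_input_error")
  expect_error(mixture_spec("diuron", tu_levels = c(0, 2, 1)),
               class = "seagrasstox_input_error")
  tab <- tu_table()
  sp48 <- mixture_spec(c("diuron", "atrazine"), duration = 48)
  expect_error(design_mixture_series(sp48, tab), class = "seagrasstox_basis_error")
})

test_that("the Concentration-Addition expectation passes 50% at 1 TU", {
  obs <- make_4pl_obs(0, 100, 1.3, 1, doses = c(0.25, 0.5, 0.75, 1, 1.5, 2, 4),
                      dose_scale = "TU")
  ref <- fit_4pl(obs)
  curve <- ca_expected_curve(ref)
  expect_equal(curve(1), 50, tolerance = 1e-6)
  expect_equal(curve(0), 0, tolerance = 1e-4)        # s = 0 returns the bottom
  expect_equal(curve(1e8), 100, tolerance = 1e-3)    # asymptote

  conc_fit <- fit_4pl(make_4pl_obs(0, 100, 1, 10))
  expect_error(ca_expected_curve(conc_fit), class = "seagrasstox_basis_error")
})

test_that("sham self-mixtures match the single herbicide on the TU scale", {
  # Loewe self-consistency: [X+X] in any proportions is X itself. The design
  # collapses to the same TU dosing, so the fitted TU-scale IC50 of the sham
  # equals the single herbicide's IC50 rescaled by its own IC50 (1 TU).
  tab <- tu_table()
  sc <- assay_scenario(seed = 77)
  sham <- simulate_mixture_assay(sc, mixture_spec(c("diuron", "diuron"),
                                                  proportions = c(0.3, 0.7)), tab)
  single <- simulate_mixture_assay(sc, mixture_spec("diuron"), tab)
  expect_equal(sham$dose, single$dose)
  expect_equal(sham$inhibition, single$inhibition)  # identical seed, identical draw
  fit <- fit_4pl(sham)
  expect_equal(fit$ic50, 1, tolerance = 0.15)
})

test_that("joint-action classification follows the reference-dominated rule", {
  tab <- tu_table()
  sc <- assay_scenario(seed = 100)
  refs <- lapply(1:2, function(i) {
    f <- fit_4pl(simulate_mixture_assay(sc, mixture_spec(c("diuron", "diuron")),
                                        tab, seed = 500 + i))
    f$treatment_id <- paste0("sham", i)
    f
  })

  # Additive: simulated under exact Concentration Addition.
  add_fit <- fit_4pl(simulate_mixture_assay(sc, mixture_spec(c("diuron", "atrazine")),
                                            tab, seed = 1))
  res_add <- classify_additivity(add_fit, refs)
  expect_equal(res_add$classification, "additive")
  expect_equal(res_add$ic50_tu, 1, tolerance = 0.1)
  expect_false(res_add$ci_fallback)

  # Synergistic: each nominal TU acts as 2 TU.
  sc_syn <- assay_scenario(seed = 100, deviation_factor = 2)
  syn_fit <- fit_4pl(simulate_mixture_assay(sc_syn, mixture_spec(c("diuron", "atrazine")),
                                            tab, seed = 2))
  res_syn <- classify_additivity(syn_fit, refs)
  expect_equal(res_syn$classification, "synergistic")
  expect_equal(res_syn$ic50_tu, 0.5, tolerance = 0.1)

  # Antagonistic: each nominal TU acts as half a TU.
  sc_ant <- assay_scenario(seed = 100, deviation_factor = 0.5)
  ant_fit <- fit_4pl(simulate_mixture_assay(sc_ant, mixture_spec(c("diuron", "atrazine")),
                                            tab, seed = 3))
  res_ant <- classify_additivity(ant_fit, refs)
  expect_equal(res_ant$classification, "antagonistic")

  # Fallback without references: CI-contains-1 rule, flagged.
  res_fb <- classify_additivity(syn_fit)
  expect_true(res_fb$ci_fallback)
  expect_equal(res_fb$classification, "synergistic")
  res_fb_add <- classify_additivity(add_fit)
  expect_true(res_fb_add$classification %in% c("additive", "synergistic", "antagonistic"))

  td <- tidy(res_syn)
  expect_named(td, c("mixture_id", "ic10_tu", "ic50_tu", "ic50_lo", "ic50_hi",
                     "classification", "n_references", "min_p", "ci_fallback"))
})

test_that("percent_below reproduces reference-relative IC50 differences", {
  expect_equal(percent_below(0.85, 0.90), 100 * 0.05 / 0.90)
  expect_equal(percent_below(1, 1), 0)
})
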