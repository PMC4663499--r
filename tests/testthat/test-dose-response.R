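test_that("noiseless 4PL data are recovered to optimizer tolerance", {
  truths <- list(
    list(bottom = 0, top = 100, hill = 1.5, ic50 = 10),
    list(bottom = 5, top = 92, hill = 0.8, ic50 = 4.3),
    list(bottom = 0, top = 100, hill = 2.5, ic50 = 132)
  )
  for (tr in truths) {
    obs <- make_4pl_obs(tr$bottom, tr$top, tr$hill, tr$ic50, replicates = 2)
    fit <- fit_4pl(obs)
    expect_equal(fit$ic50, tr$ic50, tolerance = 1e-6)
    expect_equal(unname(coef(fit)["hill"]), tr$hill, tolerance = 1e-5)
    expect_equal(unname(coef(fit)["bottom"]), tr$bottom, tolerance = 1e-4)
    expect_equal(unname(coef(fit)["top"]), tr$top, tolerance = 1e-4)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
    expect_equal(fit$df, nrow(obs) - 4)
  }
})

test_that("degenerate or under-designed inputs are refused", {
  flat <- make_4pl_obs(0, 100, 1, 10)
  flat$inhibition <- 42
  expect_error(fit_4pl(flat), class = "seagrasstox_fit_error")

  few <- make_4pl_obs(doses = c(1, 10, 100))
  expect_error(fit_4pl(few), class = "seagrasstox_fit_error")

  neg <- make_4pl_obs()
  neg$dose[1] <- -1
  expect_error(fit_4pl(neg), class = "seagrasstox_input_error")
})

test_that("constrained mode pins the asymptotes at 0 and 100", {
  obs <- make_4pl_obs(0, 100, 1.2, 7)
  fit <- fit_4pl(obs, constrain = TRUE)
  expect_equal(unname(coef(fit)[c("bottom", "top")]), c(0, 100))
  expect_equal(fit$ic50, 7, tolerance = 1e-6)
  expect_equal(fit$df, nrow(obs) - 2)
})

test_that("fit_4pl agrees with an independent grid+bisection SS minimizer", {
  cases <- list(
    list(bottom = 0, top = 100, hill = 1, ic50 = 4.3),
    list(bottom = 3, top = 95, hill = 1.8, ic50 = 28)
  )
  for (tr in cases) {
    obs <- make_4pl_obs(tr$bottom, tr$top, tr$hill, tr$ic50)
    fit <- fit_4pl(obs)
    oracle <- oracle_fit_4pl(obs$dose, obs$inhibition)
    expect_lt(abs(fit$ic50 - oracle$ic50) / oracle$ic50, 1e-4)
  }
})

test_that("ICx inversion matches the closed form and round-trips through the curve", {
  obs <- make_4pl_obs(0, 100, 1, 10)
  fit <- fit_4pl(obs)
  expect_equal(invert_icx(fit, 50)$estimate, 10, tolerance = 1e-6)
  expect_equal(invert_icx(fit, 10)$estimate, 10 * (10 / 90), tolerance = 1e-5)

  # Round trip I(invert_icx(f)) = f holds for any level inside (B, T),
  # including fits whose B + T != 100.
  obs2 <- make_4pl_obs(8, 88, 1.4, 5)
  fit2 <- fit_4pl(obs2)
  for (f in c(10, 20, 50, 80)) {
    x <- invert_icx(fit2, f)$estimate
    expect_equal(predict(fit2, x), f, tolerance = 1e-9)
  }

  # Monotone: invert_icx increases in level; IC10 < IC50 for increasing fits.
  xs <- vapply(c(10, 20, 50, 80), function(f) invert_icx(fit2, f)$estimate, numeric(1))
  expect_true(all(diff(xs) > 0))

  # Levels outside the fitted span are reported as not reached.
  obs3 <- make_4pl_obs(20, 80, 1, 10)
  fit3 <- fit_4pl(obs3)
  expect_error(invert_icx(fit3, 90), class = "seagrasstox_icx_not_reached")
  expect_error(invert_icx(fit3, 10), class = "seagrasstox_icx_not_reached")
})

test_that("delta and bootstrap intervals bracket the estimate sensibly", {
  sc <- assay_scenario(seed = 5)
  obs <- simulate_single_assay(sc, "diuron")
  fit <- fit_4pl(obs)

  d <- invert_icx(fit, 50)
  expect_true(d$ci_low < d$estimate && d$estimate < d$ci_high)

  b <- invert_icx(fit, 50, ci_method = "bootstrap", bootstrap_n = 60, seed = 2)
  expect_true(b$ci_low < b$estimate && b$estimate < b$ci_high)
  b2 <- invert_icx(fit, 50, ci_method = "bootstrap", bootstrap_n = 60, seed = 2)
  expect_identical(b, b2)  # seeded resampling is reproducible
})

test_that("relative potency matches the printed ratios and is antisymmetric", {
  expect_equal(signif(relative_potency(4.3, 132), 2), 0.033)
  expect_equal(round(relative_potency(4.3, 3.5), 2), 1.23)
  expect_equal(relative_potency(4.3, 4.3), 1)
  expect_error(relative_potency(-1, 2), class = "seagrasstox_input_error")

  set.seed(3)
  a <- runif(10, 0.5, 50); b <- runif(10, 0.5, 50)
  expect_equal(relative_potency(a, b) * relative_potency(b, a), rep(1, 10))
})

test_that("rep_table uses duration-matched references with a 24 h fallback", {
  ep <- reference_endpoints()
  out <- rep_table(dplyr::select(ep, herbicide, duration_h, ic50))
  expect_equal(out$rep[out$herbicide == "diuron" & out$duration_h == 24], 1)
  # no 48 h diuron row exists, so 48 h rows divide the 24 h reference IC50
  expect_true(all(out$reference_duration[out$duration_h == 48] == 24))
  expect_equal(out$rep[out$herbicide == "ametryn" & out$duration_h == 48],
               4.3 / 3.5, tolerance = 1e-12)
  expect_error(rep_table(dplyr::filter(ep, herbicide != "diuron")),
               class = "seagrasstox_input_error")
})

test_that("goodness of fit is 1 on noiseless data and NA without variance", {
  obs <- make_4pl_obs(0, 100, 1, 10)
  expect_equal(goodness_of_fit(fit_4pl(obs)), 1, tolerance = 1e-9)

  sc <- assay_scenario(seed = 9)
  fit <- fit_4pl(simulate_single_assay(sc, "atrazine"))
  expect_true(goodness_of_fit(fit) < 1 && goodness_of_fit(fit) > 0.9)
})

test_that("tidy and glance summarise a fit in broom style", {
  fit <- fit_4pl(make_4pl_obs(0, 100, 1, 10, replicates = 3))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("bottom", "top", "hill", "log10_ic50"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 21)
  expect_s3_class(autoplot(fit), "ggplot")
})
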