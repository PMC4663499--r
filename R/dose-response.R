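# Four-parameter logistic concentration-response fitting and ICx inversion.
#
# Model, for dose x > 0 and parameters bottom B, top T, hill slope h and
# midpoint IC50 (fit internally as lambda = log10 IC50):
#
#   I(x) = B + (T - B) / (1 + 10^(h * (lambda - log10 x)))
#
# which equals the usual B + (T - B)/(1 + (IC50/x)^h). For h > 0 the curve
# increases from B (x -> 0) to T (x -> Inf) and crosses (B + T)/2 at x = IC50.

LOG10 <- log(10)

fourpl_mean <- function(logx, b, t, h, lambda) {
  b + (t - b) / (1 + 10^(h * (lambda - logx)))
}

# Jacobian of fourpl_mean wrt (b, t, h, lambda); rows = observations.
clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

default_4pl_bounds <- function(logx, bounds = NULL) {
  out <- list(
    bottom = c(-50, 50),
    top = c(0, 110),
    hill = c(0.1, 10),
    log10_ic50 = c(min(logx) - 1.5, max(logx) + 1.5)
  )
  for (nm in names(bounds %||% list())) out[[nm]] <- bounds[[nm]]
  out
}

fourpl_jacobian <- function(logx, b, t, h, lambda) {
  u <- 10^(h * (lambda - logx))
  denom <- (1 + u)^2
  cbind(
    b = u / (1 + u),
    t = 1 / (1 + u),
    h = -(t - b) * u * LOG10 * (lambda - logx) / denom,
    lambda = -(t - b) * u * LOG10 * h / denom
  )
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Fits I(x) = B + (T - B) / (1 + (IC50/x)^h) to percent-inhibition data by
#' nonlinear least squares (Levenberg–Marquardt, via \pkg{minpack.lm}) on the
#' log10-dose scale with log10(IC50) as the free midpoint parameter. The fit is
#' multi-started over a deterministic grid (log10 IC50 at the dose grid's
#' midpoint and ±1 decade; hill slope 0.5, 1, 2) and the best start by residual
#' sum of squares wins; ties break toward the start closest to the grid
#' midpoint. Controls (dose 0) are excluded: inhibition is already normalised
#' to them and they carry no information about the curve on the log-dose scale.
#'
#' @param observations Data frame with columns `dose` (>= 0; 0 rows are
#'   dropped as controls) and `inhibition` (percent). Optional columns
#'   `treatment_id`, `duration` and `dose_scale` annotate the result.
#' @param constrain If `TRUE`, fixes bottom = 0 and top = 100 and fits only the
#'   hill slope and IC50.
#' @param min_doses Minimum number of distinct positive doses required.
#' @param bounds Box constraints for the optimizer as a list with elements
#'   `bottom`, `top`, `hill`, `log10_ic50`, each `c(lower, upper)`. The default
#'   keeps the search inside the region the endpoint and design can identify:
#'   percent inhibition of a quantum yield cannot exceed 100 (top in
#'   \[0, 110\], bottom in \[-50, 50\] to admit stimulation), the hill slope in
#'   \[0.1, 10\], and log10(IC50) within the tested dose range ±1.5 decades
#'   (a midpoint further out is not estimable from the design). On
#'   well-determined data the optimum is interior and the bounds are inactive;
#'   on weak designs they prevent the divergence of the 4PL's flat likelihood
#'   ridge (top and IC50 growing without bound at essentially unchanged SS).
#' @return An object of class `logistic_fit`: fitted coefficients (`bottom`,
#'   `top`, `hill`, `log10_ic50`), `ic50`, the 4x4 parameter covariance matrix
#'   (zero rows/columns for constrained parameters), `r2`, `ss_resid`, `df`,
#'   `n_obs`, the modelling data, and metadata. Methods: `print()`, `coef()`,
#'   `predict()`, `tidy()`, `glance()`, `autoplot()`.
#' @examples
#' obs <- tibble::tibble(dose = rep(c(1, 3, 10, 30, 100, 300, 1000), 2))
#' obs$inhibition <- 100 / (1 + (50 / obs$dose))
#' fit <- fit_4pl(obs)
#' coef(fit)
#' @export
fit_4pl <- function(observations, constrain = FALSE, min_doses = 5,
                    bounds = NULL) {
  assert_df_has(observations, c("dose", "inhibition"), "observations")
  obs <- tibble::as_tibble(observations)
  if (any(!is.finite(obs$dose) | obs$dose < 0)) {
    abort("Doses must be finite and non-negative.", class = "seagrasstox_input_error")
  }
  obs <- obs[obs$dose > 0, , drop = FALSE]
  doses <- sort(unique(obs$dose))
  if (length(doses) < min_doses) {
    abort(sprintf("Need at least %d distinct positive doses; got %d.",
                  min_doses, length(doses)),
          class = "seagrasstox_fit_error")
  }
  y <- obs$inhibition
  if (!all(is.finite(y))) {
    abort("Inhibition values must be finite.", class = "seagrasstox_input_error")
  }
  if (var(y) == 0) {
    abort("All responses identical: no concentration-response to fit.",
          class = "seagrasstox_fit_error")
  }
  logx <- log10(obs$dose)

  dose_means <- obs |>
    dplyr::summarise(m = mean(.data$inhibition), .by = "dose") |>
    dplyr::arrange(.data$dose)
  span <- diff(range(dose_means$m))
  if (span < 40) {
    warn(paste0("Dose series spans only ", round(span, 1),
                " inhibition points; the curve may be poorly determined."))
  }
  if (dose_means$m[nrow(dose_means)] < dose_means$m[1]) {
    warn("Mean response decreases with dose; check the hill-slope sign on the fit.")
  }

  mid <- mean(range(logx))
  bounds <- default_4pl_bounds(logx, bounds)
  b0 <- clamp(min(dose_means$m), bounds$bottom)
  t0 <- clamp(max(dose_means$m), bounds$top)
  starts <- expand.grid(lambda = clamp(mid + c(-1, 0, 1), bounds$log10_ic50),
                        h = c(0.5, 1, 2))

  resid_fn <- if (constrain) {
    function(p) y - fourpl_mean(logx, 0, 100, p[1], p[2])
  } else {
    function(p) y - fourpl_mean(logx, p[1], p[2], p[3], p[4])
  }
  jac_fn <- if (constrain) {
    function(p) -fourpl_jacobian(logx, 0, 100, p[1], p[2])[, c("h", "lambda"), drop = FALSE]
  } else {
    function(p) -fourpl_jacobian(logx, p[1], p[2], p[3], p[4])
  }

  lower <- if (constrain) {
    c(bounds$hill[1], bounds$log10_ic50[1])
  } else {
    c(bounds$bottom[1], bounds$top[1], bounds$hill[1], bounds$log10_ic50[1])
  }
  upper <- if (constrain) {
    c(bounds$hill[2], bounds$log10_ic50[2])
  } else {
    c(bounds$bottom[2], bounds$top[2], bounds$hill[2], bounds$log10_ic50[2])
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- if (constrain) c(starts$h[i], starts$lambda[i]) else c(b0, t0, starts$h[i], starts$lambda[i])
    ans <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
      ),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    ss <- sum(ans$fvec^2)
    if (!is.finite(ss)) next
    lam_i <- if (constrain) ans$par[2] else ans$par[4]
    cand <- list(par = ans$par, ss = ss, info = ans$info,
                 dist = abs(lam_i - mid))
    if (is.null(best) || ss < best$ss - 1e-12 ||
        (abs(ss - best$ss) <= 1e-12 && cand$dist < best$dist)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    abort("4PL fit failed to converge from every start.", class = "seagrasstox_fit_error")
  }

  par <- if (constrain) c(0, 100, best$par) else best$par
  names(par) <- c("bottom", "top", "hill", "log10_ic50")
  # Canonical orientation: (B, T, h) and (T, B, -h) give the same curve.
  if (par["hill"] < 0) {
    par <- c(bottom = unname(par["top"]), top = unname(par["bottom"]),
             hill = -unname(par["hill"]), log10_ic50 = unname(par["log10_ic50"]))
  }
  if (par["hill"] < 0 || (par["top"] < par["bottom"])) {
    warn("Fitted curve is non-increasing in dose; interpret ICx with care.")
  }

  n <- length(y)
  p_free <- if (constrain) 2L else 4L
  df <- n - p_free
  fitted <- fourpl_mean(logx, par[1], par[2], par[3], par[4])
  ss_resid <- sum((y - fitted)^2)
  ss_total <- sum((y - mean(y))^2)
  r2 <- 1 - ss_resid / ss_total

  jac <- fourpl_jacobian(logx, par[1], par[2], par[3], par[4])
  free_idx <- if (constrain) 3:4 else 1:4
  sigma2 <- if (df > 0) ss_resid / df else NA_real_
  vcov4 <- matrix(0, 4, 4, dimnames = list(names(par), names(par)))
  jtj <- crossprod(jac[, free_idx, drop = FALSE])
  vsub <- tryCatch(solve(jtj), error = function(e) {
    s <- svd(jtj)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
  })
  vcov4[free_idx, free_idx] <- sigma2 * vsub

  meta_first <- function(col, default) {
    if (col %in% names(observations) && nrow(observations) > 0) observations[[col]][1] else default
  }
  structure(
    list(
      coefficients = par,
      ic50 = unname(10^par["log10_ic50"]),
      vcov = vcov4,
      r2 = r2,
      ss_resid = ss_resid,
      ss_total = ss_total,
      df = df,
      n_obs = n,
      sigma = sqrt(sigma2),
      constrained = constrain,
      convergence = best$info,
      data = obs,
      treatment_id = meta_first("treatment_id", NA_character_),
      duration = meta_first("duration", NA_real_),
      dose_scale = meta_first("dose_scale", "concentration")
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Four-parameter logistic concentration-response fit\n")
  if (!is.na(x$treatment_id)) cat("  treatment:", x$treatment_id, "\n")
  cat(sprintf("  bottom %.2f  top %.2f  hill %.3f  IC50 %.4g (%s)\n",
              x$coefficients["bottom"], x$coefficients["top"],
              x$coefficients["hill"], x$ic50, x$dose_scale))
  cat(sprintf("  n = %d, residual df = %d, R-squared = %.4f\n", x$n_obs, x$df, x$r2))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' Predicted inhibition from a fitted logistic curve
#'
#' @param object A `logistic_fit`.
#' @param newdata Optional data frame with a `dose` column (or a numeric dose
#'   vector); defaults to the modelling data.
#' @param ... Unused.
#' @return Numeric vector of predicted percent inhibition.
#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) {
    object$data$dose
  } else if (is.data.frame(newdata)) {
    assert_df_has(newdata, "dose", "newdata")
    newdata$dose
  } else {
    as.numeric(newdata)
  }
  p <- object$coefficients
  out <- rep(NA_real_, length(dose))
  pos <- dose > 0
  out[pos] <- fourpl_mean(log10(dose[pos]), p[1], p[2], p[3], p[4])
  out[dose == 0] <- p[1]
  out
}

#' Coefficient of determination of a logistic fit
#'
#' R-squared about the mean of the fitted observations,
#' 1 - SS_resid / SS_total.
#'
#' @param fit A `logistic_fit`.
#' @return A single number in \[0, 1\], or `NA` when the observations carry no
#'   variance.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$ss_total == 0) return(NA_real_)
  fit$r2
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = ifelse(x$constrained & names(x$coefficients) %in% c("bottom", "top"),
                       NA_real_, unname(se))
  )
}

#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    treatment_id = x$treatment_id,
    dose_scale = x$dose_scale,
    ic50 = x$ic50,
    r.squared = x$r2,
    ss_resid = x$ss_resid,
    df.residual = x$df,
    nobs = x$n_obs,
    sigma = x$sigma,
    constrained = x$constrained
  )
}

#' Invert a fitted logistic curve to an ICx estimate
#'
#' In the default absolute mode the ICx is the dose at which the fitted curve
#' crosses `level` percent inhibition:
#' `x = IC50 * ((level - B)/(T - level))^(1/h)`. The relative mode instead uses
#' the fraction of the fitted span, `x = IC50 * (f/(100 - f))^(1/h)`.
#' Confidence intervals come from the delta method on log10(ICx) using the fit
#' covariance (symmetric on the log scale), or from a nonparametric bootstrap
#' that resamples replicates within dose and refits.
#'
#' @param fit A `logistic_fit`.
#' @param level Target inhibition percent, e.g. 10 or 50.
#' @param mode `"absolute"` (default) or `"relative"`.
#' @param ci_method `"delta"` (default) or `"bootstrap"`.
#' @param conf Confidence level, default 0.95.
#' @param bootstrap_n Bootstrap draws when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap resampling.
#' @return A one-row tibble: `level`, `estimate`, `ci_low`, `ci_high`, `mode`,
#'   `ci_method`, `dose_scale`.
#' @examples
#' obs <- tibble::tibble(dose = c(1, 3, 10, 30, 100, 300, 1000))
#' obs$inhibition <- 100 / (1 + (10 / obs$dose))
#' invert_icx(fit_4pl(obs), 50)
#' @export
invert_icx <- function(fit, level, mode = c("absolute", "relative"),
                       ci_method = c("delta", "bootstrap"), conf = 0.95,
                       bootstrap_n = 1000, seed = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  assert_scalar_number(level, "level", 0, 100, strict = TRUE)
  p <- fit$coefficients
  b <- p[["bottom"]]; t <- p[["top"]]; h <- p[["hill"]]; lam <- p[["log10_ic50"]]

  if (mode == "absolute") {
    if (!(b < level && level < t)) {
      abort(sprintf(
        "IC%s not reached: %s%% is outside the fitted response range (%.1f, %.1f); report as '> max dose tested'.",
        format(level), format(level), b, t),
        class = "seagrasstox_icx_not_reached")
    }
    q <- log10((level - b) / (t - level))
  } else {
    q <- log10(level / (100 - level))
  }
  log_icx <- lam + q / h

  z <- qnorm(1 - (1 - conf) / 2)
  if (ci_method == "delta") {
    grad <- if (mode == "absolute") {
      c(bottom = -1 / (h * LOG10 * (level - b)),
        top = -1 / (h * LOG10 * (t - level)),
        hill = -q / h^2,
        log10_ic50 = 1)
    } else {
      c(bottom = 0, top = 0, hill = -q / h^2, log10_ic50 = 1)
    }
    se <- sqrt(max(0, drop(grad %*% fit$vcov %*% grad)))
    lo <- 10^(log_icx - z * se)
    hi <- 10^(log_icx + z * se)
  } else {
    draws <- bootstrap_icx(fit, level, mode, bootstrap_n, seed)
    qs <- quantile(draws, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }

  tibble::tibble(
    level = level,
    estimate = 10^log_icx,
    ci_low = lo,
    ci_high = hi,
    mode = mode,
    ci_method = ci_method,
    dose_scale = fit$dose_scale
  )
}

bootstrap_icx <- function(fit, level, mode, n_draws, seed) {
  dat <- fit$data
  groups <- split(seq_len(nrow(dat)), dat$dose)
  with_seed_if(seed, {
    vapply(seq_len(n_draws), function(i) {
      idx <- unlist(lapply(groups, function(g) sample(g, length(g), replace = TRUE)),
                    use.names = FALSE)
      f <- tryCatch(fit_4pl(dat[idx, , drop = FALSE], constrain = fit$constrained),
                    error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      est <- tryCatch(invert_icx(f, level, mode = mode, ci_method = "delta")$estimate,
                      error = function(e) NA_real_)
      est
    }, numeric(1))
  })
}

#' Relative potency of a test compound against a reference
#'
#' ReP = IC50(reference) / IC50(test): values above 1 mean the test compound is
#' more potent than the reference. Antisymmetric under swapping the arguments:
#' `relative_potency(a, b) * relative_potency(b, a) == 1`.
#'
#' @param ic50_reference Reference IC50 (same dose units as `ic50_test`).
#' @param ic50_test Test-compound IC50.
#' @return Numeric relative potency (vectorised over `ic50_test`).
#' @examples
#' relative_potency(4.3, 132) # fluometuron vs diuron, ~0.033
#' @export
relative_potency <- function(ic50_reference, ic50_test) {
  if (any(!is.finite(ic50_reference) | ic50_reference <= 0) ||
      any(!is.finite(ic50_test) | ic50_test <= 0)) {
    abort("IC50 values must be positive.", class = "seagrasstox_input_error")
  }
  ic50_reference / ic50_test
}

#' Relative-potency table against a reference herbicide
#'
#' Divides the reference herbicide's IC50 by each row's IC50, duration by
#' duration. When the reference was assayed at a row's duration its matching
#' IC50 is used; otherwise the reference IC50 at `fallback_duration` (default
#' 24 h, the Toxic-Unit basis) is used and flagged in `reference_duration`.
#'
#' @param endpoints Data frame with columns `herbicide`, `duration_h`, `ic50`.
#' @param reference Reference herbicide name, default `"diuron"`.
#' @param fallback_duration Reference duration used when the reference has no
#'   IC50 at a row's duration.
#' @return The input with `rep` and `reference_duration` columns appended.
#' @export
rep_table <- function(endpoints, reference = "diuron", fallback_duration = 24) {
  assert_df_has(endpoints, c("herbicide", "duration_h", "ic50"), "endpoints")
  ref_rows <- endpoints[endpoints$herbicide == reference, , drop = FALSE]
  if (nrow(ref_rows) == 0) {
    abort(sprintf("Reference herbicide '%s' not found.", reference),
          class = "seagrasstox_input_error")
  }
  ref_ic50_for <- function(dur) {
    hit <- ref_rows$ic50[ref_rows$duration_h == dur]
    if (length(hit) > 0) c(hit[1], dur) else {
      fb <- ref_rows$ic50[ref_rows$duration_h == fallback_duration]
      if (length(fb) == 0) {
        abort(sprintf("Reference '%s' has no IC50 at %s h or the fallback %s h.",
                      reference, dur, fallback_duration),
              class = "seagrasstox_input_error")
      }
      c(fb[1], fallback_duration)
    }
  }
  refs <- vapply(endpoints$duration_h, ref_ic50_for, numeric(2))
  tibble::as_tibble(endpoints) |>
    dplyr::mutate(
      rep = relative_potency(refs[1, ], .data$ic50),
      reference = reference,
      reference_duration = refs[2, ]
    )
}

#' Curve overlay for a fitted logistic curve
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot: observations (jittered points), dose-level means, and the
#'   fitted curve on a log10 dose axis.
#' @method autoplot logistic_fit
#' @export
autoplot.logistic_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(dose = 10^seq(log10(min(dat$dose)) - 0.2,
                                       log10(max(dat$dose)) + 0.2, length.out = 200))
  grid$inhibition <- predict(object, grid)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose, y = .data$inhibition)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "steelblue", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = if (identical(object$dose_scale, "TU")) "Toxic units (TU_sum)" else "Concentration (µg/L)",
      y = "Inhibition of ΔF/Fm' (%)",
      title = if (!is.na(object$treatment_id)) object$treatment_id else NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
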