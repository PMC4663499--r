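# Extra-sum-of-squares F-tests between fitted concentration-response curves.
#
# Under the default "shared_bth" scheme both nested models share one bottom,
# top and hill slope across all curves; the full model gives each curve its
# own log10(IC50) while the reduced model forces a single common IC50:
#
#   F = [(SS_reduced - SS_full) / (df_reduced - df_full)] / (SS_full / df_full)
#
# The alternative "separate_all" scheme fits all four parameters per curve in
# the full model and one pooled curve in the reduced model.

# Joint shared-(B,T,h) fit; lambda either per-group or shared.
fit_joint_shared_bth <- function(datasets, share_lambda = FALSE) {
  k <- length(datasets)
  logx <- lapply(datasets, function(d) log10(d$dose[d$dose > 0]))
  y <- lapply(datasets, function(d) d$inhibition[d$dose > 0])
  yy <- unlist(y, use.names = FALSE)
  n <- length(yy)
  idx <- rep(seq_len(k), lengths(y))
  lx <- unlist(logx, use.names = FALSE)
  n_lambda <- if (share_lambda) 1L else k

  resid_fn <- function(p) {
    b <- p[1]; t <- p[2]; h <- p[3]
    lam <- if (share_lambda) rep(p[4], k) else p[3 + seq_len(k)]
    yy - fourpl_mean(lx, b, t, h, lam[idx])
  }
  jac_fn <- function(p) {
    b <- p[1]; t <- p[2]; h <- p[3]
    lam <- if (share_lambda) rep(p[4], k) else p[3 + seq_len(k)]
    full <- fourpl_jacobian(lx, b, t, h, lam[idx])
    out <- matrix(0, n, 3 + n_lambda)
    out[, 1:3] <- full[, 1:3]
    if (share_lambda) {
      out[, 4] <- full[, 4]
    } else {
      for (g in seq_len(k)) out[idx == g, 3 + g] <- full[idx == g, 4]
    }
    -out
  }

  indiv <- lapply(datasets, function(d) {
    tryCatch(fit_4pl(d), error = function(e) NULL)
  })
  ok <- !vapply(indiv, is.null, logical(1))
  if (!any(ok)) {
    abort("No dataset could be fitted individually.", class = "seagrasstox_fit_error")
  }
  b0 <- mean(vapply(indiv[ok], function(f) f$coefficients[["bottom"]], numeric(1)))
  t0 <- mean(vapply(indiv[ok], function(f) f$coefficients[["top"]], numeric(1)))
  h0 <- mean(vapply(indiv[ok], function(f) f$coefficients[["hill"]], numeric(1)))
  lam_ind <- vapply(seq_len(k), function(g) {
    if (ok[g]) indiv[[g]]$coefficients[["log10_ic50"]] else mean(range(logx[[g]]))
  }, numeric(1))
  lam0 <- if (share_lambda) mean(lam_ind) else lam_ind

  # Same box constraints as fit_4pl: the percent-inhibition endpoint bounds
  # the asymptotes, and midpoints are only estimable near the tested range.
  lam_bounds <- if (share_lambda) {
    rng <- range(lx)
    cbind(rng[1] - 1.5, rng[2] + 1.5)
  } else {
    t(vapply(logx, function(l) range(l) + c(-1.5, 1.5), numeric(2)))
  }
  lower <- c(-50, 0, 0.1, lam_bounds[, 1])
  upper <- c(50, 110, 10, lam_bounds[, 2])
  clamp_par <- function(p) pmin(pmax(p, lower), upper)

  starts <- lapply(list(
    c(b0, t0, h0, lam0),
    c(min(yy), max(yy), 1, if (share_lambda) mean(vapply(logx, function(l) mean(range(l)), numeric(1))) else
      vapply(logx, function(l) mean(range(l)), numeric(1)))
  ), clamp_par)
  best <- NULL
  for (p0 in starts) {
    ans <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 300))
      ),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    ss <- sum(ans$fvec^2)
    if (!is.finite(ss)) next
    if (is.null(best) || ss < best$ss) best <- list(par = ans$par, ss = ss)
  }
  if (is.null(best)) {
    abort("Joint fit failed to converge.", class = "seagrasstox_fit_error")
  }
  lam <- if (share_lambda) best$par[4] else best$par[3 + seq_len(k)]
  list(bottom = best$par[1], top = best$par[2], hill = best$par[3],
       log10_ic50 = lam, ss = best$ss, n = n,
       df = n - (3 + n_lambda), n_par = 3 + n_lambda)
}

#' Test whether concentration-response curves share an IC50
#'
#' Extra-sum-of-squares F-test comparing a reduced model in which all curves
#' share one IC50 against a full model in which each curve has its own. A
#' post-hoc table of all pairwise two-curve tests is attached (uncorrected, as
#' letter-group presentations use, with a Holm-adjusted column alongside).
#'
#' @param data A data frame of observations with a grouping column naming the
#'   curve (default `treatment_id`), or a named list of per-curve data frames
#'   or `logistic_fit` objects.
#' @param group Name of the grouping column when `data` is a single data frame.
#' @param sharing `"shared_bth"` (bottom, top and hill shared across curves in
#'   both models; default) or `"separate_all"` (all four parameters per curve
#'   in the full model vs one pooled curve).
#' @param alpha Significance level used when reporting pairwise differences.
#' @return An object of class `ic50_ftest` with the overall `statistic`,
#'   `df`, `p.value`, per-curve IC50s, and a `pairwise` tibble. Methods:
#'   `print()`, `tidy()` (pairwise table), `glance()` (overall test).
#' @export
compare_ic50_ftest <- function(data, group = "treatment_id",
                               sharing = c("shared_bth", "separate_all"),
                               alpha = 0.05) {
  sharing <- match.arg(sharing)
  assert_scalar_number(alpha, "alpha", 0, 1, strict = TRUE)
  datasets <- normalise_curve_list(data, group)
  if (length(datasets) < 2) {
    abort("Need at least two curves to compare.", class = "seagrasstox_input_error")
  }
  res <- ess_ftest(datasets, sharing)

  pair_names <- utils::combn(names(datasets), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pair_names, function(nm) {
    pr <- ess_ftest(datasets[nm], sharing)
    tibble::tibble(curve1 = nm[1], curve2 = nm[2],
                   statistic = pr$statistic, df1 = pr$df1, df2 = pr$df2,
                   p.value = pr$p.value)
  })
  pairwise$p.holm <- stats::p.adjust(pairwise$p.value, method = "holm")
  pairwise$significant <- pairwise$p.value < alpha

  structure(
    list(statistic = res$statistic, df1 = res$df1, df2 = res$df2,
         p.value = res$p.value, sharing = sharing, alpha = alpha,
         ic50 = res$ic50, ic50_shared = res$ic50_shared,
         ss_full = res$ss_full, ss_reduced = res$ss_reduced,
         pairwise = pairwise, n_curves = length(datasets)),
    class = "ic50_ftest"
  )
}

ess_ftest <- function(datasets, sharing) {
  if (sharing == "shared_bth") {
    full <- fit_joint_shared_bth(datasets, share_lambda = FALSE)
    red <- fit_joint_shared_bth(datasets, share_lambda = TRUE)
    ss_full <- full$ss; df_full <- full$df
    ss_red <- red$ss; df_red <- red$df
    ic50 <- setNames(10^full$log10_ic50, names(datasets))
    ic50_shared <- 10^red$log10_ic50
  } else {
    fits <- lapply(datasets, fit_4pl)
    ss_full <- sum(vapply(fits, function(f) f$ss_resid, numeric(1)))
    df_full <- sum(vapply(fits, function(f) f$df, numeric(1)))
    pooled <- fit_4pl(dplyr::bind_rows(datasets))
    ss_red <- pooled$ss_resid; df_red <- pooled$df
    ic50 <- setNames(vapply(fits, function(f) f$ic50, numeric(1)), names(datasets))
    ic50_shared <- pooled$ic50
  }
  df1 <- df_red - df_full
  df2 <- df_full
  if (ss_full <= .Machine$double.eps * max(1, ss_red)) {
    # Perfect full-model fit: identical curves give F = 0, separated curves F = Inf.
    perfect_sep <- ss_red > sqrt(.Machine$double.eps)
    f_stat <- if (perfect_sep) Inf else 0
    p <- if (perfect_sep) 0 else 1
  } else {
    f_stat <- max(0, ((ss_red - ss_full) / df1) / (ss_full / df2))
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  list(statistic = f_stat, df1 = df1, df2 = df2, p.value = p,
       ss_full = ss_full, ss_reduced = ss_red,
       ic50 = ic50, ic50_shared = ic50_shared)
}

normalise_curve_list <- function(data, group) {
  if (is.data.frame(data)) {
    assert_df_has(data, c(group, "dose", "inhibition"), "data")
    datasets <- split(tibble::as_tibble(data), data[[group]])
  } else if (is.list(data)) {
    datasets <- lapply(data, function(d) {
      if (inherits(d, "logistic_fit")) d$data else tibble::as_tibble(d)
    })
    lapply(datasets, assert_df_has, cols = c("dose", "inhibition"), what = "data")
    if (is.null(names(datasets)) || any(names(datasets) == "")) {
      names(datasets) <- paste0("curve", seq_along(datasets))
    }
  } else {
    abort("`data` must be a data frame or a list of curves.",
          class = "seagrasstox_input_error")
  }
  datasets
}

#' @export
print.ic50_ftest <- function(x, ...) {
  cat("Extra-sum-of-squares F-test for equal IC50s (", x$sharing, ")\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g across %d curves\n",
              x$df1, x$df2, x$statistic, x$p.value, x$n_curves))
  cat("  per-curve IC50:", paste(sprintf("%s = %.4g", names(x$ic50), x$ic50),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy ic50_ftest
#' @export
tidy.ic50_ftest <- function(x, ...) x$pairwise

#' @method glance ic50_ftest
#' @export
glance.ic50_ftest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df1 = x$df1, df2 = x$df2, p.value = x$p.value,
    sharing = x$sharing, n_curves = x$n_curves,
    ss_full = x$ss_full, ss_reduced = x$ss_reduced
  )
}
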