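# Independent brute-force SS minimizer for the 4PL model, used only as a test
# oracle. For fixed (hill, lambda = log10 IC50) the model is linear in
# (bottom, top): I = B*(1-w) + T*w with w = 1/(1 + 10^(hill*(lambda - log10 x))),
# so B and T are profiled out by linear least squares; the outer search is a
# coarse grid over (hill, lambda) followed by repeated bracket bisection around
# the incumbent. Shares no code path with fit_4pl.
oracle_fit_4pl <- function(dose, inhibition, n_refine = 45) {
  keep <- dose > 0
  logx <- log10(dose[keep])
  y <- inhibition[keep]
  ss_at <- function(h, lam) {
    w <- 1 / (1 + 10^(h * (lam - logx)))
    fit <- stats::lm.fit(cbind(1 - w, w), y)
    list(ss = sum(fit$residuals^2),
         b = unname(fit$coefficients[1]), t = unname(fit$coefficients[2]))
  }
  best <- list(ss = Inf)
  hs <- seq(0.2, 4, length.out = 30)
  lams <- seq(min(logx) - 1, max(logx) + 1, length.out = 60)
  for (h in hs) for (lam in lams) {
    cand <- ss_at(h, lam)
    if (is.finite(cand$ss) && cand$ss < best$ss) best <- c(cand, list(h = h, lam = lam))
  }
  dh <- hs[2] - hs[1]
  dl <- lams[2] - lams[1]
  for (i in seq_len(n_refine)) {
    dh <- dh / 2
    dl <- dl / 2
    for (h in best$h + c(-dh, 0, dh)) for (lam in best$lam + c(-dl, 0, dl)) {
      cand <- ss_at(h, lam)
      if (is.finite(cand$ss) && cand$ss < best$ss) best <- c(cand, list(h = h, lam = lam))
    }
  }
  list(bottom = best$b, top = best$t, hill = best$h,
       ic50 = 10^best$lam, ss = best$ss)
}

# Noiseless observations from a known 4PL truth.
make_4pl_obs <- function(bottom = 0, top = 100, hill = 1, ic50 = 10,
                         doses = 10^seq(log10(ic50 / 30), log10(ic50 * 30),
                                        length.out = 7),
                         replicates = 1, treatment_id = "truth",
                         dose_scale = "concentration") {
  grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(replicates))
  tibble::tibble(
    treatment_id = treatment_id,
    dose = grid$dose,
    replicate = grid$replicate,
    duration = 24,
    inhibition = bottom + (top - bottom) / (1 + (ic50 / grid$dose)^hill),
    dose_scale = dose_scale
  )
}
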