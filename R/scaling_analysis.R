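#' Fit a power law to rate vs concentration
#'
#' Ordinary least squares on `(ln c, ln rate)`: `rate = A * c^n`. The
#' exponent estimates the reaction order of the rate-limiting step (n ~ 2
#' for a bimolecular step); the pre-exponential factor `A` measures how
#' productive an encounter is.
#'
#' @param concs protein concentrations (uM), all > 0, length >= 3.
#' @param rates maximum aggregation rates (AU/s), all > 0.
#' @param arm optional arm label (e.g. "control", "+inositol").
#' @return A `power_law_fit` list: `A`, `n`, `A_se`, `n_se` (standard
#'   errors; `A_se` by the delta method from the intercept SE), `r2`,
#'   `arm`, and the underlying `lm` fit.
#' @export
fit_power_law <- function(concs, rates, arm = NA_character_) {
  if (length(concs) != length(rates) || length(concs) < 3L)
    stop("need >= 3 matched (concentration, rate) pairs", call. = FALSE)
  if (any(concs <= 0) || any(rates <= 0))
    stop("concentrations and rates must be > 0", call. = FALSE)
  lx <- log(concs); ly <- log(rates)
  fit <- stats::lm(ly ~ lx)
  cf <- summary(fit)$coefficients
  A <- exp(cf[1L, 1L])
  structure(list(A = A, n = cf[2L, 1L],
                 A_se = A * cf[1L, 2L], n_se = cf[2L, 2L],
                 intercept_se = cf[1L, 2L],
                 r2 = summary(fit)$r.squared, arm = arm, lm = fit),
            class = "power_law_fit")
}

#' Compare power-law fits between treatment arms
#'
#' Reports the pre-exponential factor ratio `A_treated / A_control`, the
#' exponent difference `n_treated - n_control`, and normal-approximation
#' z-scores from the fit standard errors (on the log scale for `A`).
#'
#' @param fit_control,fit_treated `power_law_fit` objects.
#' @return List with `A_ratio`, `dn`, `z_A`, `z_n`.
#' @export
compare_arms <- function(fit_control, fit_treated) {
  dlogA <- log(fit_treated$A) - log(fit_control$A)
  se_logA <- sqrt(fit_control$intercept_se^2 + fit_treated$intercept_se^2)
  dn <- fit_treated$n - fit_control$n
  se_n <- sqrt(fit_control$n_se^2 + fit_treated$n_se^2)
  list(A_ratio = fit_treated$A / fit_control$A,
       dn = dn,
       z_A = if (se_logA > 0) dlogA / se_logA else NA_real_,
       z_n = if (se_n > 0) dn / se_n else NA_real_)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit%s: rate = A * c^n\n",
              if (is.na(x$arm)) "" else paste0(" [", x$arm, "]")))
  cat(sprintf("  A = %.4g +/- %.2g   n = %.3f +/- %.3f   R^2 = %.4f\n",
              x$A, x$A_se, x$n, x$n_se, x$r2))
  invisible(x)
}
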