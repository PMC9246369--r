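#!/usr/bin/env Rscript
# Calibration of the shipped default parameter set.
#
# The mechanistic scheme fixes the structure of the model; the two summary
# statistics the default parameterization must reproduce are the percent
# suppression of the tangent-method maximum aggregation rate by 100 mM
# myo-inositol:
#   * 35% for 40 uM protein under fully oxidizing conditions (0.5 mM GSSG),
#   * 51% on average across the six OxD 0.15-0.40 redox buffers
#     (50 uM protein, 2 mM total glutathione).
# The free calibration parameters are the inhibition constant K_I and the
# dimerization rate k_dim (the split between the two targets is controlled
# by how far the locked-precursor pool is from quasi-equilibrium at the
# time of maximum rate); all other rates are fixed at round values chosen
# for trace shape (sigmoidal, 4.5 h span) and are documented in the
# methods vignette. Least squares on the two percentages.
#
# Usage: Rscript scripts/calibrate.R [--out inst/extdata/default_params.json]

suppressMessages({
  if (requireNamespace("crystagg", quietly = TRUE)) library(crystagg)
  else devtools::load_all(".", quiet = TRUE)
})

args <- commandArgs(trailingOnly = TRUE)
out <- "inst/extdata/default_params.json"
if (length(args) >= 2 && args[1] == "--out") out <- args[2]

fixed <- list(k_mis = 8e-4, k_fold = 4e-3, k_ox = 1.0, k_red = 0.1,
              k_diss = 5e-4, k_nuc = 5e-3, k_elong = 2e-4,
              k_coal = 1e-3, k_settle = 2e-4,
              w_P = 0.02, w_G = 0.04,
              dim_oxidizes = FALSE, inhibit_coal = FALSE)

make_params <- function(logKI, logkdim) {
  do.call(rate_params, c(fixed, list(K_I = exp(logKI),
                                     k_dim = exp(logkdim))))
}

targets <- c(full_ox = 35, redox_mean = 51)

objective <- function(x) {
  p <- make_params(x[1], x[2])
  t3 <- suppression_full_ox(p)
  t4 <- attr(suppression_redox_panel(p), "mean_suppression_pct")
  cat(sprintf("  K_I = %7.2f  k_dim = %.3e  ->  full-ox %.2f%%  redox %.2f%%\n",
              exp(x[1]), exp(x[2]), t3, t4))
  (t3 - targets["full_ox"])^2 + (t4 - targets["redox_mean"])^2
}

cat("Calibrating (K_I, k_dim) by least squares on the two suppression",
    "percentages...\n")
fit <- optim(c(log(50), log(3e-7)), objective, method = "Nelder-Mead",
             control = list(reltol = 1e-4, maxit = 60))

params <- make_params(fit$par[1], fit$par[2])
t3 <- suppression_full_ox(params)
t4 <- attr(suppression_redox_panel(params), "mean_suppression_pct")
cat(sprintf("\nCalibrated: K_I = %.4g mM, k_dim = %.6g 1/(uM s)\n",
            params$K_I, params$k_dim))
cat(sprintf("  full-ox suppression  %.2f%% (target 35%%)\n", t3))
cat(sprintf("  redox-panel mean     %.2f%% (target 51%%)\n", t4))

save_params_json(params, out,
                 observable = list(
                   note = paste("turbidity = w_P*P1 + w_G*(G1+S1);",
                                "w_G = 2*w_P permits biphasic traces")))
cat("Wrote ", out, "\n", sep = "")
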