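#' Percent suppression of the maximum aggregation rate by inositol
#'
#' Simulates one well condition noise-free with and without inositol,
#' extracts the tangent-method maximum rate from both traces, and reports
#' the percent rate suppression `100 * (1 - rate_inositol / rate_control)`.
#'
#' @param cond a `well_condition`; its `inositol_mM` field gives the
#'   control arm (normally 0).
#' @param inositol_mM treated-arm inositol (mM; default 100).
#' @param params a `rate_params` object.
#' @param phase_rule passed to [tangent_fit()] (`"global_max"` or
#'   `"second_phase"`; the second-phase rule is used for conditions whose
#'   traces go biphasic).
#' @param duration_s,read_interval_s assay grid (defaults 16200 s, 90 s).
#' @return List with `suppression_pct`, `rate_control`, `rate_treated`,
#'   `fit_control`, `fit_treated`.
#' @export
rate_suppression <- function(cond, inositol_mM = 100,
                             params = default_params(),
                             phase_rule = "global_max",
                             duration_s = 16200, read_interval_s = 90) {
  times <- seq(0, duration_s, by = read_interval_s)
  cond_trt <- cond
  cond_trt$inositol_mM <- inositol_mM
  tr0 <- simulate_condition(cond, params, times)
  tr1 <- simulate_condition(cond_trt, params, times)
  f0 <- tangent_fit(tr0, phase_rule = phase_rule)
  f1 <- tangent_fit(tr1, phase_rule = phase_rule)
  list(suppression_pct = 100 * (1 - f1$max_rate / f0$max_rate),
       rate_control = f0$max_rate, rate_treated = f1$max_rate,
       fit_control = f0, fit_treated = f1)
}

#' Rate suppression under fully oxidizing conditions
#'
#' The fully oxidizing reference assay: 40 uM protein with 0.5 mM GSSG
#' and no GSH, with and without 100 mM inositol.
#'
#' @param params a `rate_params` object.
#' @param inositol_mM treated-arm inositol (default 100 mM).
#' @return Percent suppression of the maximum rate.
#' @export
suppression_full_ox <- function(params = default_params(),
                                inositol_mM = 100) {
  cond <- well_condition(protein_uM = 40, inositol_mM = 0, oxd = 1,
                         total_glutathione_mM = 1)  # = 0.5 mM GSSG, no GSH
  rate_suppression(cond, inositol_mM, params)$suppression_pct
}

#' Rate suppression across the glutathione redox-buffer panel
#'
#' The redox panel: 50 uM protein at 2 mM total glutathione, OxD 0.15 to
#' 0.40 in steps of 0.05, with and without 100 mM inositol. The kinetic
#' statistics use the second-phase rule, since traces in the
#' least-oxidizing buffers with inositol go biphasic.
#'
#' @param params a `rate_params` object.
#' @param oxd_values OxD grid (default `seq(0.15, 0.40, 0.05)`).
#' @param inositol_mM treated-arm inositol (default 100 mM).
#' @param protein_uM protein (default 50 uM).
#' @param total_glutathione_mM total glutathione (default 2 mM).
#' @return data.frame with `oxd` and `suppression_pct`; the mean over the
#'   panel is attached as attribute `mean_suppression_pct`.
#' @export
suppression_redox_panel <- function(params = default_params(),
                                    oxd_values = seq(0.15, 0.40, by = 0.05),
                                    inositol_mM = 100, protein_uM = 50,
                                    total_glutathione_mM = 2) {
  supp <- vapply(oxd_values, function(x) {
    cond <- well_condition(protein_uM = protein_uM, inositol_mM = 0,
                           oxd = x,
                           total_glutathione_mM = total_glutathione_mM)
    rate_suppression(cond, inositol_mM, params,
                     phase_rule = "second_phase")$suppression_pct
  }, numeric(1))
  out <- data.frame(oxd = oxd_values, suppression_pct = supp)
  attr(out, "mean_suppression_pct") <- mean(supp)
  out
}

#' Concentration-dependence (dilution series) of the maximum rate
#'
#' Simulates a dilution series at fixed redox and inositol conditions and
#' returns the per-concentration tangent-method maximum rates, ready for
#' [fit_power_law()].
#'
#' @param protein_uM concentrations (uM).
#' @param params a `rate_params` object.
#' @param inositol_mM inositol (mM).
#' @param oxd,total_glutathione_mM redox buffer composition.
#' @param phase_rule passed to [tangent_fit()].
#' @param duration_s,read_interval_s assay grid.
#' @return data.frame with `protein_uM` and `max_rate`.
#' @export
dilution_series_rates <- function(protein_uM, params = default_params(),
                                  inositol_mM = 0, oxd = 0.2,
                                  total_glutathione_mM = 2,
                                  phase_rule = "global_max",
                                  duration_s = 16200,
                                  read_interval_s = 90) {
  times <- seq(0, duration_s, by = read_interval_s)
  rates <- vapply(protein_uM, function(c0) {
    cond <- well_condition(protein_uM = c0, inositol_mM = inositol_mM,
                           oxd = oxd,
                           total_glutathione_mM = total_glutathione_mM)
    tr <- simulate_condition(cond, params, times)
    tangent_fit(tr, phase_rule = phase_rule)$max_rate
  }, numeric(1))
  data.frame(protein_uM = protein_uM, max_rate = rates)
}
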