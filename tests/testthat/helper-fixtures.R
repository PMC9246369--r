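# Shared fixtures: parameter variants and analytic traces.

# Default parameters with selected fields overridden.
mk_params <- function(...) {
  over <- list(...)
  base <- unclass(default_params())
  attributes(base) <- list(names = names(base))
  do.call(rate_params, utils::modifyList(base, over))
}

# Analytic logistic turbidity trace on the plate-reader grid.
logistic_trace <- function(L = 1, k = 0.02, t0 = 6000, base = 0,
                           times = seq(0, 16200, by = 90)) {
  turbidity_trace(times, base + L / (1 + exp(-k * (times - t0))))
}

# Standard assay grid.
assay_times <- function(duration = 16200, interval = 90) {
  seq(0, duration, by = interval)
}

# Noise-free trace for one condition under given parameters.
sim_trace <- function(protein = 40, inositol = 0, oxd = 1, total = 1,
                      params = default_params(), times = assay_times()) {
  cond <- well_condition(protein_uM = protein, inositol_mM = inositol,
                         oxd = oxd, total_glutathione_mM = total)
  crystagg:::simulate_condition(cond, params, times)
}
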