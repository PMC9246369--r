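#!/usr/bin/env Rscript
# Step 5: late-addition protocol. Samples aggregate undisturbed at
# OxD 0.2 (75 and 50 uM protein, 60 uL), then 40 uL of inositol solution
# or blank buffer is added after the rapid phase and incubation resumes.
# The question: does inositol still slow turbidity development when added
# to an already-turbid solution?
#
# Outputs: results/late_addition_traces.csv,
#          results/late_addition_rates.csv

suppressMessages(library(crystagg))
dir.create("results", showWarnings = FALSE)
params <- default_params()

added <- c(blank = 0, ino100 = 250, ino200 = 500)  # added-solution mM
conds <- list()
for (prot in c(75, 50)) for (a in names(added)) {
  id <- sprintf("p%d_%s", prot, a)
  conds[[id]] <- well_condition(protein_uM = prot, inositol_mM = 0,
                                oxd = 0.2, total_glutathione_mM = 2,
                                volume_uL = 60)
}
design <- plate_design(conds, noise_sigma = 0, baseline_sd = 0,
                       seed = 303)
plate <- late_addition_plate(design, addition_time_s = 5400,
                             added_inositol_mM = rep(added, 2),
                             added_volume_uL = 40, params = params)
write_plate_csv(plate, "results/late_addition_traces.csv")

post_rate <- function(tr) {
  post <- tr$time >= 5580
  sub <- turbidity_trace(tr$time[post], tr$turbidity[post])
  suppressWarnings(tangent_fit(sub))$max_rate
}
rates <- data.frame(well = names(plate),
                    final_inositol_mM = rep(added, 2) * 0.4,
                    post_rate_AU_per_s = vapply(plate, post_rate,
                                                numeric(1)))
write.csv(rates, "results/late_addition_rates.csv", row.names = FALSE)
for (prot in c(75, 50)) {
  r <- rates[grepl(paste0("p", prot), rates$well), ]
  message(sprintf(
    "%d uM: post-addition rate %.2e (blank) -> %.2e (100 mM) -> %.2e (200 mM) AU/s",
    prot, r$post_rate_AU_per_s[1], r$post_rate_AU_per_s[2],
    r$post_rate_AU_per_s[3]))
}
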