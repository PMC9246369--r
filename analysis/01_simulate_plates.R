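#!/usr/bin/env Rscript
# Step 1: generate the synthetic plate-reader datasets used by the later
# analysis steps, with the shipped default-calibrated kinetic parameters.
#
#  * a dose-response plate: 40 uM protein, fully oxidizing buffer
#    (0.5 mM GSSG), 8-point myo-inositol series, triplicate noisy wells;
#  * a redox-panel plate: 50 uM protein, 2 mM total glutathione,
#    OxD 0.15-0.40, with and without 100 mM inositol.
#
# Outputs: results/plate_dose_response.csv, results/plate_redox_panel.csv

suppressMessages(library(crystagg))
dir.create("results", showWarnings = FALSE)
params <- default_params()

doses <- c(0, 10, 25, 50, 100, 200, 350, 500)
conds <- lapply(doses, function(d)
  well_condition(protein_uM = 40, inositol_mM = d, oxd = 1,
                 total_glutathione_mM = 1))   # 0.5 mM GSSG, no GSH
names(conds) <- sprintf("dose%03d", doses)
dose_design <- plate_design(conds, replicates = 3, seed = 101)
dose_plate <- make_plate(dose_design, params)
write_plate_csv(dose_plate, "results/plate_dose_response.csv")
message("dose-response plate: ", length(dose_plate), " traces, ",
        "inositol 0-500 mM")

oxds <- seq(0.15, 0.40, by = 0.05)
redox_conds <- list()
for (x in oxds) for (ino in c(0, 100)) {
  id <- sprintf("oxd%02.0f_ino%03d", 100 * x, ino)
  redox_conds[[id]] <- well_condition(protein_uM = 50, inositol_mM = ino,
                                      oxd = x, total_glutathione_mM = 2)
}
redox_design <- plate_design(redox_conds, replicates = 3, seed = 202)
redox_plate <- make_plate(redox_design, params)
write_plate_csv(redox_plate, "results/plate_redox_panel.csv")
message("redox-panel plate: ", length(redox_plate), " traces, OxD ",
        min(oxds), "-", max(oxds))
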