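#!/usr/bin/env Rscript
# Build the synthetic study fixtures: a reference shift table for a
# 354-residue G-alpha subunit, free/bound TROSY peak-list pairs for the
# GBA-construct ("givct") and GBA-peptide ("givpept") profiles, a
# six-point titration, and the mutant FP/activity panel tables.
# Everything is written as plain text under results/fixtures/.

suppressPackageStartupMessages(library(gbamap))
fix <- "results/fixtures"
dir.create(fix, showWarnings = FALSE, recursive = TRUE)
seed <- 1

shifts <- gen_shift_table(250, seed = seed)
write_shift_table(shifts, file.path(fix, "reference_shifts.tsv"))
cat(sprintf("shift table: %d backbone + %d indole entries, min spacing %.4f scaled ppm\n",
            sum(shifts$atom_group == "backbone-amide"),
            sum(shifts$atom_group == "trp-indole"),
            min_scaled_spacing(shifts)))

for (prof_name in c("givct", "givpept")) {
  prof <- default_profile(prof_name)
  pair <- gen_peaklist_pair(shifts, prof, seed = seed + 1)
  write_peaklist(strip_assignments(pair$free),
                 file.path(fix, paste0(prof_name, "_free.list")))
  write_peaklist(strip_assignments(pair$bound),
                 file.path(fix, paste0(prof_name, "_bound.list")))
  cat(sprintf("%s: binding site of %d residues, %d bound peaks (broadened: %s)\n",
              prof_name, length(pair$truth$site), nrow(pair$bound),
              paste(prof$broadened_out, collapse = ", ")))
}

ts <- gen_titration(shifts, default_profile("givct"), kd_uM = 10,
                    protein_uM = 32, seed = seed + 1)
for (i in seq_along(ts$molar_ratios)) {
  write_peaklist(strip_assignments(ts$peaklists[[i]]),
                 file.path(fix, sprintf("titration_ratio_%02d.list", i)))
}
cat(sprintf("titration: ratios 1:%s, f_bound at endpoint %.3f\n",
            paste(ts$molar_ratios[-1], collapse = "/1:"),
            attr(ts, "truth")$f_bound[length(ts$molar_ratios)]))

truth <- gen_panel_truth(n_mutants = 12, rho = 0.97, seed = seed + 2)
fp <- gen_fp_panel(truth, seed = seed + 3)
write.csv(fp, file.path(fix, "fp_curves.csv"), row.names = FALSE, quote = FALSE)
act <- gen_activity_panel(truth, seed = seed + 4)
write.csv(act, file.path(fix, "activity.csv"), row.names = FALSE, quote = FALSE)
cat(sprintf("panel: %d mutants x %d ligands, cross-ligand effect rho %.2f\n",
            length(truth$variants) - 1, length(truth$ligands), truth$rho))
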