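#!/usr/bin/env Rscript
# End-to-end residue-level perturbation mapping on the shipped synthetic
# conditions: referencing-offset estimation, assignment transfer,
# titration tracking of the bound form, CSP / intensity-ratio statistics
# with median-multiple classes, region summaries over the G-boxes and
# switches, and the class-coded structure. Outputs under
# results/perturbation_run/.

suppressPackageStartupMessages(library(gbamap))

cfg <- pipeline_config(out_dir = "results/perturbation_run", seed = 1,
                       profile = "givct", n_residues = 250)
res <- suppressWarnings(run_pipeline(cfg))

cat("recovered offsets: ")
print(res$offsets)
med <- attr(res$records, "medians")
cat(sprintf("%d residues quantified; median CSP %.4f ppm, median I_ratio %.2f\n",
            nrow(res$records), med["csp"], med["i_ratio"]))

key <- c("G-1/P-loop", "G-2/SwI", "SwII", "G-4", "G-5")
sub <- res$regions[res$regions$name %in% key,
                   c("name", "n_data", "top_class", "status")]
print(sub, row.names = FALSE)
ok <- all(sub$status[match(c("G-1/P-loop", "G-2/SwI"), sub$name)] == "perturbed") &&
  all(sub$status[match(c("G-4", "G-5"), sub$name)] == "unperturbed")
cat(if (ok) {
  "=> nucleotide phosphate-side elements (G-1/P-loop, G-2/SwI) perturbed;\n   guanine-side elements (G-4, G-5) untouched - the GBA signature.\n"
} else {
  "=> WARNING: the expected G-box contrast was not reproduced on this run.\n"
})
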