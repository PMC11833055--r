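#!/usr/bin/env Rscript
# Simulate the three-study panel: a spaceflight-like reference (rho = 1) and
# two ground models with high (0.8) and low (0.2) concordance to it.
# Writes per-study count matrices, sample sheets and the planted truth table.

suppressPackageStartupMessages(library(fcconcord))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(rho = c(FL = 1, CS = 0.8, HU = 0.2), seed = 20260901L)
panel <- simulate_panel(cfg)

for (s in names(panel$studies)) {
  write_study_tsv(panel$studies[[s]],
                  file.path(out_dir, paste0(s, "_counts.tsv")),
                  file.path(out_dir, paste0(s, "_samples.tsv")))
}

truth <- data.frame(gene_id = panel$truth$genes,
                    is_de = panel$truth$is_de,
                    beta_ref = panel$truth$beta_ref,
                    panel$truth$beta_study, check.names = FALSE)
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genes (%d differential) x %d studies, %d+%d samples each.\n",
            cfg$n_genes, sum(panel$truth$is_de), length(panel$studies),
            cfg$n_per_group, cfg$n_per_group))
cat("Planted concordance to FL:  CS = 0.8, HU = 0.2\n")
cat("Outputs under", out_dir, "\n")
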