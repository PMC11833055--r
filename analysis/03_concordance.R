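#!/usr/bin/env Rscript
# Cross-model concordance: align the studies on shared genes, compute all
# pairwise L1 fold-change distances S, rank the ground models by similarity
# to the FL reference, partition the three DEG sets, and select the
# heatmap gene panel (P < 0.05 and FC > 2 or < 0.5 in at least one model).

suppressPackageStartupMessages(library(fcconcord))

deg_dir <- "results/deg"
out_dir <- "results/concordance"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

studies <- sub("_deg_table\\.tsv$", "",
               basename(Sys.glob(file.path(deg_dir, "*_deg_table.tsv"))))
profiles <- lapply(studies, function(s)
  read_profile(file.path(deg_dir, paste0(s, "_deg_table.tsv")), label = s))

m <- intersect_profiles(profiles)
write_shared_matrix(m, file.path(out_dir, "shared_log2fc_matrix.tsv"))
cat(sprintf("%d genes shared by all %d studies.\n",
            length(m$genes), length(studies)))

dm <- distance_matrix(m)
print(dm)
write.table(data.frame(study = rownames(dm$values), dm$values,
                       check.names = FALSE),
            file.path(out_dir, "distance_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

if ("FL" %in% studies) {
  ranking <- rank_by_similarity(dm, "FL")
  write.table(ranking, file.path(out_dir, "ranking_vs_FL.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("Similarity ranking to FL (ascending S):",
      paste(ranking$label, collapse = " < "), "\n")
}

sets <- lapply(profiles, deg_set)
names(sets) <- studies
venn <- venn_partition(sets[[1]], sets[[2]], sets[[3]],
                       labels = studies[1:3])
print(venn)
write.table(data.frame(region = names(venn$counts), count = venn$counts),
            file.path(out_dir, "venn_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

hm <- select_heatmap_genes(m, profiles)
writeLines(hm, file.path(out_dir, "heatmap_genes.txt"))
cat(sprintf("%d shared genes pass the heatmap criteria in >= 1 model.\n",
            length(hm)))
cat("Outputs under", out_dir, "\n")
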