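#!/usr/bin/env Rscript

## Step 4: expression-side integration. Builds the floored log2 FPKM
## ratio matrix over genes called DE at any stage (hierarchically
## ordered), tests gene-set overlaps against the annotated universe,
## associates each stage's DE genes with their nearest differential
## THSS, and tallies enhancer overlap of differential distal THSSs.

suppressPackageStartupMessages(library(thssdiff))

ds <- load_synthetic_dataset("results/synthetic_data")
out <- "results/integration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- data.frame(gene_id = ds$expression$gene_id,
                   stage = sub("^HD_", "", ds$expression$sample_2),
                   fpkm_wt = ds$expression$value_1,
                   fpkm_hd = ds$expression$value_2,
                   q = ds$expression$q_value)
expr$is_de <- expr$q < 0.05
de_any <- sort(unique(expr$gene_id[expr$is_de]))
message(length(de_any), " genes DE at any stage (q < 0.05)")

lr <- build_logratio_matrix(expr, gene_order = de_any,
                            stage_order = unique(expr$stage))
lr <- lr[hierarchical_order(lr), , drop = FALSE]
write.table(data.frame(gene_id = rownames(lr), lr, check.names = FALSE),
            file.path(out, "logratio_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

gs <- do.call(rbind, lapply(names(ds$gene_sets), function(id) {
  t <- geneset_overlap_test(de_any, ds$gene_sets[[id]],
                            ds$genes$gene_id)
  data.frame(set_id = id, N11 = t$N11, N12 = t$N12, N21 = t$N21,
             N22 = t$N22, fraction_pct = t$fraction_pct, p = t$p)
}))
write.table(gs, file.path(out, "geneset_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("gene-set overlaps: ",
        paste(sprintf("%s %.1f%% (p = %.2g)", gs$set_id,
                      gs$fraction_pct, gs$p), collapse = "; "))

assoc <- list()
enh <- list()
for (stage in unique(expr$stage)) {
  d <- read.table(sprintf("results/differential/differential_%s.tsv",
                          stage),
                  sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  dp <- d[d$selected, ]
  de_genes <- ds$genes[ds$genes$gene_id %in%
                         expr$gene_id[expr$is_de & expr$stage == stage], ]
  if (nrow(dp) > 0 && nrow(de_genes) > 0) {
    a <- nearest_diff_peak_per_gene(de_genes, dp)
    assoc[[stage]] <- cbind(stage = stage, a)
  }
  ov <- enhancer_overlap_counts(dp[dp$proximity == "distal", ],
                                ds$enhancers, ds$genes)
  enh[[stage]] <- data.frame(stage = stage,
                             enhancers_hit = ov$enhancers_hit,
                             thss_hitting = ov$thss_hitting,
                             intragenic_fraction = ov$intragenic_fraction)
}
assoc <- do.call(rbind, assoc)
write.table(assoc, file.path(out, "nearest_peak_associations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(round(100 * mean(assoc$within_250kb), 1),
        "% of nearest differential THSSs lie within 250 kb of their ",
        "DE gene's promoter")
enh <- do.call(rbind, enh)
write.table(enh, file.path(out, "enhancer_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
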