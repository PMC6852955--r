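#!/usr/bin/env Rscript

## Step 3: motif enrichment at differential THSSs. Scans every peak's
## 200-bp summit window against the motif library with exact score
## p-values, keeps the best motif per peak, and tests each motif's
## nested contingency (direction set vs all peaks) with Fisher's exact
## test, separately per stage, direction (HD-up / WT-up) and context
## (proximal / distal). Raw p-values, no multiple-test adjustment.

suppressPackageStartupMessages(library(thssdiff))

ds <- load_synthetic_dataset("results/synthetic_data")
out <- "results/motifs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seqs <- summit_window_sequences(ds$genome, ds$peaks)
hits <- scan_peak_windows(seqs, ds$pwms)
dedup <- best_hit_per_peak(hits)
message(nrow(hits), " raw hits; ", nrow(dedup),
        " peaks keep a best motif")
write.table(dedup, file.path(out, "best_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

enrich <- list()
for (stage in names(ds$fragments)) {
  d <- read.table(sprintf("results/differential/differential_%s.tsv",
                          stage),
                  sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  info <- data.frame(peak_id = d$peak_id, direction = d$direction,
                     proximity = d$proximity)
  e <- enrichment_scan(dedup, info, motif_ids = names(ds$pwms))
  enrich[[stage]] <- cbind(stage = stage, e)
  top <- e[e$direction == "HD_up" & e$context == "distal", ]
  top <- top[order(top$p), ][1, ]
  message(stage, ": top HD-up distal motif ", top$motif_id,
          " (p = ", signif(top$p, 3), ")")
}
enrich <- do.call(rbind, enrich)
write.table(enrich, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sum(enrich$significant), " of ", nrow(enrich),
        " motif/stage/direction/context combinations at p < 0.05")
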