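#!/usr/bin/env Rscript

## Step 1: generate the synthetic two-condition (HD vs WT) study —
## genome + annotation, peaks with planted differential accessibility,
## motifs planted in HD-up summit windows, per-stage/replicate fragment
## sets, stage-patterned expression, gene sets and enhancers — and write
## it to results/synthetic_data/ in the pipeline's input formats.

suppressPackageStartupMessages(library(thssdiff))

cfg <- synthetic_config(seed = 1L)
message("generating dataset (seed ", cfg$seed, ") ...")
ds <- generate_synthetic_dataset(cfg)

out <- "results/synthetic_data"
write_synthetic_dataset(ds, out)

tr <- ds$truth$peaks
message("wrote ", out, ":")
message("  chromosomes: ", paste(names(ds$chrom_lengths), collapse = ", "))
message("  genes: ", nrow(ds$genes), "; peaks: ", nrow(ds$peaks))
message("  planted differential peaks: ", sum(tr$is_differential),
        " (", sum(tr$is_differential & tr$excluded),
        " on excluded chromosomes)")
message("  planted motif occurrences (", names(ds$pwms)[1], "): ",
        sum(ds$truth$motifs$motif_id == names(ds$pwms)[1]))
message("  DE-truth genes: ", sum(ds$truth$genes$is_de_any),
        " of ", nrow(ds$genes))
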