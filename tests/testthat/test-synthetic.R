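test_that("generation is deterministic given the seed", {
  cfg <- small_config(seed = 99L)
  d1 <- generate_synthetic_dataset(cfg)
  d2 <- generate_synthetic_dataset(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$fragments, d2$fragments)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_synthetic_dataset(small_config(seed = 100L))
  expect_false(identical(d1$genome, d3$genome))
})

test_that("the random genome is near-uniform and genes stay in bounds", {
  set.seed(81)
  g <- make_genome(synthetic_config(n_chroms = 1L, chrom_length = 1e6,
                                    n_genes = 100L))
  gc <- sum(strsplit(g$genome[["chr1"]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
  genes <- g$genes
  expect_true(all(genes$start >= 0 & genes$end <= 1e6))
  ## non-overlapping bodies
  o <- order(genes$start)
  expect_true(all(genes$end[o][-nrow(genes)] <= genes$start[o][-1]))
  expect_true(all(genes$tss >= genes$start & genes$tss < genes$end))
  ## empty annotation supported
  set.seed(82)
  g0 <- make_genome(synthetic_config(n_genes = 0L, chrom_length = 1e4,
                                     decoy_length = 1e3))
  expect_equal(nrow(g0$genes), 0L)
  expect_equal(names(g0$genome), c("chr1", "chr2", "chr2a", "chr2b"))
})

test_that("planted peaks show the configured fold change and scale bias", {
  cfg <- small_config(seed = 83L, mean_count = 100)
  ds <- generate_synthetic_dataset(cfg)
  frag <- ds$fragments$PSC
  hd <- rbind(frag$HD[[1]], frag$HD[[2]])
  wt <- rbind(frag$WT[[1]], frag$WT[[2]])
  x_hd <- count_fragments_in_peaks(hd, ds$peaks)$counts
  x_wt <- count_fragments_in_peaks(wt, ds$peaks)$counts
  fit <- fit_ma_normalization(x_hd, x_wt,
                              common = !ds$peaks$is_differential)
  x_wt_n <- apply_normalization(x_hd, x_wt, fit)
  lfc <- log2((x_hd + 0.5) / (x_wt_n + 0.5))
  up <- ds$peaks$direction == "HD_up"
  dn <- ds$peaks$direction == "HD_down"
  expect_lt(abs(mean(lfc[up]) - cfg$true_logFC), 0.5)
  expect_lt(abs(mean(lfc[dn]) + cfg$true_logFC), 0.5)
  ## the library-scale bias matches the configured factor
  A <- 0.5 * log2((x_hd + 0.5) * (x_wt + 0.5))
  est <- fit$intercept + fit$slope * mean(A[!ds$peaks$is_differential])
  expect_lt(abs(est - log2(cfg$scale_factor)), 0.15)
})

test_that("no planted signal and no scale bias give a null MA fit", {
  cfg <- small_config(seed = 84L, frac_differential = 0,
                      scale_factor = 1)
  ds <- generate_synthetic_dataset(cfg)
  frag <- ds$fragments$NPC
  x1 <- count_fragments_in_peaks(rbind(frag$HD[[1]], frag$HD[[2]]),
                                 ds$peaks)$counts
  x2 <- count_fragments_in_peaks(rbind(frag$WT[[1]], frag$WT[[2]]),
                                 ds$peaks)$counts
  fit <- fit_ma_normalization(x1, x2)
  A <- 0.5 * log2((x1 + 0.5) * (x2 + 0.5))
  expect_lt(abs(fit$intercept + fit$slope * mean(A)), 0.1)
})

test_that("planted motif occurrences are recovered by the scanner", {
  cfg <- small_config(seed = 85L, planted_motif_rate = 1,
                      background_motif_rate = 0)
  ds <- generate_synthetic_dataset(cfg)
  up_ids <- ds$peaks$peak_id[ds$peaks$direction == "HD_up"]
  seqs <- summit_window_sequences(ds$genome, ds$peaks)
  hits <- scan_peak_windows(seqs[up_ids], ds$pwms[1])
  found <- unique(hits$peak_id)
  planted <- ds$truth$motifs$peak_id[ds$truth$motifs$motif_id ==
                                       names(ds$pwms)[1]]
  expect_gte(length(intersect(planted, found)),
             ceiling(0.95 * length(planted)))
  ## planted positions recorded in truth match the genome content
  tm <- ds$truth$motifs[1, ]
  cons <- paste(c("A", "C", "G", "T")[
    apply(ds$pwms[[tm$motif_id]]$probs, 1, which.max)], collapse = "")
  L <- nchar(cons)
  chrom <- ds$peaks$chrom[ds$peaks$peak_id == tm$peak_id]
  word <- substr(ds$genome[[chrom]], tm$position + 1, tm$position + L)
  if (tm$strand == "-")
    word <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(word)))
  expect_equal(word, cons)
})

test_that("expression truth drives calls at the configured power", {
  ## null: no effect -> nominal type-I rate
  cfg0 <- small_config(seed = 86L, de_fraction = 0, n_genes = 400L,
                       chrom_length = 2e6)
  set.seed(cfg0$seed)
  g <- make_genome(cfg0)
  e0 <- simulate_expression(cfg0, g$genes)
  frac <- mean(e0$table$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(e0$table)))
  ## planted effects at 3 replicates are nearly always recovered
  cfg1 <- small_config(seed = 87L, n_replicates = 3L)
  set.seed(cfg1$seed)
  g1 <- make_genome(cfg1)
  e1 <- simulate_expression(cfg1, g1$genes)
  tab <- e1$table
  tab$stage <- sub("^HD_", "", tab$sample_2)
  truth_long <- sapply(cfg1$stages, function(s)
    e1$truth[[paste0("de_", s)]])
  called <- sapply(cfg1$stages, function(s)
    tab$q_value[tab$stage == s] < 0.05)
  expect_gte(mean(called[truth_long]), 0.8)
})

test_that("datasets round-trip through the on-disk text formats", {
  cfg <- small_config(seed = 88L, n_stages = 2L, mean_count = 20)
  ds <- generate_synthetic_dataset(cfg)
  dir <- tempfile("ds")
  write_synthetic_dataset(ds, dir)
  back <- load_synthetic_dataset(dir)
  expect_identical(back$genome, ds$genome)
  expect_equal(back$genes, ds$genes)
  expect_equal(back$peaks$summit, ds$peaks$summit)
  expect_equal(names(back$fragments), names(ds$fragments))
  expect_equal(back$fragments$PSC$HD[[2]][, c("chrom", "start", "end")],
               ds$fragments$PSC$HD[[2]])
  expect_equal(back$gene_sets, ds$gene_sets)
  expect_equal(back$truth$peaks$direction, ds$truth$peaks$direction)
  ## byte determinism of the writer
  dir2 <- tempfile("ds")
  write_synthetic_dataset(generate_synthetic_dataset(cfg), dir2)
  f1 <- list.files(dir, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})
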