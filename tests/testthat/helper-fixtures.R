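# Small-scale generator configuration for fast unit tests; the
# default-scale configuration is exercised by the end-to-end recovery
# tests.
small_config <- function(seed = 42L, ...) {
  defaults <- list(chrom_length = 2e5, decoy_length = 5e4, n_genes = 40L,
                   n_peaks = 200L, mean_count = 60, n_motifs = 5L,
                   n_enhancers = 30L)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(synthetic_config, c(list(seed = seed), defaults))
}

random_regions <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e4,
                           max_width = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE))
}

random_genes <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e4) {
  g <- random_regions(n, chroms, max_pos, max_width = 800)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = g$chrom,
             strand = strand, start = g$start, end = g$end,
             tss = ifelse(strand == "+", g$start, g$end - 1L),
             tes = ifelse(strand == "+", g$end - 1L, g$start))
}

# Independent brute-force Fisher p: enumerate all tables with the
# observed margins and sum the probabilities (computed from binomial
# coefficients directly) of those no more likely than the observed one.
enumerate_fisher <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; r2 <- n21 + n22; c1 <- n11 + n21
  ks <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(ks, function(k)
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1)),
    numeric(1))
  obs <- prob[ks == n11]
  sum(prob[prob <= obs * (1 + 1e-7)])
}
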