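## Seeded synthetic-data generator. Emulates the structure of a
## two-condition (HD vs WT), four-stage, two-replicate ATAC-seq/RNA-seq
## study: a small random genome with gene models and decoy chromosomes,
## non-overlapping peaks with planted differential accessibility, planted
## motif enrichment in one direction's peaks, promoter mononucleosome
## occupancy differences, and stage-patterned differentially expressed
## genes — all with recorded ground truth.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions every recovery test assumes:
#' 2 main chromosomes of 1 Mb plus chr2a/chr2b decoys, 200 genes, 1000
#' peaks of which 10\% are differential at |log2 fold change| 4, a 1.5x
#' library-scale bias between conditions, 20 motifs with the first one
#' planted in 80\% of HD-up peaks against a 10\% background rate, and
#' 30\% of genes differentially expressed (log2 effect 3) in
#' stage-specific patterns across 4 stages x 2 replicates.
#'
#' Counting noise is Poisson around a per-peak intensity shared by the
#' two conditions; that intensity is gamma-distributed with dispersion
#' `nb_dispersion`, so marginal counts are negative-binomial while the
#' two conditions stay exactly binomially exchangeable under the null.
#'
#' @param seed integer RNG seed.
#' @param n_chroms,chrom_length main chromosomes and their length (bp).
#' @param decoy_length length of the chr2a/chr2b decoy chromosomes (bp).
#' @param n_genes,n_peaks feature counts.
#' @param frac_differential fraction of peaks with planted accessibility
#'   differences.
#' @param true_logFC planted log2 fold change (HD/WT) magnitude.
#' @param scale_factor multiplicative library-depth bias of the HD
#'   condition that the MA normalization must remove.
#' @param nb_dispersion gamma dispersion of per-peak intensities.
#' @param mean_count mean pooled fragment count per peak per condition.
#' @param n_motifs,motif_lengths motif count and admissible widths.
#' @param planted_motif_rate,background_motif_rate planting rate of the
#'   designated motif in HD-up peaks vs all other peaks.
#' @param n_stages,n_replicates study design.
#' @param de_fraction,de_effect,fpkm_log_sd expression truth: DE gene
#'   fraction, log2 effect size, replicate log2-FPKM noise SD.
#' @param frac_promoter_diff,promoter_occ_fold,promoter_mean_count
#'   promoter nucleosome-occupancy truth.
#' @param bg_fragment_rate off-peak background fragments relative to
#'   in-peak fragments.
#' @param n_enhancers enhancer regions to emit.
#' @return named list of settings.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L, chrom_length = 1e6,
                             decoy_length = 2e5,
                             n_genes = 200L, n_peaks = 1000L,
                             frac_differential = 0.1, true_logFC = 4,
                             scale_factor = 1.5, nb_dispersion = 0.05,
                             mean_count = 100,
                             n_motifs = 20L, motif_lengths = 8:12,
                             planted_motif_rate = 0.8,
                             background_motif_rate = 0.1,
                             n_stages = 4L, n_replicates = 2L,
                             de_fraction = 0.3, de_effect = 3,
                             fpkm_log_sd = 0.25,
                             frac_promoter_diff = 0.05,
                             promoter_occ_fold = 3,
                             promoter_mean_count = 60,
                             bg_fragment_rate = 0.2,
                             n_enhancers = 100L) {
  cfg <- as.list(environment())
  stopifnot(cfg$frac_differential >= 0, cfg$frac_differential <= 1,
            cfg$planted_motif_rate >= 0, cfg$planted_motif_rate <= 1,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$chrom_length > 0, cfg$decoy_length > 0)
  cfg$stages <- c("PSC", "NPC", "Day3", "Astrocyte")[seq_len(cfg$n_stages)]
  if (cfg$n_stages > 4L)
    cfg$stages <- c(cfg$stages, paste0("Stage", 5:cfg$n_stages))
  cfg
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a random genome with gene annotation
#'
#' Uniform-base chromosomes `chr1..chrN` plus decoy chromosomes `chr2a`
#' and `chr2b` (gene-free) that exercise the exclusion rule. Genes are
#' placed in disjoint slots so bodies never overlap, with random strand.
#' Draws from the current RNG state; seed via [generate_synthetic_dataset()]
#' or `set.seed()`.
#'
#' @param cfg configuration from [synthetic_config()].
#' @return list: `genome` (named character vector), `chrom_lengths`,
#'   `genes` (gene-model data.frame).
#' @export
make_genome <- function(cfg) {
  chroms <- c(setNames(rep(cfg$chrom_length, cfg$n_chroms),
                       paste0("chr", seq_len(cfg$n_chroms))),
              chr2a = cfg$decoy_length, chr2b = cfg$decoy_length)
  genome <- vapply(chroms, random_dna, character(1))
  if (cfg$n_genes == 0L) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer(), tss = integer(), tes = integer())
    return(list(genome = genome, chrom_lengths = chroms, genes = genes))
  }
  main <- paste0("chr", seq_len(cfg$n_chroms))
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out =
                                cfg$n_chroms + 1L)))
  rows <- list()
  gid <- 0L
  for (ci in seq_along(main)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    slot <- floor(cfg$chrom_length / n)
    if (slot < 2500L)
      stop("cannot place ", n, " genes without overlap; ",
           "use a longer chromosome")
    for (k in seq_len(n)) {
      gid <- gid + 1L
      len <- sample(2000:min(8000L, slot - 400L), 1L)
      start <- (k - 1L) * slot + sample.int(slot - len - 200L, 1L)
      strand <- sample(c("+", "-"), 1L)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid), chrom = main[ci],
        strand = strand, start = start, end = start + len,
        tss = if (strand == "+") start else start + len - 1L,
        tes = if (strand == "+") start + len - 1L else start)
    }
  }
  list(genome = genome, chrom_lengths = chroms,
       genes = do.call(rbind, rows))
}

#' Place peaks and assign differential truth
#'
#' Peaks are laid out in disjoint slots on every chromosome (decoys
#' included) proportionally to length, each with a summit near its
#' center and a shared gamma-distributed intensity. `frac_differential`
#' of the peaks receive a planted log2 fold change of `true_logFC`
#' magnitude with random direction, constant across stages; planted
#' peaks on decoy chromosomes are marked `excluded` in the truth.
#'
#' @param cfg configuration.
#' @param chrom_lengths named chromosome lengths.
#' @return peak data.frame: `peak_id`, `chrom`, `start`, `end`, `summit`,
#'   `intensity`, `is_differential`, `direction`, `excluded`.
#' @export
make_peaks <- function(cfg, chrom_lengths) {
  alloc <- round(cfg$n_peaks * chrom_lengths / sum(chrom_lengths))
  rows <- list()
  pid <- 0L
  for (chr in names(chrom_lengths)) {
    n <- alloc[[chr]]
    if (n == 0L) next
    slot <- floor(chrom_lengths[[chr]] / n)
    if (slot < 900L) stop("too many peaks for chromosome ", chr)
    for (k in seq_len(n)) {
      pid <- pid + 1L
      width <- sample(400:700, 1L)
      start <- (k - 1L) * slot + sample.int(slot - width - 1L, 1L)
      summit <- start + width %/% 2L + sample(-50:50, 1L)
      rows[[pid]] <- data.frame(
        peak_id = sprintf("p%05d", pid), chrom = chr,
        start = start, end = start + width, summit = summit)
    }
  }
  peaks <- do.call(rbind, rows)
  n <- nrow(peaks)
  peaks$intensity <- cfg$mean_count *
    rgamma(n, shape = 1 / cfg$nb_dispersion, rate = 1 / cfg$nb_dispersion)
  diff_idx <- sample.int(n, round(cfg$frac_differential * n))
  peaks$is_differential <- seq_len(n) %in% diff_idx
  peaks$direction <- ifelse(peaks$is_differential,
                            sample(c("HD_up", "HD_down"), n, replace = TRUE),
                            "none")
  peaks$excluded <- peaks$chrom %in% c("chr2a", "chr2b")
  peaks
}

#' Generate random informative PWMs
#'
#' Each motif has a random consensus word with per-position probability
#' 0.85 on the consensus base and 0.05 elsewhere (about 1.15 bits of
#' information per position) over a uniform background.
#'
#' @param cfg configuration.
#' @return named list of PWMs (see [read_meme()]).
#' @export
make_pwms <- function(cfg) {
  bg <- setNames(rep(0.25, 4), DNA_BASES)
  pwms <- lapply(seq_len(cfg$n_motifs), function(i) {
    L <- if (length(cfg$motif_lengths) == 1L) cfg$motif_lengths else
      sample(cfg$motif_lengths, 1L)
    cons <- sample.int(4L, L, replace = TRUE)
    probs <- matrix(0.05, L, 4, dimnames = list(NULL, DNA_BASES))
    probs[cbind(seq_len(L), cons)] <- 0.85
    list(motif_id = sprintf("motif_%02d", i), probs = probs,
         background = bg)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
  pwms
}

pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write motif consensus sequences into peak summit windows
#'
#' The designated (first) motif's consensus is inserted at a random
#' offset and strand inside the 200-bp summit window of
#' `planted_motif_rate` of the HD-up-truth peaks and
#' `background_motif_rate` of every other peak; independently, each peak
#' receives one random non-designated motif at the background rate, so
#' the contingency's "other motifs" cells are populated. Planted
#' positions are recorded.
#'
#' @param cfg configuration.
#' @param genome named character vector of chromosome sequences.
#' @param peaks peak table from [make_peaks()].
#' @param pwms PWMs from [make_pwms()].
#' @param half_width summit window half-width (default 200 bp).
#' @return list: `genome` (modified), `planted` (data.frame `peak_id`,
#'   `motif_id`, `position` absolute 0-based, `strand`).
#' @export
plant_motifs <- function(cfg, genome, peaks, pwms, half_width = 200L) {
  target <- pwms[[1]]$motif_id
  planted <- list()
  insert <- function(genome, chrom, summit, word) {
    L <- nchar(word)
    chrom_len <- nchar(genome[[chrom]])
    lo <- max(0L, summit - half_width)
    hi <- min(chrom_len, summit + half_width) - L
    if (hi <= lo) return(NULL)   # window shorter than motif: skip
    pos <- lo + sample.int(hi - lo, 1L)
    substr(genome[[chrom]], pos + 1L, pos + L) <- word
    list(genome = genome, pos = pos)
  }
  for (i in seq_len(nrow(peaks))) {
    is_target_peak <- peaks$direction[i] == "HD_up"
    rate <- if (is_target_peak) cfg$planted_motif_rate else
      cfg$background_motif_rate
    if (runif(1) < rate) {
      strand <- sample(c("+", "-"), 1L)
      cons <- pwm_consensus(pwms[[target]])
      word <- if (strand == "+") cons else revcomp_chr(cons)
      ins <- insert(genome, peaks$chrom[i], peaks$summit[i], word)
      if (!is.null(ins)) {
        genome <- ins$genome
        planted[[length(planted) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], motif_id = target,
          position = ins$pos, strand = strand)
      }
    }
    if (length(pwms) > 1L && runif(1) < cfg$background_motif_rate) {
      other <- sample(names(pwms)[-1L], 1L)
      strand <- sample(c("+", "-"), 1L)
      cons <- pwm_consensus(pwms[[other]])
      word <- if (strand == "+") cons else revcomp_chr(cons)
      ins <- insert(genome, peaks$chrom[i], peaks$summit[i], word)
      if (!is.null(ins)) {
        genome <- ins$genome
        planted[[length(planted) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], motif_id = other,
          position = ins$pos, strand = strand)
      }
    }
  }
  list(genome = genome,
       planted = if (length(planted)) do.call(rbind, planted) else
         data.frame(peak_id = character(), motif_id = character(),
                    position = integer(), strand = character()))
}

## Raw fragment lengths are drawn so that after the +4/-5 Tn5 offset
## (length - 9) sub-nucleosomal fragments fall below 125 bp and
## mononucleosome fragments inside 171-254 bp.
sample_fragments_around <- function(n, chrom, center, lengths, sd_pos,
                                    chrom_len) {
  if (n == 0L) return(NULL)
  len <- sample(lengths, n, replace = TRUE)
  start <- round(rnorm(n, center - len / 2, sd_pos))
  start <- pmax(0L, pmin(as.integer(start), chrom_len - len))
  data.frame(chrom = chrom, start = start, end = start + len)
}

#' Simulate one sample's fragment set
#'
#' Per-peak expected counts are the shared peak intensity, divided by the
#' replicate count, multiplied by the condition's library scale factor
#' and, for differential-truth peaks, by `2^(+/- true_logFC / 2)`
#' (halved in log space for each condition so the HD/WT contrast equals
#' `true_logFC`). Counts are Poisson; fragments are sub-nucleosomal and
#' scatter around the summit. Promoter mononucleosome fragments and
#' uniform background fragments are added on top.
#'
#' @param cfg configuration.
#' @param peaks peak table with truth columns.
#' @param genes gene models (for promoter fragments).
#' @param chrom_lengths named lengths.
#' @param condition `"HD"` or `"WT"`.
#' @param promoter_truth data.frame `gene_id`, `occupancy`, `is_diff`
#'   from the caller (shared across samples).
#' @return fragment data.frame `chrom`, `start`, `end`.
#' @export
simulate_sample_fragments <- function(cfg, peaks, genes, chrom_lengths,
                                      condition, promoter_truth = NULL) {
  sf <- if (condition == "HD") cfg$scale_factor else 1
  fold <- rep(1, nrow(peaks))
  up <- peaks$direction == "HD_up"
  dn <- peaks$direction == "HD_down"
  half <- cfg$true_logFC / 2
  if (condition == "HD") {
    fold[up] <- 2^half; fold[dn] <- 2^(-half)
  } else {
    fold[up] <- 2^(-half); fold[dn] <- 2^half
  }
  mu <- peaks$intensity / cfg$n_replicates * sf * fold
  counts <- rpois(nrow(peaks), mu)
  frag <- lapply(which(counts > 0L), function(i)
    sample_fragments_around(counts[i], peaks$chrom[i], peaks$summit[i],
                            50:133, 50, chrom_lengths[[peaks$chrom[i]]]))
  ## promoter mononucleosome fragments
  if (!is.null(promoter_truth) && nrow(genes) > 0L) {
    occ <- promoter_truth$occupancy / cfg$n_replicates * sf
    if (condition == "HD")
      occ <- occ * ifelse(promoter_truth$is_diff, cfg$promoter_occ_fold, 1)
    pc <- rpois(nrow(genes), occ)
    frag <- c(frag, lapply(which(pc > 0L), function(g)
      sample_fragments_around(pc[g], genes$chrom[g], genes$tss[g],
                              180:263, 300,
                              chrom_lengths[[genes$chrom[g]]])))
  }
  ## uniform background (sub-nucleosomal)
  n_bg <- rpois(1, cfg$bg_fragment_rate * sum(mu))
  if (n_bg > 0L) {
    chr <- sample(names(chrom_lengths), n_bg, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
    len <- sample(50:133, n_bg, replace = TRUE)
    start <- vapply(seq_len(n_bg), function(i)
      sample.int(chrom_lengths[[chr[i]]] - len[i], 1L), integer(1))
    frag <- c(frag, list(data.frame(chrom = chr, start = start,
                                    end = start + len)))
  }
  out <- do.call(rbind, frag)
  rownames(out) <- NULL
  out
}

#' Simulate a stage-patterned differential expression table
#'
#' Baseline log2 FPKM is normal per gene; DE-truth genes get a log2
#' shift of `de_effect` following one of four stage patterns (all
#' stages, early-only, late-only, or an inverse pattern that flips sign
#' between the NPC and astrocyte ends), with random overall sign.
#' Replicate FPKMs add lognormal noise; per stage, the two conditions
#' are compared on log2 replicate FPKMs with a common-dispersion z-test
#' (the per-gene variance is pooled across all genes, emulating
#' transcriptome-wide dispersion modelling of DE callers), BH-adjusted
#' across genes to q.
#'
#' @param cfg configuration.
#' @param genes gene models.
#' @return list: `table` (cuffdiff-style data.frame), `truth`
#'   (data.frame `gene_id`, `is_de_any`, per-stage `de_<stage>`
#'   indicators), `replicates` (log2 FPKM array).
#' @export
simulate_expression <- function(cfg, genes) {
  n <- nrow(genes)
  stages <- cfg$stages
  ns <- length(stages)
  base <- rnorm(n, 3, 1.5)
  patterns <- list(all = rep(1, ns),
                   early = as.numeric(seq_len(ns) <= ceiling(ns / 2)),
                   late = as.numeric(seq_len(ns) > ceiling(ns / 2)),
                   inverse = if (ns >= 3)
                     c(0, 1, rep(-1, ns - 2)) else rep(1, ns))
  de <- sample.int(n, round(cfg$de_fraction * n))
  shift <- matrix(0, n, ns, dimnames = list(genes$gene_id, stages))
  for (g in de) {
    pat <- patterns[[sample.int(length(patterns), 1L)]]
    shift[g, ] <- sample(c(-1, 1), 1L) * cfg$de_effect * pat
  }
  rows <- list()
  for (s in seq_len(ns)) {
    wt <- matrix(rnorm(n * cfg$n_replicates, base, cfg$fpkm_log_sd),
                 n, cfg$n_replicates)
    hd <- matrix(rnorm(n * cfg$n_replicates, base + shift[, s],
                       cfg$fpkm_log_sd), n, cfg$n_replicates)
    if (cfg$n_replicates >= 2L) {
      ## common dispersion pooled over genes and both conditions
      s2 <- mean(c(apply(wt, 1, stats::var), apply(hd, 1, stats::var)))
      se <- sqrt(2 * s2 / cfg$n_replicates)
      z <- (rowMeans(hd) - rowMeans(wt)) / se
      p <- 2 * stats::pnorm(-abs(z))
    } else {
      p <- rep(NA_real_, n)
    }
    q <- bh_adjust(p)
    rows[[s]] <- data.frame(
      gene_id = genes$gene_id,
      sample_1 = paste0("WT_", stages[s]),
      sample_2 = paste0("HD_", stages[s]),
      value_1 = rowMeans(2^wt), value_2 = rowMeans(2^hd),
      p_value = p, q_value = q)
  }
  truth <- data.frame(gene_id = genes$gene_id,
                      is_de_any = rowSums(shift != 0) > 0)
  for (s in seq_len(ns))
    truth[[paste0("de_", stages[s])]] <- shift[, s] != 0
  list(table = do.call(rbind, rows), truth = truth)
}

#' Generate the full synthetic dataset
#'
#' Seeds the RNG once from `cfg$seed` and builds, in a fixed order, the
#' genome and annotation, peaks with differential truth, PWMs with
#' planted motif occurrences, per-stage/condition/replicate fragment
#' sets, the expression table with DE truth, gene sets (the planted DE
#' set plus random decoy sets), and enhancer regions anchored on a
#' subset of distal peaks. All outputs are deterministic given the seed.
#'
#' @param cfg configuration from [synthetic_config()].
#' @return a `synthetic_dataset` list; see fields in the source.
#' @export
generate_synthetic_dataset <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  g <- make_genome(cfg)
  peaks <- make_peaks(cfg, g$chrom_lengths)
  pwms <- make_pwms(cfg)
  pm <- plant_motifs(cfg, g$genome, peaks, pwms)
  genome <- pm$genome
  promoter_truth <- if (nrow(g$genes) > 0L) data.frame(
    gene_id = g$genes$gene_id,
    occupancy = cfg$promoter_mean_count *
      rgamma(nrow(g$genes), 1 / cfg$nb_dispersion, 1 / cfg$nb_dispersion),
    is_diff = runif(nrow(g$genes)) < cfg$frac_promoter_diff) else NULL
  fragments <- list()
  for (stage in cfg$stages) {
    fragments[[stage]] <- list()
    for (cond in c("HD", "WT")) {
      fragments[[stage]][[cond]] <- lapply(seq_len(cfg$n_replicates),
        function(r) simulate_sample_fragments(
          cfg, peaks, g$genes, g$chrom_lengths, cond, promoter_truth))
    }
  }
  expr <- simulate_expression(cfg, g$genes)
  gene_sets <- list(planted_de =
                      expr$truth$gene_id[expr$truth$is_de_any])
  for (k in 1:3) {
    gene_sets[[paste0("random_set_", k)]] <-
      sample(g$genes$gene_id, min(20L, nrow(g$genes)))
  }
  ## enhancers: extend a subset of distal non-promoter peaks, plus decoys
  prox <- classify_tss_proximity(peaks, g$genes)
  distal_idx <- which(prox == "distal" & !peaks$excluded)
  anchor <- sample(distal_idx, min(cfg$n_enhancers %/% 2,
                                   length(distal_idx)))
  enh1 <- data.frame(chrom = peaks$chrom[anchor],
                     start = pmax(0L, peaks$start[anchor] -
                                    sample(0:200, length(anchor), TRUE)),
                     end = peaks$end[anchor] +
                       sample(0:200, length(anchor), TRUE))
  n2 <- cfg$n_enhancers - nrow(enh1)
  chr <- sample(paste0("chr", seq_len(cfg$n_chroms)), n2, replace = TRUE)
  st <- vapply(chr, function(c2)
    sample.int(g$chrom_lengths[[c2]] - 2000L, 1L), integer(1))
  enh2 <- data.frame(chrom = chr, start = st,
                     end = st + sample(500:2000, n2, replace = TRUE))
  enhancers <- merge_intervals(rbind(enh1, enh2))
  structure(list(
    config = cfg, genome = genome, chrom_lengths = g$chrom_lengths,
    genes = g$genes, peaks = peaks, pwms = pwms, fragments = fragments,
    expression = expr$table, gene_sets = gene_sets, enhancers = enhancers,
    truth = list(peaks = peaks[c("peak_id", "chrom", "is_differential",
                                 "direction", "excluded")],
                 motifs = pm$planted, genes = expr$truth,
                 promoters = promoter_truth)
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' FASTA genome, GTF-subset annotation, per-sample fragment and peak
#' BEDs, MEME minimal motifs, cuffdiff-style expression TSV, GMT gene
#' sets, enhancer BED, and truth TSVs, all plain text.
#'
#' @param ds dataset from [generate_synthetic_dataset()].
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$genome),
                              pth("genome.fa"))
  write_gtf_genes(ds$genes, pth("genes.gtf"))
  write_meme(ds$pwms, pth("motifs.meme"))
  for (stage in names(ds$fragments)) {
    for (cond in names(ds$fragments[[stage]])) {
      reps <- ds$fragments[[stage]][[cond]]
      for (r in seq_along(reps)) {
        write_bed(reps[[r]],
                  pth(sprintf("fragments_%s_%s_rep%d.bed", stage, cond, r)))
        pk <- data.frame(chrom = ds$peaks$chrom, start = ds$peaks$start,
                         end = ds$peaks$end, name = ds$peaks$peak_id,
                         summit = ds$peaks$summit)
        write_bed(pk,
                  pth(sprintf("peaks_%s_%s_rep%d.bed", stage, cond, r)))
      }
    }
  }
  write.table(ds$expression, pth("expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(ds$gene_sets, pth("gene_sets.gmt"))
  write_bed(ds$enhancers, pth("enhancers.bed"))
  write.table(ds$truth$peaks, pth("truth_peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$truth$motifs, pth("truth_motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$truth$genes, pth("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(ds$truth$promoters))
    write.table(ds$truth$promoters, pth("truth_promoters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Load a dataset directory written by [write_synthetic_dataset()]
#'
#' Reads the plain-text formats back through the package's readers
#' (FASTA, GTF subset, BED with summit column, MEME minimal, GMT,
#' cuffdiff-style TSV) into the structure [run_pipeline()] consumes.
#' Stages, conditions and replicates are inferred from the fragment file
#' names.
#'
#' @param dir dataset directory.
#' @return a `synthetic_dataset`-shaped list (without `config`).
#' @export
load_synthetic_dataset <- function(dir) {
  pth <- function(...) file.path(dir, ...)
  genome_ss <- Biostrings::readDNAStringSet(pth("genome.fa"))
  genome <- setNames(as.character(genome_ss), names(genome_ss))
  genes <- read_gtf_genes(pth("genes.gtf"))
  frag_files <- list.files(dir, "^fragments_.*\\.bed$")
  parts <- regmatches(frag_files,
                      regexec("^fragments_(.+)_(HD|WT)_rep(\\d+)\\.bed$",
                              frag_files))
  fragments <- list()
  peaks <- NULL
  for (i in seq_along(frag_files)) {
    stage <- parts[[i]][2]; cond <- parts[[i]][3]
    r <- as.integer(parts[[i]][4])
    fragments[[stage]][[cond]][[r]] <- read_bed(pth(frag_files[i]))
    if (is.null(peaks)) {
      pk <- read_bed(pth(sub("^fragments", "peaks", frag_files[i])))
      peaks <- data.frame(peak_id = pk$name, chrom = pk$chrom,
                          start = pk$start, end = pk$end,
                          summit = pk$summit)
    }
  }
  ## restore the canonical stage order if recognizable
  known <- c("PSC", "NPC", "Day3", "Astrocyte")
  ord <- c(intersect(known, names(fragments)),
           setdiff(names(fragments), known))
  fragments <- fragments[ord]
  expr <- read.table(pth("expression.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  structure(list(
    genome = genome,
    chrom_lengths = setNames(Biostrings::width(genome_ss),
                             names(genome_ss)),
    genes = genes, peaks = peaks, pwms = read_meme(pth("motifs.meme")),
    fragments = fragments, expression = expr,
    gene_sets = read_gmt(pth("gene_sets.gmt")),
    enhancers = read_bed(pth("enhancers.bed")),
    truth = list(
      peaks = read.table(pth("truth_peaks.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE),
      motifs = read.table(pth("truth_motifs.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE),
      genes = read.table(pth("truth_genes.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE))
  ), class = "synthetic_dataset")
}
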