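## Expression-side computations and ATAC/RNA joins: floored log2 FPKM
## ratio matrices, gene-set overlap tests on the literal nested
## contingency, nearest-differential-peak association, and enhancer
## overlap accounting.

#' Floored log2 FPKM ratio
#'
#' log2((fpkm_hd + 1e-4) / (fpkm_wt + 1e-4)), with the value forced to 0
#' whenever both FPKMs are below 1 — genes essentially unexpressed in
#' both conditions carry no usable ratio and would otherwise dominate the
#' color scale of a ratio heatmap. The 1e-4 pseudocount only guards
#' against division by zero.
#'
#' @param fpkm_hd,fpkm_wt non-negative FPKM values (vectorized).
#' @return log2 ratio(s).
#' @export
log2_ratio_fpkm <- function(fpkm_hd, fpkm_wt) {
  if (any(fpkm_hd < 0 | fpkm_wt < 0)) stop("FPKM must be non-negative")
  ifelse(fpkm_hd < 1 & fpkm_wt < 1, 0,
         log2((fpkm_hd + 1e-4) / (fpkm_wt + 1e-4)))
}

#' Genes x stages matrix of floored log2 FPKM ratios
#'
#' Replicate FPKMs are assumed already pooled (arithmetic mean) into one
#' value per gene, stage and condition. Missing (gene, stage) pairs are
#' imputed as (0, 0), i.e. ratio 0; duplicate pairs are an error.
#'
#' @param records data.frame with `gene_id`, `stage`, `fpkm_hd`,
#'   `fpkm_wt`.
#' @param gene_order character vector giving the row order.
#' @param stage_order optional column order (default: order of first
#'   appearance).
#' @return numeric matrix, rows = `gene_order`, columns = stages.
#' @export
build_logratio_matrix <- function(records, gene_order,
                                  stage_order = unique(records$stage)) {
  if (anyDuplicated(records[c("gene_id", "stage")]))
    stop("duplicate (gene, stage) rows")
  m <- matrix(0, length(gene_order), length(stage_order),
              dimnames = list(gene_order, stage_order))
  keep <- records$gene_id %in% gene_order & records$stage %in% stage_order
  r <- records[keep, , drop = FALSE]
  m[cbind(r$gene_id, r$stage)] <- log2_ratio_fpkm(r$fpkm_hd, r$fpkm_wt)
  m
}

#' Gene-set overlap test for differentially expressed genes
#'
#' Builds the literal 2x2 table N11 = DE genes in the set, N12 = set
#' genes not DE, N21 = DE genes in the whole annotated universe, N22 =
#' non-DE genes in the universe (rows nested by construction), tests it
#' with Fisher's exact test, and reports the DE fraction of the set as a
#' percentage.
#'
#' @param de_genes character vector of DE gene ids.
#' @param set_genes character vector of gene-set member ids (non-empty).
#' @param universe character vector of all annotated genes considered.
#' @return list: `N11`, `N12`, `N21`, `N22`, `overlap` (= N11),
#'   `fraction_pct`, `p`.
#' @export
geneset_overlap_test <- function(de_genes, set_genes, universe) {
  if (length(set_genes) == 0L) stop("empty gene set")
  set_genes <- unique(set_genes)
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  stopifnot(length(universe) >= length(set_genes),
            length(universe) >= length(de_genes))
  n11 <- length(intersect(de_genes, set_genes))
  n12 <- length(set_genes) - n11
  n21 <- length(intersect(de_genes, universe))
  n22 <- length(universe) - n21
  p <- suppressWarnings(fisher_exact(n11, n12, n21, n22))
  list(N11 = n11, N12 = n12, N21 = n21, N22 = n22, overlap = n11,
       fraction_pct = 100 * n11 / length(set_genes), p = p)
}

#' Nearest differential peak to each gene's promoter
#'
#' For each gene, finds the nearest differential peak on the same
#' chromosome (distance measured from peak edge to the strand-aware TSS
#' point, signed positive downstream of the TSS) and flags whether it
#' falls within `max_dist` bp. Genes with no same-chromosome differential
#' peak are omitted and counted in the `n_unassociated` attribute.
#'
#' @param genes gene-model data.frame (needs `gene_id`, `chrom`, `tss`).
#' @param diff_peaks differential peak data.frame (`chrom`, `start`,
#'   `end`, and optionally `direction`, `M`).
#' @param max_dist distance threshold for the flag (default 250000 bp).
#' @return data.frame: `gene_id`, peak `chrom`/`start`/`end`, `distance`,
#'   `within_250kb`, plus `direction`/`M` when present.
#' @export
nearest_diff_peak_per_gene <- function(genes, diff_peaks,
                                       max_dist = 250000L) {
  promoters <- data.frame(chrom = genes$chrom, start = genes$tss,
                          end = genes$tss + 1L)
  nf <- nearest_feature(promoters, diff_peaks)
  has <- !is.na(nf$target_idx)
  idx <- nf$target_idx[has]
  ## distance sign from the peak's point of view: positive when the peak
  ## lies downstream (to the right) of the promoter
  out <- data.frame(
    gene_id = genes$gene_id[has],
    chrom = diff_peaks$chrom[idx],
    start = diff_peaks$start[idx],
    end = diff_peaks$end[idx],
    distance = nf$distance[has],
    within_250kb = abs(nf$distance[has]) <= max_dist
  )
  for (col in c("direction", "M", "logFC")) {
    if (col %in% names(diff_peaks)) out[[col]] <- diff_peaks[[col]][idx]
  }
  attr(out, "n_unassociated") <- sum(!has)
  out
}

#' Overlap accounting between differential distal peaks and enhancers
#'
#' Counts in both directions — enhancers touched by at least one
#' differential distal peak, and differential distal peaks touching at
#' least one enhancer (the two differ when several peaks share one
#' enhancer) — and the intragenic fraction of the overlapped enhancers.
#'
#' @param diff_distal differential distal peak regions.
#' @param enhancers enhancer regions (non-empty).
#' @param genes gene models for the genic classification (optional).
#' @return list: `enhancers_hit`, `thss_hitting`,
#'   `intragenic_fraction` (of overlapped enhancers; NA if none or no
#'   genes given).
#' @export
enhancer_overlap_counts <- function(diff_distal, enhancers, genes = NULL) {
  stopifnot(nrow(enhancers) > 0L)
  if (nrow(diff_distal) == 0L) {
    return(list(enhancers_hit = 0L, thss_hitting = 0L,
                intragenic_fraction = NA_real_))
  }
  ov_e <- GenomicRanges::countOverlaps(as_granges(enhancers),
                                       as_granges(diff_distal)) > 0L
  ov_t <- GenomicRanges::countOverlaps(as_granges(diff_distal),
                                       as_granges(enhancers)) > 0L
  frac <- NA_real_
  if (!is.null(genes) && sum(ov_e) > 0L) {
    ctx <- classify_genic_context(enhancers[ov_e, , drop = FALSE], genes)
    frac <- mean(ctx == "intragenic")
  }
  list(enhancers_hit = sum(ov_e), thss_hitting = sum(ov_t),
       intragenic_fraction = frac)
}

#' Deterministic hierarchical row ordering of a matrix
#'
#' Agglomerative clustering with Euclidean distance and average linkage;
#' the returned leaf order is seed-free and reproducible.
#'
#' @param m finite numeric matrix.
#' @return integer row order.
#' @export
hierarchical_order <- function(m) {
  stopifnot(all(is.finite(m)))
  if (nrow(m) <= 1L) return(seq_len(nrow(m)))
  hclust(dist(m, method = "euclidean"), method = "average")$order
}
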