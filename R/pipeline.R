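## End-to-end orchestration over a dataset: fragment preprocessing,
## replicate QC, per-stage differential accessibility, promoter
## nucleosome occupancy, motif enrichment, and the expression-side
## integration, collected into a single report.

fragment_lengths <- function(frags) frags$end - frags$start

preprocess_fragments <- function(frags) {
  shifted <- shift_tn5(frags)
  cls <- classify_fragment_length(fragment_lengths(shifted))
  list(non_nucleosomal = shifted[cls == "non_nucleosomal", , drop = FALSE],
       mononucleosome = shifted[cls == "mononucleosome", , drop = FALSE],
       n_rejected = attr(shifted, "n_rejected"))
}

#' Run the full analysis over a dataset
#'
#' Executes, per stage: Tn5 offsetting and size-class filtering of each
#' replicate's fragments, replicate correlation QC, pooling, fragment
#' counting in the stage's peak set, MA normalization with the exact
#' binomial test and compound selection, TSS-proximity and genic
#' labelling, and promoter mononucleosome occupancy testing. Motif
#' scanning runs once over the summit windows (the peak set is shared
#' across stages) and the Fisher enrichment contingencies are built per
#' stage, direction and context. The expression side computes the
#' floored log2 ratio matrix over DE genes (hierarchically ordered),
#' gene-set overlap tests, nearest-differential-peak associations for DE
#' genes, and enhancer overlap accounting.
#'
#' @param ds dataset from [generate_synthetic_dataset()] (or assembled
#'   with the same fields).
#' @param criteria differential selection criteria
#'   ([selection_criteria()]).
#' @param de_q_cut q cutoff calling a gene DE (default 0.05).
#' @param motif_p_threshold PWM match p cutoff (default 1e-4).
#' @param proximity_radius TSS proximity radius in bp (default 500).
#' @param summit_half_width motif window half-width (default 200).
#' @param promoter_half_width occupancy window half-width (default 1000).
#' @param nearest_flag_dist distance flag for peak-gene association
#'   (default 250 kb).
#' @param motif_alpha significance flag for enrichment (default 0.05).
#' @return a `run_report` list: `differential` (per-stage tables),
#'   `summary`, `promoter_occupancy`, `motif_hits`, `motif_enrichment`,
#'   `expression` (matrix + DE calls), `geneset_tests`, `associations`,
#'   `enhancer_overlap`, `qc`, `parameters`.
#' @export
run_pipeline <- function(ds, criteria = selection_criteria(),
                         de_q_cut = 0.05, motif_p_threshold = 1e-4,
                         proximity_radius = 500L,
                         summit_half_width = 200L,
                         promoter_half_width = 1000L,
                         nearest_flag_dist = 250000L,
                         motif_alpha = 0.05) {
  stages <- names(ds$fragments)
  peaks <- ds$peaks
  proximity <- classify_tss_proximity(peaks, ds$genes,
                                      radius = proximity_radius)
  genic <- classify_genic_context(peaks, ds$genes)

  differential <- list()
  promoter_occ <- list()
  qc <- list(replicate_correlation = list(), rejected_fragments = list())

  for (stage in stages) {
    pooled <- list()
    mono <- list()
    for (cond in c("HD", "WT")) {
      reps <- lapply(ds$fragments[[stage]][[cond]], preprocess_fragments)
      qc$rejected_fragments[[paste(stage, cond, sep = "_")]] <-
        sum(vapply(reps, `[[`, numeric(1), "n_rejected"))
      if (length(reps) >= 2L) {
        rc <- replicate_correlation(
          count_fragments_in_peaks(reps[[1]]$non_nucleosomal, peaks)$counts,
          count_fragments_in_peaks(reps[[2]]$non_nucleosomal, peaks)$counts)
        qc$replicate_correlation[[paste(stage, cond, sep = "_")]] <- rc
      }
      pooled[[cond]] <- do.call(rbind, lapply(reps, `[[`,
                                              "non_nucleosomal"))
      mono[[cond]] <- do.call(rbind, lapply(reps, `[[`,
                                            "mononucleosome"))
    }
    d <- differential_accessibility(pooled$HD, pooled$WT, peaks,
                                    criteria = criteria)
    d$proximity <- proximity
    d$genic_context <- genic
    differential[[stage]] <- d
    promoter_occ[[stage]] <- diff_promoter_occupancy(
      mono$HD, mono$WT, ds$genes, half_width = promoter_half_width,
      criteria = criteria)
  }

  ## motif scanning: one pass over the shared summit windows
  seqs <- summit_window_sequences(ds$genome, peaks,
                                  half_width = summit_half_width)
  hits <- scan_peak_windows(seqs, ds$pwms,
                            p_threshold = motif_p_threshold)
  dedup <- best_hit_per_peak(hits)
  enrichment <- do.call(rbind, lapply(stages, function(stage) {
    d <- differential[[stage]]
    info <- data.frame(peak_id = d$peak_id, direction = d$direction,
                       proximity = d$proximity)
    e <- enrichment_scan(dedup, info, motif_ids = names(ds$pwms),
                         alpha = motif_alpha)
    cbind(stage = stage, e)
  }))

  ## expression side
  expr <- data.frame(gene_id = ds$expression$gene_id,
                     stage = sub("^HD_", "", ds$expression$sample_2),
                     fpkm_wt = ds$expression$value_1,
                     fpkm_hd = ds$expression$value_2,
                     p = ds$expression$p_value,
                     q = ds$expression$q_value)
  expr$is_de <- expr$q < de_q_cut
  de_any <- sort(unique(expr$gene_id[expr$is_de]))
  lr <- build_logratio_matrix(expr, gene_order = de_any,
                              stage_order = stages)
  if (nrow(lr) > 1L) lr <- lr[hierarchical_order(lr), , drop = FALSE]

  geneset_tests <- lapply(names(ds$gene_sets), function(id) {
    t <- geneset_overlap_test(de_any, ds$gene_sets[[id]],
                              ds$genes$gene_id)
    c(list(set_id = id), t)
  })
  geneset_tests <- do.call(rbind, lapply(geneset_tests, as.data.frame))

  associations <- do.call(rbind, lapply(stages, function(stage) {
    d <- differential[[stage]]
    dp <- d[d$selected, , drop = FALSE]
    de_genes <- ds$genes[ds$genes$gene_id %in%
                           expr$gene_id[expr$is_de & expr$stage == stage],
                         , drop = FALSE]
    if (nrow(dp) == 0L || nrow(de_genes) == 0L) return(NULL)
    a <- nearest_diff_peak_per_gene(de_genes, dp,
                                    max_dist = nearest_flag_dist)
    if (nrow(a) == 0L) return(NULL)
    cbind(stage = stage, a)
  }))

  enhancer_overlap <- lapply(stages, function(stage) {
    d <- differential[[stage]]
    dd <- d[d$selected & d$proximity == "distal", , drop = FALSE]
    enhancer_overlap_counts(dd, ds$enhancers, ds$genes)
  })
  names(enhancer_overlap) <- stages

  structure(list(
    differential = differential,
    summary = summarize_differential(differential),
    promoter_occupancy = promoter_occ,
    motif_hits = dedup,
    motif_enrichment = enrichment,
    expression = list(records = expr, logratio = lr, de_genes = de_any),
    geneset_tests = geneset_tests,
    associations = associations,
    enhancer_overlap = enhancer_overlap,
    qc = qc,
    parameters = list(criteria = criteria, de_q_cut = de_q_cut,
                      motif_p_threshold = motif_p_threshold,
                      proximity_radius = proximity_radius,
                      summit_half_width = summit_half_width,
                      promoter_half_width = promoter_half_width,
                      nearest_flag_dist = nearest_flag_dist)
  ), class = "run_report")
}

#' Render a count with its percentage share
#'
#' `count(percent)` cell style with one decimal; `"NA"` when the
#' percentage is undefined (zero denominator).
#'
#' @param n integer count(s).
#' @param pct percentage(s), already rounded half-up to one decimal.
#' @return character vector of cells like `"6342(89.8%)"`.
#' @export
format_count_pct <- function(n, pct) {
  ifelse(is.na(pct), "NA", sprintf("%d(%.1f%%)", n, pct))
}

#' Write a report's tables to TSV files
#'
#' One file per section. Summary percentage cells are rendered in the
#' `count(percent)` style with one decimal (half-up), `NA` for empty
#' denominators.
#'
#' @param report result of [run_pipeline()].
#' @param out_dir output directory (created).
#' @return invisible character vector of written paths.
#' @export
render_summary <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  st <- report$summary$per_stage
  disp <- data.frame(stage = st$stage,
                     n_proximal = st$n_proximal, n_distal = st$n_distal,
                     n_differential = st$n_diff,
                     enriched = format_count_pct(st$n_up, st$pct_up),
                     depleted = format_count_pct(st$n_down, st$pct_down))
  wr(disp, "summary_differential.tsv")
  for (stage in names(report$differential)) {
    d <- report$differential[[stage]]
    wr(d[d$selected, , drop = FALSE],
       sprintf("differential_%s.tsv", stage))
  }
  wr(report$motif_enrichment, "motif_enrichment.tsv")
  ## bubble-style matrix: motif x stage, -log10 p of the best context per
  ## direction
  me <- report$motif_enrichment
  if (nrow(me) > 0L) {
    key <- paste(me$stage, me$direction, sep = ":")
    mat <- tapply(-log10(pmax(me$p, 1e-300)),
                  list(me$motif_id, key), max)
    wr(data.frame(motif_id = rownames(mat), mat, check.names = FALSE),
       "motif_matrix.tsv")
  }
  lr <- report$expression$logratio
  wr(data.frame(gene_id = rownames(lr), lr, check.names = FALSE),
     "logratio_matrix.tsv")
  wr(report$geneset_tests, "geneset_overlap.tsv")
  if (!is.null(report$associations))
    wr(report$associations, "nearest_peak_associations.tsv")
  eo <- do.call(rbind, lapply(names(report$enhancer_overlap), function(s)
    data.frame(stage = s,
               enhancers_hit = report$enhancer_overlap[[s]]$enhancers_hit,
               thss_hitting = report$enhancer_overlap[[s]]$thss_hitting,
               intragenic_fraction =
                 report$enhancer_overlap[[s]]$intragenic_fraction)))
  wr(eo, "enhancer_overlap.tsv")
  qc <- data.frame(
    sample = names(report$qc$replicate_correlation),
    replicate_correlation =
      unlist(report$qc$replicate_correlation, use.names = FALSE),
    rejected_fragments =
      unlist(report$qc$rejected_fragments, use.names = FALSE))
  wr(qc, "qc.tsv")
  invisible(paths)
}
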