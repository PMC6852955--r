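## Differential accessibility between two pooled samples (e.g. HD vs WT at
## one stage): fragment counting in peaks, MA normalization on common
## peaks, per-peak exact binomial test, BH adjustment, and the compound
## selection criteria.

#' Count fragments overlapping each peak
#'
#' A fragment is counted for every peak it overlaps by >= 1 bp, so a
#' fragment spanning two peaks increments both. The library size is the
#' total number of fragments supplied (not the column sum over peaks).
#'
#' @param fragments fragment data.frame (`chrom`, `start`, `end`).
#' @param peaks peak region data.frame.
#' @return list with `counts` (integer per peak) and `library_size`.
#' @export
count_fragments_in_peaks <- function(fragments, peaks) {
  if (nrow(fragments) == 0L || nrow(peaks) == 0L) {
    return(list(counts = rep(0L, nrow(peaks)),
                library_size = nrow(fragments)))
  }
  counts <- GenomicRanges::countOverlaps(as_granges(peaks),
                                         as_granges(fragments))
  list(counts = as.integer(counts), library_size = nrow(fragments))
}

#' Identify peaks common to two samples
#'
#' A merged peak is "common" when it overlaps (>= 1 bp) a called peak from
#' each sample, or when the nearest per-sample summits lie within
#' `summit_dist` bp of each other. Common peaks anchor the MA
#' normalization, on the assumption that regions open in both samples are
#' mostly unchanged.
#'
#' @param merged merged peak data.frame (optionally with `summit`).
#' @param peaks1,peaks2 per-sample peak calls (optionally with `summit`).
#' @param summit_dist summit distance tolerance in bp (default 250).
#' @return logical vector over `merged` rows.
#' @export
common_peaks <- function(merged, peaks1, peaks2, summit_dist = 250L) {
  ov1 <- GenomicRanges::countOverlaps(as_granges(merged),
                                      as_granges(peaks1)) > 0L
  ov2 <- GenomicRanges::countOverlaps(as_granges(merged),
                                      as_granges(peaks2)) > 0L
  common <- ov1 & ov2
  if (all(c("summit" %in% names(peaks1), "summit" %in% names(peaks2),
            "summit" %in% names(merged)))) {
    pt <- function(p) data.frame(chrom = p$chrom, start = p$summit,
                                 end = p$summit + 1L)
    n1 <- nearest_feature(pt(merged), pt(peaks1))
    n2 <- nearest_feature(pt(merged), pt(peaks2))
    near <- !is.na(n1$distance) & !is.na(n2$distance) &
      abs(n1$distance) <= summit_dist & abs(n2$distance) <= summit_dist
    common <- common | near
  }
  common
}

ma_values <- function(x1, x2, pseudo = 0.5) {
  list(M = log2((x1 + pseudo) / (x2 + pseudo)),
       A = 0.5 * log2((x1 + pseudo) * (x2 + pseudo)))
}

#' Fit the MA normalization line on common peaks
#'
#' Robust (Huber IRLS) linear fit of M = log2((x1+0.5)/(x2+0.5)) on
#' A = 0.5 log2((x1+0.5)(x2+0.5)) over the common peaks. The fitted line
#' captures the between-sample scaling (intercept ~ -log2 of the library
#' scale factor) and any intensity-dependent trend (slope).
#'
#' @param x1,x2 per-peak fragment counts for the two samples.
#' @param common logical mask of common peaks.
#' @return list: `intercept`, `slope`, `n_common`.
#' @export
fit_ma_normalization <- function(x1, x2, common = NULL) {
  if (is.null(common)) common <- rep(TRUE, length(x1))
  use <- common & x1 > 0 & x2 > 0
  if (sum(use) < 2L) stop("need >= 2 common peaks with positive counts")
  v <- ma_values(x1[use], x2[use])
  if (stats::sd(v$A) < .Machine$double.eps^0.5) {
    ## degenerate design: fall back to a pure offset
    co <- c(stats::median(v$M), 0)
  } else {
    ## the iteration cap is part of the procedure; hitting it is not an
    ## error, the capped fit is used as-is
    fit <- withCallingHandlers(
      MASS::rlm(v$M ~ v$A, maxit = 20, acc = 1e-8),
      warning = function(w) {
        if (grepl("failed to converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    co <- unname(stats::coef(fit))
  }
  if (any(!is.finite(co))) stop("MA fit did not converge to finite values")
  list(intercept = co[1], slope = co[2], n_common = sum(use))
}

#' Rescale sample-2 counts by the fitted MA line
#'
#' Removes the fitted M-on-A trend: x2' = x2 * 2^(intercept + slope * A),
#' with A computed from the raw counts. Post-normalization M over common
#' peaks then has zero trend. Output counts are non-negative reals.
#'
#' @param x1,x2 raw per-peak counts.
#' @param fit result of [fit_ma_normalization()].
#' @return numeric vector of normalized sample-2 counts.
#' @export
apply_normalization <- function(x1, x2, fit) {
  A <- ma_values(x1, x2)$A
  x2 * 2^(fit$intercept + fit$slope * A)
}

#' Exact binomial two-sided p-value for a normalized count pair
#'
#' Tests whether the (rounded, round-half-even) normalized counts split
#' the pooled total symmetrically: round(x1) successes in
#' round(x1)+round(x2) trials at probability 0.5, two-sided by summing the
#' binomial pmf over all outcomes no more probable than the observed one.
#' Both counts zero gives p = 1 by convention.
#'
#' @param x1,x2 non-negative (possibly non-integer) counts; vectorized.
#' @return numeric p-values in [0, 1].
#' @export
diff_pvalue <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  if (any(x1 < 0 | x2 < 0)) stop("counts must be non-negative")
  k <- round(x1)   # round() is round-half-even
  n <- k + round(x2)
  vapply(seq_along(k), function(i) {
    if (n[i] == 0) return(1)
    d <- dbinom(0:n[i], n[i], 0.5)
    ## relative tolerance as in stats::binom.test
    min(1, sum(d[d <= d[k[i] + 1L] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted q-values
#' @param p numeric p-values in [0, 1].
#' @return q-values (BH step-up with monotonicity enforcement).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Default compound selection criteria for differential peaks
#'
#' Peaks are differential when logCPM (averaged over the two conditions)
#' exceeds `min_logCPM` and either q < `q_cut`, or |logFC| > `alt_logFC`
#' with p < `alt_p`. Peaks on `excluded_chroms` are dropped (duplicated
#' assembly regions whose calls are unreliable).
#'
#' @param min_logCPM logCPM floor (default 1).
#' @param q_cut primary q-value cutoff (default 0.01).
#' @param alt_logFC alternate |logFC| threshold (default 3).
#' @param alt_p alternate p-value cutoff (default 0.01).
#' @param excluded_chroms chromosomes excluded from selection.
#' @return list of criteria.
#' @export
selection_criteria <- function(min_logCPM = 1, q_cut = 0.01, alt_logFC = 3,
                               alt_p = 0.01,
                               excluded_chroms = c("chr2a", "chr2b")) {
  list(min_logCPM = min_logCPM, q_cut = q_cut, alt_logFC = alt_logFC,
       alt_p = alt_p, excluded_chroms = excluded_chroms)
}

#' Apply the compound selection criteria to tested peaks
#'
#' @param peaks data.frame with `chrom`, `logCPM`, `logFC`, `p`, `q`.
#' @param criteria list from [selection_criteria()].
#' @return the input with `selected` (logical) and `direction`
#'   (`HD_up`/`HD_down`/`not_differential`) columns added.
#' @export
select_differential <- function(peaks, criteria = selection_criteria()) {
  sel <- peaks$logCPM > criteria$min_logCPM &
    (peaks$q < criteria$q_cut |
       (abs(peaks$logFC) > criteria$alt_logFC & peaks$p < criteria$alt_p))
  sel <- sel & !(peaks$chrom %in% criteria$excluded_chroms)
  peaks$selected <- sel
  peaks$direction <- ifelse(!sel, "not_differential",
                            ifelse(peaks$logFC > 0, "HD_up", "HD_down"))
  peaks
}

#' Differential accessibility test between two pooled samples
#'
#' Full per-stage routine: count fragments in peaks for both samples,
#' fit and apply the MA normalization on common peaks, compute logCPM
#' (log2 of the mean of the two samples' counts-per-million, +0.5
#' pseudocount) and normalized logFC, run the exact binomial test, adjust
#' by BH, and apply the selection criteria.
#'
#' @param fragments1,fragments2 fragment tables for sample 1 (test, HD)
#'   and sample 2 (reference, WT).
#' @param peaks merged peak table (optionally with `summit`).
#' @param common logical mask of common peaks; default all.
#' @param criteria selection criteria list.
#' @return `peaks` augmented with `count_hd`, `count_wt`,
#'   `count_wt_norm`, `M`, `A`, `logCPM`, `logFC`, `p`, `q`, `selected`,
#'   `direction`; the normalization fit is attached as attribute
#'   `ma_fit`.
#' @export
differential_accessibility <- function(fragments1, fragments2, peaks,
                                       common = NULL,
                                       criteria = selection_criteria()) {
  c1 <- count_fragments_in_peaks(fragments1, peaks)
  c2 <- count_fragments_in_peaks(fragments2, peaks)
  differential_from_counts(c1$counts, c2$counts,
                           c1$library_size, c2$library_size,
                           peaks, common = common, criteria = criteria)
}

#' Differential accessibility from precomputed counts
#'
#' @param x1,x2 per-peak counts (sample 1 = HD, sample 2 = WT).
#' @param lib1,lib2 library sizes (total fragments).
#' @inheritParams differential_accessibility
#' @return see [differential_accessibility()].
#' @export
differential_from_counts <- function(x1, x2, lib1, lib2, peaks,
                                     common = NULL,
                                     criteria = selection_criteria()) {
  fit <- fit_ma_normalization(x1, x2, common)
  x2n <- apply_normalization(x1, x2, fit)
  v <- ma_values(x1, x2)
  cpm1 <- (x1 + 0.5) / (lib1 + 1) * 1e6
  cpm2 <- (x2 + 0.5) / (lib2 + 1) * 1e6
  out <- peaks
  out$count_hd <- x1
  out$count_wt <- x2
  out$count_wt_norm <- x2n
  out$M <- v$M
  out$A <- v$A
  out$logCPM <- log2((cpm1 + cpm2) / 2)
  out$logFC <- log2((x1 + 0.5) / (x2n + 0.5))
  out$p <- diff_pvalue(x1, x2n)
  out$q <- bh_adjust(out$p)
  out <- select_differential(out, criteria)
  attr(out, "ma_fit") <- fit
  out
}

#' Differential nucleosome occupancy at promoters
#'
#' Runs the count / normalize / test / select machinery over 2-kb windows
#' centered at TSSs, using mononucleosome-sized fragments, to detect
#' promoter occupancy differences between the two samples.
#'
#' @param mono1,mono2 mononucleosome fragment tables (HD, WT).
#' @param genes gene-model data.frame.
#' @param half_width promoter window half-width (default 1000 bp).
#' @param criteria selection criteria.
#' @return per-promoter differential table (one row per gene) as in
#'   [differential_accessibility()], with `gene_id` carried through.
#' @export
diff_promoter_occupancy <- function(mono1, mono2, genes,
                                    half_width = 1000L,
                                    criteria = selection_criteria()) {
  w <- center_window(genes$tss, half_width)
  windows <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = w$start, end = w$end)
  if (nrow(mono1) == 0L && nrow(mono2) == 0L) {
    return(windows[0, , drop = FALSE])
  }
  differential_accessibility(mono1, mono2, windows, criteria = criteria)
}

#' Replicate agreement on log-scale peak counts
#'
#' Pearson correlation of log2(count + 1) across a shared peak set; `NA`
#' when either replicate is constant.
#'
#' @param counts_rep1,counts_rep2 per-peak counts for the two replicates.
#' @return correlation coefficient or NA.
#' @export
replicate_correlation <- function(counts_rep1, counts_rep2) {
  stopifnot(length(counts_rep1) == length(counts_rep2))
  l1 <- log2(counts_rep1 + 1)
  l2 <- log2(counts_rep2 + 1)
  if (stats::sd(l1) == 0 || stats::sd(l2) == 0) return(NA_real_)
  cor(l1, l2)
}

round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize per-stage differential peak calls
#'
#' Accepts either a named list of per-stage differential tables (from
#' [differential_accessibility()], with `proximity` labels) or a
#' data.frame of per-stage component counts, and produces a summary in
#' the style of a differential-peak accounting table: per stage the
#' proximal/distal peak totals, differential total, enriched (HD_up) and
#' depleted (HD_down) counts with percentage shares (one decimal,
#' half-up), plus grand totals of proximal and distal differential peaks
#' across stages.
#'
#' @param stages named list of differential tables, or a data.frame with
#'   columns `stage`, `n_up`, `n_down` and optionally `n_proximal`,
#'   `n_distal`, `n_up_proximal`, `n_down_proximal`.
#' @return list with `per_stage` (data.frame) and `totals` (list with
#'   `differential`, `proximal_differential`, `distal_differential`,
#'   `enriched`, `depleted`).
#' @export
summarize_differential <- function(stages) {
  if (is.data.frame(stages)) {
    tab <- stages
  } else {
    tab <- do.call(rbind, lapply(names(stages), function(s) {
      d <- stages[[s]]
      sel <- d[d$selected, , drop = FALSE]
      prox <- if ("proximity" %in% names(d)) d$proximity else
        rep(NA_character_, nrow(d))
      psel <- if ("proximity" %in% names(sel)) sel$proximity else
        rep(NA_character_, nrow(sel))
      data.frame(
        stage = s,
        n_proximal = sum(prox == "proximal", na.rm = TRUE),
        n_distal = sum(prox == "distal", na.rm = TRUE),
        n_up = sum(sel$direction == "HD_up"),
        n_down = sum(sel$direction == "HD_down"),
        n_up_proximal = sum(sel$direction == "HD_up" & psel == "proximal",
                            na.rm = TRUE),
        n_down_proximal = sum(sel$direction == "HD_down" &
                                psel == "proximal", na.rm = TRUE)
      )
    }))
  }
  tab$n_diff <- tab$n_up + tab$n_down
  tab$pct_up <- ifelse(tab$n_diff > 0,
                       round_half_up(100 * tab$n_up / tab$n_diff), NA_real_)
  tab$pct_down <- ifelse(tab$n_diff > 0,
                         round_half_up(100 * tab$n_down / tab$n_diff),
                         NA_real_)
  totals <- list(differential = sum(tab$n_diff),
                 enriched = sum(tab$n_up), depleted = sum(tab$n_down))
  if (all(c("n_up_proximal", "n_down_proximal") %in% names(tab))) {
    tab$n_diff_proximal <- tab$n_up_proximal + tab$n_down_proximal
    tab$n_diff_distal <- tab$n_diff - tab$n_diff_proximal
    totals$proximal_differential <- sum(tab$n_diff_proximal)
    totals$distal_differential <- sum(tab$n_diff_distal)
    totals$proximal_enriched <- sum(tab$n_up_proximal)
    totals$proximal_depleted <- sum(tab$n_down_proximal)
    totals$distal_enriched <- totals$enriched - totals$proximal_enriched
    totals$distal_depleted <- totals$depleted - totals$proximal_depleted
  }
  list(per_stage = tab, totals = totals)
}
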