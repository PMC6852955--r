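## PWM motif scanning in peak summit windows with exact score p-values,
## best-motif-per-peak deduplication, and per-motif Fisher enrichment on
## the literal nested contingency (the direction set is a subset of the
## condition's peak set; rows are intentionally not disjoint).

DNA_BASES <- c("A", "C", "G", "T")

#' Read motifs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` and the
#' file-level `Background letter frequencies`. Rows whose probabilities
#' sum to within 1e-3 of 1 are renormalized; larger deviations are an
#' error naming the offending motif.
#'
#' @param path MEME minimal file.
#' @return named list of PWMs; each a list with `motif_id`, `probs`
#'   (L x 4 matrix, columns A,C,G,T) and `background` (length-4 named
#'   vector).
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- setNames(rep(0.25, 4), DNA_BASES)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1L && bg_at < length(lines)) {
    f <- strsplit(lines[bg_at + 1L], "\\s+")[[1]]
    vals <- as.numeric(f[seq(2, length(f), by = 2)])
    names(vals) <- f[seq(1, length(f), by = 2)]
    bg <- vals[DNA_BASES]
    if (abs(sum(bg) - 1) > 1e-6) stop("background frequencies must sum to 1")
  }
  starts <- grep("^MOTIF\\b", lines)
  pwms <- lapply(starts, function(i) {
    id <- strsplit(lines[i], "\\s+")[[1]][2]
    hdr <- i + which(grepl("^letter-probability matrix",
                           lines[(i + 1):length(lines)]))[1]
    if (is.na(hdr)) stop("motif ", id, ": no letter-probability matrix")
    w <- suppressWarnings(
      as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    if (is.na(w)) stop("motif ", id, ": cannot parse matrix width")
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]])))
    if (ncol(mat) != 4L || any(is.na(mat)))
      stop("motif ", id, ": malformed probability matrix")
    rs <- rowSums(mat)
    if (any(abs(rs - 1) > 1e-3 + 1e-9))
      stop("motif ", id, ": probability rows do not sum to 1")
    mat <- mat / rs
    colnames(mat) <- DNA_BASES
    list(motif_id = id, probs = mat, background = bg)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "motif_id")
  pwms
}

#' Write motifs in MEME minimal format
#' @param pwms list of PWMs as returned by [read_meme()].
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, bg), collapse = " "),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$probs)), con)
    writeLines(apply(p$probs, 1, function(r)
      paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

## Integer-discretized log-odds score matrix (bits / delta), with a small
## pseudo-probability blended in so zero entries stay finite.
pwm_int_scores <- function(pwm, delta = 0.001, pseudo = 1e-3) {
  p <- (pwm$probs + pseudo * rep(pwm$background, each = nrow(pwm$probs))) /
    (1 + pseudo)
  bits <- log2(p / rep(pwm$background, each = nrow(p)))
  matrix(as.integer(round(bits / delta)), nrow(p), 4,
         dimnames = list(NULL, DNA_BASES))
}

reverse_complement_scores <- function(S) {
  S[rev(seq_len(nrow(S))), c("T", "G", "C", "A"), drop = FALSE]
}

#' Exact null distribution of the discretized PWM score
#'
#' Computes, by position-wise convolution over the integer-discretized
#' log-odds scores (default granularity 1/1000 bit), the exact
#' distribution of the score of a random background sequence of the
#' motif's length, and from it the tail p-value p(s) = P(score >= s).
#'
#' @param S integer score matrix from `pwm_int_scores`, or a PWM (then
#'   converted with defaults).
#' @param background length-4 base probabilities of the 0-order background.
#' @param delta bits per score unit (metadata only; default 0.001).
#' @return list: `delta`, `min_score`, `max_score` (integer units),
#'   `density` and `pvals` vectors indexed by `score - min_score + 1`;
#'   `pvals[i]` is the tail mass at that score.
#' @export
score_pvalue_table <- function(S, background = NULL, delta = 0.001) {
  if (is.list(S) && !is.null(S$probs)) {
    if (is.null(background)) background <- S$background
    S <- pwm_int_scores(S, delta = delta)
  }
  stopifnot(!is.null(background), abs(sum(background) - 1) < 1e-6)
  dist <- 1
  offset <- 0L
  for (l in seq_len(nrow(S))) {
    s <- S[l, ]
    ml <- min(s)
    new <- numeric(length(dist) + max(s) - ml)
    for (b in 1:4) {
      sh <- s[b] - ml
      idx <- sh + seq_along(dist)
      new[idx] <- new[idx] + background[b] * dist
    }
    dist <- new
    offset <- offset + ml
  }
  pv <- rev(cumsum(rev(dist)))
  list(delta = delta, min_score = offset,
       max_score = offset + length(dist) - 1L,
       density = dist, pvals = pv)
}

score_to_pvalue <- function(score_int, table) {
  i <- score_int - table$min_score + 1L
  i <- pmin(pmax(i, 1L), length(table$pvals))
  p <- table$pvals[i]
  p[score_int < table$min_score] <- 1
  p
}

encode_sequences <- function(seqs) {
  W <- max(nchar(seqs))
  code <- matrix(NA_integer_, length(seqs), W)
  for (i in seq_along(seqs)) {
    b <- strsplit(toupper(seqs[i]), "")[[1]]
    code[i, seq_along(b)] <- match(b, DNA_BASES)   # N and others -> NA
  }
  code
}

#' Scan peak summit-window sequences for PWM matches
#'
#' Scores every offset of every window on both strands against each PWM's
#' discretized log-odds matrix, converts scores to exact background
#' p-values, and keeps matches with p <= `p_threshold`. Positions whose
#' window contains an ambiguous base (N) are skipped; windows shorter
#' than a motif yield no hits for it.
#'
#' @param seqs named character vector of window sequences (names are peak
#'   ids; A/C/G/T/N).
#' @param pwms list of PWMs ([read_meme()] format).
#' @param p_threshold match p-value cutoff (default 1e-4).
#' @param delta score granularity in bits (default 0.001).
#' @param pseudo pseudo-probability blended into the PWM (default 1e-3).
#' @return data.frame of hits: `peak_id`, `motif_id`, `offset` (0-based
#'   within window, forward coordinates), `strand`, `score` (bits), `p`.
#' @export
scan_peak_windows <- function(seqs, pwms, p_threshold = 1e-4,
                              delta = 0.001, pseudo = 1e-3) {
  stopifnot(!is.null(names(seqs)))
  empty <- data.frame(peak_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p = numeric())
  if (length(seqs) == 0L) return(empty)
  code <- encode_sequences(seqs)
  n <- nrow(code); W <- ncol(code)
  out <- list()
  for (pwm in pwms) {
    Sf <- pwm_int_scores(pwm, delta = delta, pseudo = pseudo)
    L <- nrow(Sf)
    if (W < L) next
    for (strand in c("+", "-")) {
      S <- if (strand == "+") Sf else reverse_complement_scores(Sf)
      tab <- score_pvalue_table(S, pwm$background, delta = delta)
      ## smallest integer score still significant at the threshold
      sig <- which(tab$pvals <= p_threshold)
      if (length(sig) == 0L) next
      min_sig <- tab$min_score + sig[1L] - 1L
      for (j in seq_len(W - L + 1L)) {
        sc <- rowSums(matrix(
          S[cbind(rep(seq_len(L), each = n),
                  as.vector(code[, j:(j + L - 1L), drop = FALSE]))],
          n, L))
        hit <- which(!is.na(sc) & sc >= min_sig)
        if (length(hit) > 0L) {
          out[[length(out) + 1L]] <- data.frame(
            peak_id = names(seqs)[hit], motif_id = pwm$motif_id,
            offset = j - 1L, strand = strand,
            score = sc[hit] * delta,
            p = score_to_pvalue(sc[hit], tab))
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep the most significant motif hit per peak
#'
#' Per peak, the hit with the lowest match p-value; ties broken by higher
#' score, then leftmost offset, then + strand over -, then lexicographic
#' motif id.
#'
#' @param hits hit data.frame from [scan_peak_windows()].
#' @return at most one row per `peak_id`.
#' @export
best_hit_per_peak <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$peak_id, hits$p, -hits$score, hits$offset,
               hits$strand != "+", hits$motif_id)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$peak_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Per-motif enrichment contingency table
#'
#' Built literally from deduplicated (best-per-peak) hits:
#' N11 = peaks in the direction set carrying motif X, N12 = direction-set
#' peaks carrying any other motif, N21 = condition peaks carrying X,
#' N22 = condition peaks carrying any other motif. The direction set is a
#' subset of the condition peaks, so the rows are nested, not disjoint —
#' the test contrasts the motif's share among differential peaks with its
#' share among all peaks.
#'
#' @param motif_id motif to tabulate.
#' @param dedup_hits data.frame with `peak_id`, `motif_id` (<= 1 row per
#'   peak).
#' @param direction_peaks peak ids of the differential set for one
#'   direction.
#' @param all_peaks peak ids of every peak of that condition.
#' @return list: `motif_id`, `N11`, `N12`, `N21`, `N22`.
#' @export
build_contingency <- function(motif_id, dedup_hits, direction_peaks,
                              all_peaks) {
  stopifnot(!anyDuplicated(dedup_hits$peak_id))
  in_dir <- dedup_hits$peak_id %in% direction_peaks
  in_all <- dedup_hits$peak_id %in% all_peaks
  is_x <- dedup_hits$motif_id == motif_id
  list(motif_id = motif_id,
       N11 = sum(is_x & in_dir), N12 = sum(!is_x & in_dir),
       N21 = sum(is_x & in_all), N22 = sum(!is_x & in_all))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities, under fixed margins, of every
#' table no more probable than the observed one (the standard two-sided
#' rule). A zero row sum gives p = 1 with a warning.
#'
#' @param n11,n12,n21,n22 non-negative cell counts, or a single list with
#'   fields `N11`..`N22` as first argument.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(n11, n12 = NULL, n21 = NULL, n22 = NULL) {
  if (is.list(n11)) {
    t <- n11
    n11 <- t$N11; n12 <- t$N12; n21 <- t$N21; n22 <- t$N22
  }
  stopifnot(all(c(n11, n12, n21, n22) >= 0))
  r1 <- n11 + n12
  r2 <- n21 + n22
  if (r1 == 0 || r2 == 0) {
    warning("zero row sum; p = 1")
    return(1)
  }
  c1 <- n11 + n21
  support <- max(0, c1 - r2):min(r1, c1)
  d <- dhyper(support, r1, r2, c1)
  obs <- dhyper(n11, r1, r2, c1)
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Motif enrichment over directions and proximity contexts
#'
#' For each direction (`HD_up`, `WT_up`) crossed with each context
#' (`proximal`, `distal`) and each motif, builds the nested contingency
#' from the deduplicated hits and tests it with Fisher's exact test. Raw
#' p-values are reported without multiple-test adjustment; motifs with
#' p < `alpha` are flagged significant.
#'
#' @param dedup_hits best-per-peak hits (`peak_id`, `motif_id`).
#' @param peak_info data.frame with `peak_id`, `direction`
#'   (`HD_up`/`HD_down`/`not_differential`) and `proximity`
#'   (`proximal`/`distal`); `HD_down` peaks form the `WT_up` set.
#' @param motif_ids motifs to test (default: all in `dedup_hits`).
#' @param alpha significance flag threshold (default 0.05).
#' @return data.frame: `direction`, `context`, `motif_id`, `N11`..`N22`,
#'   `p`, `prop_diff` (difference of motif shares), `significant`.
#' @export
enrichment_scan <- function(dedup_hits, peak_info, motif_ids = NULL,
                            alpha = 0.05) {
  if (is.null(motif_ids)) motif_ids <- sort(unique(dedup_hits$motif_id))
  dir_sets <- list(HD_up = "HD_up", WT_up = "HD_down")
  out <- list()
  for (dir in names(dir_sets)) {
    for (ctx in c("proximal", "distal")) {
      ctx_ids <- peak_info$peak_id[peak_info$proximity == ctx]
      dir_ids <- peak_info$peak_id[peak_info$direction == dir_sets[[dir]] &
                                     peak_info$proximity == ctx]
      for (m in motif_ids) {
        ct <- build_contingency(m, dedup_hits, dir_ids, ctx_ids)
        p <- if (ct$N11 + ct$N12 == 0) 1 else
          suppressWarnings(fisher_exact(ct))
        pd <- if (ct$N11 + ct$N12 > 0 && ct$N21 + ct$N22 > 0)
          ct$N11 / (ct$N11 + ct$N12) - ct$N21 / (ct$N21 + ct$N22)
        else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          direction = dir, context = ctx, motif_id = m,
          N11 = ct$N11, N12 = ct$N12, N21 = ct$N21, N22 = ct$N22,
          p = p, prop_diff = pd, significant = p < alpha)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract summit-window sequences for peaks
#'
#' @param genome named `DNAStringSet` (or named character) of chromosome
#'   sequences.
#' @param peaks peak data.frame with `chrom` and `summit` columns; peak
#'   ids taken from a `peak_id` column or generated.
#' @param half_width window half-width around the summit (default 200 bp).
#' @return named character vector of window sequences.
#' @export
summit_window_sequences <- function(genome, peaks, half_width = 200L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  ids <- if ("peak_id" %in% names(peaks)) peaks$peak_id else
    paste0("peak_", seq_len(nrow(peaks)))
  lens <- setNames(Biostrings::width(genome), names(genome))
  w <- center_window(peaks$summit, half_width,
                     max_end = lens[peaks$chrom])
  seqs <- vapply(seq_len(nrow(peaks)), function(i)
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = w$start[i] + 1L,
                                    end = w$end[i])),
    character(1))
  setNames(seqs, ids)
}
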