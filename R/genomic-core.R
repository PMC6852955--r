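#' @importFrom stats complete.cases cor dbinom dhyper hclust dist p.adjust
#'   rbinom rnbinom rnorm rpois runif rgamma setNames t.test aggregate
#' @importFrom utils read.table write.table head
NULL

## Regions are plain data.frames with columns chrom, start, end in 0-based
## half-open coordinates (BED convention). Gene models additionally carry
## gene_id, strand, tss, tes. GRanges (1-based closed) is used internally.

#' Convert a 0-based half-open region table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A `GRanges` (1-based closed) preserving row order.
#' @keywords internal
as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

validate_regions <- function(df, what = "region") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0)) stop(what, " starts must be >= 0")
  if (any(df$start >= df$end)) stop(what, " must satisfy start < end")
  if (any(!nzchar(df$chrom))) stop(what, " chromosome names must be non-empty")
  invisible(df)
}

#' Shift fragment cut sites by the Tn5 insertion offset
#'
#' ATAC-seq fragment ends mark Tn5 insertion points, which sit 9 bp apart on
#' the two strands of the insertion site. The conventional correction moves
#' the plus-strand 5' cut site by +4 bp and the minus-strand 5' cut site by
#' -5 bp so both point at the center of the insertion. For an interval
#' fragment this shifts `start` by `plus_shift` and `end` by `minus_shift`;
#' every retained fragment shortens by `plus_shift - minus_shift` bp.
#'
#' Fragments whose shifted interval would be empty or inverted are dropped
#' (not an error); their count is attached as attribute `n_rejected` and
#' reported via a message.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param plus_shift bp added to the plus-strand cut site (default +4).
#' @param minus_shift bp added to the minus-strand cut site (default -5).
#' @return The shifted fragment table (rejected rows removed), with
#'   attribute `n_rejected`.
#' @export
shift_tn5 <- function(fragments, plus_shift = 4L, minus_shift = -5L) {
  validate_regions(fragments, "fragment")
  start <- fragments$start + plus_shift
  end <- fragments$end + minus_shift
  ok <- start >= 0 & start < end
  n_rej <- sum(!ok)
  if (n_rej > 0L) {
    message(n_rej, " fragment(s) rejected: empty interval after Tn5 offset")
  }
  out <- fragments[ok, , drop = FALSE]
  out$start <- start[ok]
  out$end <- end[ok]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rej
  out
}

#' Classify ATAC fragment lengths into size classes
#'
#' Sub-nucleosomal fragments (< 125 bp) mark Tn5 hypersensitive sites;
#' mononucleosome fragments (171-254 bp inclusive) span one nucleosome and
#' are used for promoter occupancy analysis. Everything else is `other`.
#'
#' @param length integer vector of fragment lengths in bp (>= 1).
#' @return character vector in `{non_nucleosomal, mononucleosome, other}`.
#' @export
classify_fragment_length <- function(length) {
  if (any(length <= 0)) stop("fragment lengths must be positive")
  ifelse(length < 125, "non_nucleosomal",
         ifelse(length >= 171 & length <= 254, "mononucleosome", "other"))
}

#' Merge overlapping or touching intervals
#'
#' Produces the sorted non-overlapping cover of the input. Intervals that
#' merely touch (one's end equals the other's start) are merged, matching
#' common merge-tool defaults; `min_gap` extends this to merge intervals
#' separated by up to that many bp.
#'
#' @param intervals region data.frame (`chrom`, `start`, `end`).
#' @param min_gap maximum separating gap (bp) still merged; default 0
#'   (touching intervals merge, disjoint ones do not).
#' @return merged region data.frame, sorted by (chrom, start).
#' @export
merge_intervals <- function(intervals, min_gap = 0L) {
  validate_regions(intervals)
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  gr <- GenomicRanges::reduce(as_granges(intervals),
                              min.gapwidth = min_gap + 1L)
  gr <- GenomicRanges::sort(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

## TSS promoter windows [tss - radius, tss + radius] closed, as half-open.
tss_windows <- function(genes, radius) {
  data.frame(
    chrom = genes$chrom,
    start = pmax(0L, genes$tss - radius),
    end = genes$tss + radius + 1L
  )
}

#' Label regions as TSS-proximal or distal
#'
#' A region is proximal when it overlaps the closed window +/- `radius` bp
#' around any gene's transcription start site (strand-aware TSS; every
#' annotated TSS counts). Overlap is measured from the region's edges.
#'
#' @param regions region data.frame.
#' @param genes gene-model data.frame with `chrom`, `tss`.
#' @param radius window half-width in bp (default 500).
#' @return character vector `proximal`/`distal`, one per region.
#' @export
classify_tss_proximity <- function(regions, genes, radius = 500L) {
  stopifnot(radius > 0)
  if (nrow(regions) == 0L) return(character())
  if (is.null(genes) || nrow(genes) == 0L) {
    warning("no genes supplied; all regions classified distal")
    return(rep("distal", nrow(regions)))
  }
  hits <- GenomicRanges::countOverlaps(
    as_granges(regions), as_granges(tss_windows(genes, radius))
  )
  ifelse(hits > 0L, "proximal", "distal")
}

#' Label regions as intragenic or intergenic
#'
#' Intragenic means >= 1 bp overlap with any gene body.
#'
#' @param regions region data.frame.
#' @param genes gene-model data.frame with `chrom`, `start`, `end` (body).
#' @return character vector `intragenic`/`intergenic`.
#' @export
classify_genic_context <- function(regions, genes) {
  if (nrow(regions) == 0L) return(character())
  if (is.null(genes) || nrow(genes) == 0L) {
    return(rep("intergenic", nrow(regions)))
  }
  hits <- GenomicRanges::countOverlaps(as_granges(regions), as_granges(genes))
  ifelse(hits > 0L, "intragenic", "intergenic")
}

#' Nearest target interval with signed edge distance
#'
#' For each query, the closest target on the same chromosome. Distance is 0
#' when they overlap, otherwise the gap between the closest edges, signed
#' positive when the target lies downstream (to the right) of the query and
#' negative when upstream. Ties are broken deterministically: smaller
#' absolute distance, then upstream over downstream, then smaller target
#' start. Queries with no same-chromosome target get `NA`.
#'
#' @param queries region data.frame.
#' @param targets region data.frame.
#' @return data.frame with one row per query: `target_idx` (row index into
#'   `targets`, NA if none) and `distance` (signed bp).
#' @export
nearest_feature <- function(queries, targets) {
  nq <- nrow(queries)
  out <- data.frame(target_idx = rep(NA_integer_, nq),
                    distance = rep(NA_real_, nq))
  if (nq == 0L || nrow(targets) == 0L) return(out)
  for (chr in unique(queries$chrom)) {
    qi <- which(queries$chrom == chr)
    ti <- which(targets$chrom == chr)
    if (length(ti) == 0L) next
    ts <- targets$start[ti]; te <- targets$end[ti]
    for (i in qi) {
      qs <- queries$start[i]; qe <- queries$end[i]
      ## signed gap: 0 if overlapping; + if target starts at/after query end
      d <- ifelse(ts >= qe, ts - qe,
                  ifelse(te <= qs, -(qs - te), 0))
      ord <- order(abs(d), d >= 0, ts)
      best <- ord[1L]
      out$target_idx[i] <- ti[best]
      out$distance[i] <- d[best]
    }
  }
  out
}

#' Half-open window around a center position
#'
#' `[center - half_width, center + half_width)`, left-clipped at 0 and
#' optionally right-clipped at a chromosome length.
#'
#' @param center position(s) in bp.
#' @param half_width window half-width in bp (> 0).
#' @param max_end optional exclusive upper clip (chromosome length).
#' @return data.frame with `start`, `end`.
#' @export
center_window <- function(center, half_width, max_end = NULL) {
  stopifnot(half_width > 0)
  start <- pmax(0L, as.integer(center - half_width))
  end <- as.integer(center + half_width)
  if (!is.null(max_end)) end <- pmin(end, as.integer(max_end))
  data.frame(start = start, end = end)
}
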