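#' Read a BED file of regions
#'
#' Accepts BED3/BED6; an optional 7th column is read as the summit offset
#' relative to `start` (peak callers' convention), stored as absolute
#' position in column `summit`. Tab-separated, no header.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, and when present
#'   `name`, `score`, `strand`, `summit`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "",
                   comment.char = "#")
  out <- data.frame(chrom = df[[1]],
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]))
  if (ncol(df) >= 4) out$name <- df[[4]]
  if (ncol(df) >= 5) out$score <- as.numeric(df[[5]])
  if (ncol(df) >= 6) out$strand <- df[[6]]
  if (ncol(df) >= 7) out$summit <- out$start + as.integer(df[[7]])
  validate_regions(out, basename(path))
  out
}

#' Write regions to BED
#'
#' Writes BED3 plus `name`, `score`, `strand` when present; a `summit`
#' column (absolute position) is written as column 7, as offset from
#' `start`.
#'
#' @param regions region data.frame.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  cols <- list(regions$chrom, regions$start, regions$end)
  has_summit <- "summit" %in% names(regions)
  if ("name" %in% names(regions)) cols <- c(cols, list(regions$name))
  else if (has_summit) cols <- c(cols, list(rep(".", nrow(regions))))
  if ("score" %in% names(regions)) cols <- c(cols, list(regions$score))
  else if (has_summit) cols <- c(cols, list(rep(0L, nrow(regions))))
  if ("strand" %in% names(regions)) cols <- c(cols, list(regions$strand))
  else if (has_summit) cols <- c(cols, list(rep(".", nrow(regions))))
  if (has_summit) cols <- c(cols, list(regions$summit - regions$start))
  write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF subset
#'
#' Reads a tab-separated GTF restricted to `gene` (or `transcript`)
#' feature rows, converting 1-based closed coordinates to the package's
#' 0-based half-open convention and deriving the strand-aware TSS/TES.
#' Only the `gene_id` attribute is parsed.
#'
#' @param path GTF file path.
#' @param feature feature type to keep (default `"gene"`).
#' @return gene-model data.frame: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes`.
#' @export
read_gtf_genes <- function(path, feature = "gene") {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   comment.char = "#", colClasses = "character")
  df <- df[df[[3]] == feature, , drop = FALSE]
  start <- as.integer(df[[4]]) - 1L   # 1-based closed -> 0-based half-open
  end <- as.integer(df[[5]])
  strand <- df[[7]]
  if (any(!strand %in% c("+", "-"))) stop("strand must be + or -")
  gene_id <- sub('.*gene_id[ ]+"([^"]+)".*', "\\1", df[[9]])
  data.frame(
    gene_id = gene_id, chrom = df[[1]], strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end - 1L),
    tes = ifelse(strand == "+", end - 1L, start)
  )
}

#' Write gene models as a GTF subset
#' @param genes gene-model data.frame.
#' @param path output path.
#' @export
write_gtf_genes <- function(genes, path) {
  lines <- sprintf(
    "%s\tthssdiff\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, "na", sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cuffdiff-style differential-expression table
#'
#' Expects a header with columns `gene_id`, `sample_1`, `sample_2`,
#' `value_1`, `value_2`, `p_value`, `q_value` where `value_*` are FPKM and
#' sample names encode condition and stage as `<condition>_<stage>`
#' (sample 1 the reference/WT, sample 2 the test/HD condition).
#'
#' @param path TSV path.
#' @param q_cut q-value cutoff for calling a gene differentially expressed
#'   (default 0.05).
#' @return data.frame: `gene_id`, `stage`, `fpkm_wt`, `fpkm_hd`, `p`, `q`,
#'   `is_de`.
#' @export
read_cuffdiff <- function(path, q_cut = 0.05) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  stage <- sub("^[^_]+_", "", df$sample_1)
  data.frame(
    gene_id = df$gene_id, stage = stage,
    fpkm_wt = df$value_1, fpkm_hd = df$value_2,
    p = df$p_value, q = df$q_value,
    is_de = df$q_value < q_cut
  )
}
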