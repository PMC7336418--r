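#' Read gene annotations from a BED file
#'
#' Reads a BED4+ file of gene intervals for nearest-gene reporting. BED is
#' 0-based half-open; returned coordinates are 1-based inclusive, the
#' convention used throughout this package. Overlapping genes are retained
#' as-is (no merging).
#'
#' @param path Path to a BED file with at least four columns
#'   (chrom, start, end, name).
#' @return A data.frame with columns `gene_name`, `chromosome`, `start`,
#'   `end`, sorted by `start` (then `gene_name`).
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   !startsWith(lines, "browser")]
  empty <- data.frame(gene_name = character(), chromosome = character(),
                      start = integer(), end = integer())
  if (!length(lines)) return(empty)
  gr <- rtracklayer::import(path, format = "BED")
  name <- gr$name
  if (is.null(name)) name <- rep(NA_character_, length(gr))
  out <- data.frame(
    gene_name = as.character(name),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # already 1-based inclusive
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) {
    stop("gene annotation with start > end in ", path, call. = FALSE)
  }
  out <- out[order(out$start, out$gene_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
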