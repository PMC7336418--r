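#' Write a two-level DMR report CSV
#'
#' One `DMR` line per region — chromosome, initial and final position,
#' closest gene and distance, direction (hyper when the case group averages
#' higher, hypo otherwise) and mean group difference — followed by one
#' `SAMPLE` line per analyzed sample with the count of informative
#' nucleotides, min/avg/max coverage, summed reads detecting C, mC, hmC and
#' non-C, and min/avg/max distance between informative positions. Column
#' layouts are documented in `#`-prefixed header comments; the leading
#' record-type token distinguishes the two levels.
#'
#' @param regions Region data.frame from [detect_dmrs()] (one chromosome).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_dmr_csv <- function(regions, path) {
  if (nrow(regions) && length(unique(regions$chromosome)) > 1L) {
    stop("regions must belong to one chromosome; write one file per ",
         "chromosome", call. = FALSE)
  }
  header <- c(
    "# DMR report",
    "# DMR,chromosome,start,end,closest_gene,gene_distance,direction,mean_difference,n_windows",
    paste0("# SAMPLE,sample_id,n_informative,coverage_min,coverage_avg,",
           "coverage_max,reads_c,reads_mc,reads_hmc,reads_noc,",
           "gap_min,gap_avg,gap_max"))
  fmt <- function(x) {
    ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 15))
  }
  lines <- header
  for (i in seq_len(nrow(regions))) {
    lines <- c(lines, paste("DMR", regions$chromosome[i], regions$start[i],
                            regions$end[i],
                            ifelse(is.na(regions$closest_gene[i]), "NA",
                                   regions$closest_gene[i]),
                            fmt(regions$gene_distance[i]),
                            regions$direction[i],
                            fmt(regions$mean_difference[i]),
                            regions$n_windows[i], sep = ","))
    st <- regions$per_sample[[i]]
    for (k in seq_len(nrow(st))) {
      lines <- c(lines, paste("SAMPLE", st$sample_id[k], st$n_informative[k],
                              fmt(st$coverage_min[k]), fmt(st$coverage_avg[k]),
                              fmt(st$coverage_max[k]), fmt(st$reads_c[k]),
                              fmt(st$reads_mc[k]), fmt(st$reads_hmc[k]),
                              fmt(st$reads_noc[k]), fmt(st$gap_min[k]),
                              fmt(st$gap_avg[k]), fmt(st$gap_max[k]),
                              sep = ","))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a DMR report CSV
#'
#' Inverse of [write_dmr_csv()]; `read_dmr_csv(write_dmr_csv(x))` reproduces
#' all region and per-sample fields.
#'
#' @param path A file written by [write_dmr_csv()].
#' @return Region data.frame in the [detect_dmrs()] layout.
#' @export
read_dmr_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), direction = character(),
                      mean_difference = numeric(), n_windows = integer(),
                      closest_gene = character(), gene_distance = numeric())
  empty$per_sample <- list()
  if (!length(lines)) return(empty)
  num <- function(x) suppressWarnings(as.numeric(x))
  rows <- list()
  cur <- NULL
  cur_samples <- list()
  flush <- function() {
    if (is.null(cur)) return()
    cur$per_sample <- list(do.call(rbind, cur_samples))
    rows[[length(rows) + 1L]] <<- cur
  }
  for (ln in lines) {
    f <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    if (f[1L] == "DMR") {
      flush()
      cur_samples <- list()
      cur <- data.frame(chromosome = f[2L], start = as.integer(f[3L]),
                        end = as.integer(f[4L]),
                        direction = f[7L], mean_difference = num(f[8L]),
                        n_windows = as.integer(f[9L]),
                        closest_gene = if (f[5L] == "NA") NA_character_
                                       else f[5L],
                        gene_distance = num(f[6L]))
    } else if (f[1L] == "SAMPLE") {
      cur_samples[[length(cur_samples) + 1L]] <-
        data.frame(sample_id = f[2L], n_informative = as.integer(f[3L]),
                   coverage_min = num(f[4L]), coverage_avg = num(f[5L]),
                   coverage_max = num(f[6L]), reads_c = num(f[7L]),
                   reads_mc = num(f[8L]), reads_hmc = num(f[9L]),
                   reads_noc = num(f[10L]), gap_min = num(f[11L]),
                   gap_avg = num(f[12L]), gap_max = num(f[13L]))
    } else {
      stop("unrecognized record type '", f[1L], "' in ", path, call. = FALSE)
    }
  }
  flush()
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
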