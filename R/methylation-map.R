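#' Column dialect for methylation-map CSV files
#'
#' Upstream mappers emit one CSV per chromosome, strand and sample, with one
#' row per cytosine position carrying four read counts: reads showing an
#' unmethylated C, reads showing a base other than C, reads showing a
#' methylated C (5mC, inclusive of hydroxymethylated reads) and reads showing
#' a hydroxymethylated C (5hmC). The exact column layout varies between
#' pipelines, so a dialect maps the five record fields onto column names (when
#' the file has a header) or 1-based column indices (when it does not).
#'
#' @param columns Named character or integer vector mapping the field names
#'   `position`, `c_count`, `noc_count`, `mc_count`, `hmc_count` to column
#'   names (character, requires `header = TRUE`) or column indices (integer).
#' @param delim Single-character field delimiter. Default `","`.
#' @param header Whether the file carries a header row.
#' @return An object of class `meth_dialect`.
#' @examples
#' meth_dialect()  # default layout: pos,c,noc,mc,hmc
#' meth_dialect(columns = c(position = 1, c_count = 2, noc_count = 3,
#'                          mc_count = 4, hmc_count = 5), header = FALSE)
#' @export
meth_dialect <- function(columns = c(position = "pos", c_count = "c",
                                     noc_count = "noc", mc_count = "mc",
                                     hmc_count = "hmc"),
                         delim = ",", header = TRUE) {
  required <- c("position", "c_count", "noc_count", "mc_count", "hmc_count")
  if (!all(required %in% names(columns))) {
    stop("dialect must map all of: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  columns <- columns[required]
  if (is.numeric(columns)) {
    if (any(columns < 1 | columns != as.integer(columns))) {
      stop("dialect column indices must be positive integers", call. = FALSE)
    }
    columns <- as.integer(columns)
    names(columns) <- required
  } else if (!is.character(columns)) {
    stop("dialect columns must be column names or integer indices",
         call. = FALSE)
  }
  if (is.character(columns) && !header) {
    stop("a dialect with column names requires header = TRUE; ",
         "use integer indices for headerless files", call. = FALSE)
  }
  if (!is.character(delim) || nchar(delim) != 1L) {
    stop("delim must be a single character", call. = FALSE)
  }
  structure(list(columns = columns, delim = delim, header = isTRUE(header)),
            class = "meth_dialect")
}

new_methylation_map <- function(chromosome, strand, sample_id, records) {
  stopifnot(is.data.frame(records))
  structure(list(chromosome = chromosome, strand = strand,
                 sample_id = sample_id, records = records),
            class = "methylation_map")
}

#' Validate a methylation map against its invariants
#'
#' Checks strictly increasing, unique positions and per-record count
#' invariants (all counts non-negative, `hmc_count <= mc_count`,
#' `position >= 1`).
#'
#' @param map A `methylation_map`.
#' @return `map`, invisibly; stops on violation.
#' @export
validate_methylation_map <- function(map) {
  r <- map$records
  if (nrow(r)) {
    if (any(r$position < 1)) stop("positions must be >= 1", call. = FALSE)
    if (is.unsorted(r$position, strictly = TRUE)) {
      stop("record positions must be strictly increasing and unique",
           call. = FALSE)
    }
    counts <- as.matrix(r[, c("c_count", "noc_count", "mc_count", "hmc_count")])
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(r$hmc_count > r$mc_count)) {
      stop("hmc_count must not exceed mc_count ",
           "(5mC counts include hydroxymethylated reads)", call. = FALSE)
    }
  }
  invisible(map)
}

#' Read a per-chromosome methylation map CSV
#'
#' Loads one sample's methylation map for one chromosome and strand. Rows are
#' sorted by position on load; rows whose four counts are all zero are dropped
#' (they carry neither signal nor coverage). Rows with non-numeric fields,
#' negative counts, `hmc > mc`, or duplicated positions abort with an error
#' naming the offending data line.
#'
#' @param path Path to the CSV file.
#' @param dialect A [meth_dialect()] describing the column layout.
#' @param chromosome,strand,sample_id Metadata attached to the map; defaults
#'   are derived from the file name (`<chrom>.<strand>.csv` under a
#'   per-sample directory).
#' @return A `methylation_map`: a list with `chromosome`, `strand`,
#'   `sample_id` and a `records` data.frame with columns `position`,
#'   `c_count`, `noc_count`, `mc_count`, `hmc_count`.
#' @export
read_methylation_csv <- function(path, dialect = meth_dialect(),
                                 chromosome = NULL, strand = NULL,
                                 sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  stopifnot(inherits(dialect, "meth_dialect"))
  meta <- parse_map_filename(path)
  if (is.null(chromosome)) chromosome <- meta$chromosome
  if (is.null(strand)) strand <- meta$strand
  if (is.null(sample_id)) sample_id <- meta$sample_id

  raw <- data.table::fread(path, sep = dialect$delim,
                           header = dialect$header, colClasses = "character",
                           data.table = FALSE, showProgress = FALSE)
  cols <- dialect$columns
  if (is.character(cols)) {
    missing_cols <- setdiff(cols, names(raw))
    if (nrow(raw) == 0L && ncol(raw) == 0L) missing_cols <- character()
    if (length(missing_cols)) {
      stop("dialect names columns absent from ", path, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  } else if (nrow(raw) && max(cols) > ncol(raw)) {
    stop("dialect indexes column ", max(cols), " but ", path, " has only ",
         ncol(raw), " columns", call. = FALSE)
  }

  empty <- data.frame(position = integer(), c_count = integer(),
                      noc_count = integer(), mc_count = integer(),
                      hmc_count = integer())
  if (nrow(raw) == 0L) {
    return(validate_methylation_map(
      new_methylation_map(chromosome, strand, sample_id, empty)))
  }

  fields <- lapply(cols, function(col) raw[[col]])
  parsed <- lapply(fields, function(x) suppressWarnings(as.numeric(x)))
  bad <- Reduce(`|`, lapply(parsed, is.na))
  # data line numbers: header occupies line 1 when present
  line_of <- function(i) i + as.integer(dialect$header)
  if (any(bad)) {
    stop("malformed row at line ", line_of(which(bad)[1L]), " of ", path,
         call. = FALSE)
  }
  rec <- data.frame(position = parsed$position, c_count = parsed$c_count,
                    noc_count = parsed$noc_count, mc_count = parsed$mc_count,
                    hmc_count = parsed$hmc_count)
  neg <- rec$c_count < 0 | rec$noc_count < 0 | rec$mc_count < 0 |
    rec$hmc_count < 0 | rec$position < 1
  if (any(neg)) {
    stop("negative count or non-positive position at line ",
         line_of(which(neg)[1L]), " of ", path, call. = FALSE)
  }
  over <- rec$hmc_count > rec$mc_count
  if (any(over)) {
    stop("hmc_count exceeds mc_count at line ", line_of(which(over)[1L]),
         " of ", path, call. = FALSE)
  }
  dup <- duplicated(rec$position)
  if (any(dup)) {
    stop("duplicate position ", rec$position[which(dup)[1L]], " at line ",
         line_of(which(dup)[1L]), " of ", path, call. = FALSE)
  }
  keep <- rec$c_count + rec$noc_count + rec$mc_count + rec$hmc_count > 0
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[order(rec$position), , drop = FALSE]
  rownames(rec) <- NULL
  validate_methylation_map(
    new_methylation_map(chromosome, strand, sample_id, rec))
}

# <sample_dir>/<chrom>.<strand>.csv -> metadata; anything else falls back to
# the bare file name as chromosome with forward strand.
parse_map_filename <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(base, ".", fixed = TRUE)[[1L]]
  if (length(parts) >= 2L && parts[length(parts)] %in% c("forward", "reverse")) {
    strand <- parts[length(parts)]
    chrom <- paste(parts[-length(parts)], collapse = ".")
  } else {
    strand <- "forward"
    chrom <- base
  }
  list(chromosome = chrom, strand = strand,
       sample_id = basename(dirname(normalizePath(path, mustWork = FALSE))))
}

#' @export
print.methylation_map <- function(x, ...) {
  cat("<methylation_map> ", x$sample_id, " ", x$chromosome, " (",
      x$strand, "): ", nrow(x$records), " positions\n", sep = "")
  invisible(x)
}
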