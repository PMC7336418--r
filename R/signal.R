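#' Per-position methylation ratio
#'
#' The methylation level at a cytosine is the fraction of informative reads
#' that carry a methylated C:
#' \deqn{mratio_k = \frac{5mC_k}{C_k + 5mC_k}}
#' Reads showing a base other than C are ignored. A position with no
#' informative reads (denominator zero) is assigned ratio 0, matching the
#' zero-filled dense signal construction.
#'
#' @param record A record (list or one-row data.frame) with fields `c_count`
#'   and `mc_count`; vectors are accepted, in which case the computation is
#'   element-wise.
#' @return Numeric ratio(s) in `[0, 1]`.
#' @examples
#' compute_mratio(list(c_count = 2, mc_count = 2))  # 0.5
#' @export
compute_mratio <- function(record) {
  c_count <- record$c_count
  mc <- record$mc_count
  if (any(c_count < 0) || any(mc < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  denom <- c_count + mc
  ifelse(denom == 0, 0, mc / denom)
}

#' Per-position hydroxymethylation ratio
#'
#' \deqn{hmratio_k = \frac{5hmC_k}{C_k + 5hmC_k}}
#' with the same zero-denominator convention as [compute_mratio()]. Because
#' 5mC counts include hydroxymethylated reads, `hmc_count > mc_count` is a
#' validation error.
#'
#' @param record A record with fields `c_count`, `mc_count`, `hmc_count`
#'   (vectors allowed).
#' @return Numeric ratio(s) in `[0, 1]`.
#' @export
compute_hmratio <- function(record) {
  c_count <- record$c_count
  hmc <- record$hmc_count
  if (any(c_count < 0) || any(hmc < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (!is.null(record$mc_count) && any(hmc > record$mc_count)) {
    stop("hmc_count must not exceed mc_count", call. = FALSE)
  }
  denom <- c_count + hmc
  ifelse(denom == 0, 0, hmc / denom)
}

#' Build a dense methylation signal over a genomic interval
#'
#' Allocates one slot per genomic position in `[start, end]` and fills the
#' slots that have a record with the per-position ratio (5mC or 5hmC path)
#' and the informative coverage (`c + mc`, or `c + hmc` for the 5hmC path).
#' Positions without a record are 0-valued with 0 coverage and participate in
#' all downstream averaging; per-sample descriptive statistics later use
#' informative positions only. Reads with a non-C base never contribute.
#'
#' @param map A `methylation_map` (see [read_methylation_csv()]).
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#'   Records outside the interval are excluded.
#' @param analysis_type `"5mC"` or `"5hmC"`.
#' @return A `methylation_signal`: list with `chromosome`, `start`, `end`,
#'   `values` (ratios in `[0,1]`), `coverage` (informative depth),
#'   `analysis_type`, `sample_id`, and the in-interval `records` (kept for
#'   per-sample reporting).
#' @export
build_signal <- function(map, start, end, analysis_type = c("5mC", "5hmC")) {
  analysis_type <- match.arg(analysis_type)
  if (end < start) stop("end must be >= start", call. = FALSE)
  n <- end - start + 1
  values <- numeric(n)
  coverage <- numeric(n)
  rec <- map$records
  rec <- rec[rec$position >= start & rec$position <= end, , drop = FALSE]
  if (nrow(rec)) {
    idx <- rec$position - start + 1
    if (analysis_type == "5mC") {
      values[idx] <- compute_mratio(rec)
      coverage[idx] <- rec$c_count + rec$mc_count
    } else {
      values[idx] <- compute_hmratio(rec)
      coverage[idx] <- rec$c_count + rec$hmc_count
    }
  }
  structure(list(chromosome = map$chromosome, start = start, end = end,
                 values = values, coverage = coverage,
                 analysis_type = analysis_type, sample_id = map$sample_id,
                 records = rec),
            class = "methylation_signal")
}

#' @export
print.methylation_signal <- function(x, ...) {
  cat("<methylation_signal> ", x$sample_id, " ", x$chromosome, ":",
      x$start, "-", x$end, " (", x$analysis_type, "), ",
      sum(x$coverage > 0), "/", length(x$values),
      " informative positions\n", sep = "")
  invisible(x)
}
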