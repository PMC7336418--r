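#' Detection configuration
#'
#' Bundles the user-tunable parameters of the DMR caller. The resolution
#' level is mandatory because the best level is dataset-dependent (one
#' level-`j` window spans `2^j` positions, the minimum callable DMR length).
#'
#' @param level DWT level `j >= 1`.
#' @param dmr_threshold Absolute group-mean difference a window must exceed
#'   (strictly) to be marked, in `(0, 1]`. Default 0.25.
#' @param coverage_threshold Minimum informative reads for a position to
#'   count as covered during validation (`>=` comparison). Default 1.
#' @param min_valid_fraction Fraction of a window's `2^level` positions that
#'   must be covered for a marked window to survive validation, in `(0, 1]`.
#'   Default 0.25.
#' @param analysis_type `"5mC"` or `"5hmC"`.
#' @param filter Wavelet filter name (see [wavelet_filter()]). Default Haar.
#' @param validation_mode How per-position coverage is pooled across samples:
#'   `"all"` (default; a position counts only when every analyzed sample
#'   meets the coverage threshold there) or `"any"`.
#' @return A `detection_config` list.
#' @export
detection_config <- function(level,
                             dmr_threshold = 0.25,
                             coverage_threshold = 1,
                             min_valid_fraction = 0.25,
                             analysis_type = c("5mC", "5hmC"),
                             filter = "haar",
                             validation_mode = c("all", "any")) {
  analysis_type <- match.arg(analysis_type)
  validation_mode <- match.arg(validation_mode)
  if (missing(level)) stop("level must be given explicitly", call. = FALSE)
  if (length(level) != 1L || level < 1 || level != as.integer(level)) {
    stop("level must be a single integer >= 1", call. = FALSE)
  }
  if (dmr_threshold <= 0 || dmr_threshold > 1) {
    stop("dmr_threshold must be in (0, 1]", call. = FALSE)
  }
  if (coverage_threshold < 0) {
    stop("coverage_threshold must be non-negative", call. = FALSE)
  }
  if (min_valid_fraction <= 0 || min_valid_fraction > 1) {
    stop("min_valid_fraction must be in (0, 1]", call. = FALSE)
  }
  filter <- wavelet_filter(filter)$name  # validates the name
  structure(list(level = as.integer(level), dmr_threshold = dmr_threshold,
                 coverage_threshold = coverage_threshold,
                 min_valid_fraction = min_valid_fraction,
                 analysis_type = analysis_type, filter = filter,
                 validation_mode = validation_mode),
            class = "detection_config")
}

#' Element-wise average of a group of transformed signals
#'
#' @param transformed Non-empty list of `transformed_signal` objects sharing
#'   level, normalization and origin interval.
#' @return Numeric array of averaged scaling coefficients.
#' @export
group_average <- function(transformed) {
  if (!length(transformed)) stop("empty group", call. = FALSE)
  ref <- transformed[[1L]]
  for (t in transformed) {
    if (t$level != ref$level || t$normalization != ref$normalization ||
        !identical(t$origin[c("start", "end")], ref$origin[c("start", "end")]) ||
        length(t$scaling) != length(ref$scaling)) {
      stop("group members must share level, normalization and interval",
           call. = FALSE)
    }
  }
  rowMeans(do.call(cbind, lapply(transformed, `[[`, "scaling")))
}

#' Mark differentially methylated windows
#'
#' A window is marked when the absolute difference of the group averages
#' strictly exceeds the threshold.
#'
#' @param avg_case,avg_control Equal-length averaged coefficient arrays.
#' @param dmr_threshold Threshold in `(0, 1]`.
#' @return Logical mask over windows.
#' @export
mark_dm <- function(avg_case, avg_control, dmr_threshold) {
  if (length(avg_case) != length(avg_control)) {
    stop("group averages differ in length", call. = FALSE)
  }
  abs(avg_case - avg_control) > dmr_threshold
}

#' Covered positions required to validate a window
#'
#' A level-`j` window spans `2^j` positions; a marked window survives
#' validation when at least `floor(min_valid_fraction * 2^j)` of them (never
#' fewer than 1) meet the coverage threshold. Floor, not ceiling: a 7%
#' fraction of a 64-position window requires 4 positions.
#'
#' @param level DWT level `>= 1`.
#' @param min_valid_fraction Fraction in `(0, 1]`.
#' @return Integer number of required covered positions.
#' @export
required_covered <- function(level, min_valid_fraction) {
  stopifnot(level >= 1, min_valid_fraction > 0, min_valid_fraction <= 1)
  max(1L, as.integer(floor(min_valid_fraction * 2^level)))
}

#' Coverage validation of marked windows
#'
#' Applied after marking, never by zeroing the signal, so the transformed
#' signal itself is computed from the unfiltered ratios. A position counts as
#' covered when (default pooling) every analyzed sample has coverage
#' `>= coverage_threshold` there; a marked window stays marked only if at
#' least [required_covered()] of its `2^level` positions are covered.
#' Positions beyond the signal end (zero-padding of the last window) are
#' never covered.
#'
#' @param mask Logical mask over level-`j` windows.
#' @param coverages List of per-sample coverage arrays at original (level-0)
#'   resolution, aligned to the signal interval.
#' @param config A [detection_config()].
#' @return Logical mask, a subset of `mask`.
#' @export
validate_coverage <- function(mask, coverages, config) {
  stopifnot(inherits(config, "detection_config"), length(coverages) >= 1)
  n <- length(coverages[[1L]])
  if (any(vapply(coverages, length, 1L) != n)) {
    stop("coverage arrays differ in length", call. = FALSE)
  }
  w <- 2^config$level
  if (length(mask) != ceiling(n / w)) {
    stop("mask length does not match coverage arrays at this level",
         call. = FALSE)
  }
  pass <- vapply(coverages, function(cv) cv >= config$coverage_threshold,
                 logical(n))
  pass <- if (is.null(dim(pass))) matrix(pass, nrow = n) else pass
  pos_ok <- if (config$validation_mode == "all") {
    rowSums(pass) == length(coverages)
  } else {
    rowSums(pass) > 0
  }
  pos_ok_pad <- c(pos_ok, rep(FALSE, length(mask) * w - n))
  per_window <- colSums(matrix(pos_ok_pad, nrow = w))
  mask & per_window >= required_covered(config$level, config$min_valid_fraction)
}

#' Group adjacent marked windows into regions
#'
#' Maximal runs of consecutive marked windows become one region; genomic
#' bounds are the spans of the first and last window of the run (see
#' [coefficient_span()]).
#'
#' @param mask Logical mask over level-`j` windows.
#' @param level DWT level.
#' @param signal_start 1-based coordinate of the signal's first position.
#' @return data.frame with `start`, `end` (genomic, 1-based inclusive),
#'   `first_window`, `last_window` (0-based window indices), `n_windows`.
#' @export
group_adjacent <- function(mask, level, signal_start) {
  if (!length(mask) || !any(mask)) {
    return(data.frame(start = integer(), end = integer(),
                      first_window = integer(), last_window = integer(),
                      n_windows = integer()))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  first_w <- starts[keep] - 1L  # 0-based
  last_w <- ends[keep] - 1L
  w <- 2^level
  data.frame(start = signal_start + first_w * w,
             end = signal_start + (last_w + 1) * w - 1,
             first_window = first_w, last_window = last_w,
             n_windows = last_w - first_w + 1L)
}

#' Direction and mean difference of a region
#'
#' @param windows 0-based indices of the region's windows.
#' @param avg_case,avg_control Averaged coefficient arrays.
#' @return List with `direction` (`"hyper"` if the case group averages
#'   higher, else `"hypo"`) and `mean_difference` (case minus control,
#'   averaged over the region's windows).
#' @export
classify_direction <- function(windows, avg_case, avg_control) {
  if (!length(windows)) stop("empty region", call. = FALSE)
  d <- mean(avg_case[windows + 1L] - avg_control[windows + 1L])
  list(direction = if (d > 0) "hyper" else "hypo", mean_difference = d)
}

#' Per-sample descriptive statistics inside a region
#'
#' Statistics are computed over informative positions only (positions that
#' carry a record); gaps are distances between consecutive informative
#' positions. With fewer than two informative positions the gap statistics
#' are 0; with none, all statistics are 0.
#'
#' @param region Numeric `c(start, end)`, 1-based inclusive.
#' @param map A `methylation_map`.
#' @param analysis_type `"5mC"` (coverage `c + mc`) or `"5hmC"`
#'   (coverage `c + hmc`).
#' @return One-row data.frame with `sample_id`, `n_informative`,
#'   `coverage_min/avg/max`, `reads_c/mc/hmc/noc`, `gap_min/avg/max`.
#' @export
sample_stats <- function(region, map, analysis_type = c("5mC", "5hmC")) {
  analysis_type <- match.arg(analysis_type)
  rec <- map$records
  rec <- rec[rec$position >= region[1L] & rec$position <= region[2L], ,
             drop = FALSE]
  n <- nrow(rec)
  if (n == 0L) {
    return(data.frame(sample_id = map$sample_id, n_informative = 0L,
                      coverage_min = 0, coverage_avg = 0, coverage_max = 0,
                      reads_c = 0, reads_mc = 0, reads_hmc = 0, reads_noc = 0,
                      gap_min = 0, gap_avg = 0, gap_max = 0))
  }
  cov <- if (analysis_type == "5mC") rec$c_count + rec$mc_count
         else rec$c_count + rec$hmc_count
  gaps <- if (n >= 2L) diff(rec$position) else 0
  data.frame(sample_id = map$sample_id, n_informative = n,
             coverage_min = min(cov), coverage_avg = mean(cov),
             coverage_max = max(cov),
             reads_c = sum(rec$c_count), reads_mc = sum(rec$mc_count),
             reads_hmc = sum(rec$hmc_count), reads_noc = sum(rec$noc_count),
             gap_min = min(gaps), gap_avg = mean(gaps), gap_max = max(gaps))
}

#' Closest gene to a region
#'
#' Distance is 0 for any overlap, otherwise the minimal end-to-start gap;
#' ties are broken in favor of the gene with the smaller start.
#'
#' @param region Numeric `c(start, end)`.
#' @param genes data.frame from [read_gene_bed()] (same chromosome).
#' @return List with `gene_name` (NA when no annotation) and `distance`
#'   (NA when no annotation).
#' @export
nearest_gene <- function(region, genes) {
  if (is.null(genes) || nrow(genes) == 0L) {
    return(list(gene_name = NA_character_, distance = NA_real_))
  }
  dist <- ifelse(genes$end < region[1L], region[1L] - genes$end,
                 ifelse(genes$start > region[2L], genes$start - region[2L], 0))
  best <- which(dist == min(dist))
  best <- best[which.min(genes$start[best])]
  list(gene_name = genes$gene_name[best], distance = dist[best])
}

#' Detect differentially methylated regions between two groups
#'
#' The three-stage caller: every signal is transformed to the configured
#' level (mean normalization, so coefficients are on the ratio scale); the
#' two groups are averaged element-wise; windows whose absolute group
#' difference strictly exceeds `dmr_threshold` are marked; marked windows are
#' coverage-validated post hoc; surviving adjacent windows of the same sign
#' are merged into regions (a sign change splits a run, since one region
#' carries one hyper/hypo label); each region is labeled, given per-sample
#' statistics over informative positions, and annotated with its nearest
#' gene. Region bounds are full window spans, so every region length is a
#' multiple of `2^level`.
#'
#' @param case_signals,control_signals Non-empty lists of
#'   `methylation_signal` objects sharing chromosome and interval.
#' @param config A [detection_config()].
#' @param genes Optional gene annotation data.frame (see [read_gene_bed()]).
#' @param chunk_size Optional transform chunking (see [dwt_transform()]).
#' @return A data.frame of regions sorted by `start`, with columns
#'   `chromosome`, `start`, `end`, `direction`, `mean_difference`,
#'   `n_windows`, `closest_gene`, `gene_distance` and a list-column
#'   `per_sample` of per-sample statistics data.frames.
#' @export
detect_dmrs <- function(case_signals, control_signals, config, genes = NULL,
                        chunk_size = NULL) {
  stopifnot(inherits(config, "detection_config"))
  if (!length(case_signals) || !length(control_signals)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  all_signals <- c(case_signals, control_signals)
  ref <- all_signals[[1L]]
  for (s in all_signals) {
    if (!identical(s$chromosome, ref$chromosome) || s$start != ref$start ||
        s$end != ref$end) {
      stop("all signals must share chromosome and interval", call. = FALSE)
    }
    if (!identical(s$analysis_type, config$analysis_type)) {
      stop("signal analysis_type does not match config", call. = FALSE)
    }
  }
  if (!is.null(genes) && nrow(genes)) {
    genes <- genes[genes$chromosome == ref$chromosome, , drop = FALSE]
  }
  filter <- wavelet_filter(config$filter)
  tr <- lapply(all_signals, dwt_transform, filter = filter, level = config$level,
               normalization = "mean", chunk_size = chunk_size)
  n_case <- length(case_signals)
  avg_case <- group_average(tr[seq_len(n_case)])
  avg_control <- group_average(tr[-seq_len(n_case)])
  mask <- mark_dm(avg_case, avg_control, config$dmr_threshold)
  mask <- validate_coverage(mask, lapply(all_signals, `[[`, "coverage"),
                            config)
  diff <- avg_case - avg_control
  regions <- rbind(group_adjacent(mask & diff > 0, config$level, ref$start),
                   group_adjacent(mask & diff < 0, config$level, ref$start))
  regions <- regions[order(regions$start), , drop = FALSE]

  empty <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), direction = character(),
                      mean_difference = numeric(), n_windows = integer(),
                      closest_gene = character(), gene_distance = numeric())
  empty$per_sample <- list()
  if (!nrow(regions)) return(empty)

  rows <- lapply(seq_len(nrow(regions)), function(i) {
    wins <- regions$first_window[i]:regions$last_window[i]
    cls <- classify_direction(wins, avg_case, avg_control)
    ng <- nearest_gene(c(regions$start[i], regions$end[i]), genes)
    stats <- do.call(rbind, lapply(all_signals, function(s) {
      sample_stats(c(regions$start[i], regions$end[i]),
                   list(records = s$records, sample_id = s$sample_id),
                   config$analysis_type)
    }))
    out <- data.frame(chromosome = ref$chromosome, start = regions$start[i],
                      end = regions$end[i], direction = cls$direction,
                      mean_difference = cls$mean_difference,
                      n_windows = regions$n_windows[i],
                      closest_gene = ng$gene_name,
                      gene_distance = ng$distance)
    out$per_sample <- list(stats)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
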