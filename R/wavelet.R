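#' Decomposition filter banks
#'
#' Returns the low-pass (`h`) and high-pass (`g`) decomposition filters of a
#' named wavelet. The Haar pair is
#' \deqn{h = [\sqrt2/2, \sqrt2/2], \quad g = [-\sqrt2/2, \sqrt2/2].}
#' The biorthogonal banks (`bior3.1`, `bior3.3`, `bior3.5`) and the
#' Cohen-Daubechies-Feauveau 2.2 spline bank (`spline2.2`) are the standard
#' published decomposition coefficients, stored as exact multiples of
#' \eqn{\sqrt2}. Detection uses only the approximation (low-pass) path; the
#' alternatives exist for sensitivity analysis of the filter choice.
#'
#' @param name One of `"haar"` (default), `"bior3.1"`, `"bior3.3"`,
#'   `"bior3.5"`, `"spline2.2"`.
#' @return A `wavelet_filter`: list with `name`, `h`, `g`.
#' @export
wavelet_filter <- function(name = c("haar", "bior3.1", "bior3.3", "bior3.5",
                                    "spline2.2")) {
  name <- match.arg(name)
  s2 <- sqrt(2)
  bank <- switch(name,
    haar = list(h = c(s2 / 2, s2 / 2),
                g = c(-s2 / 2, s2 / 2)),
    bior3.1 = list(h = s2 / 4 * c(-1, 3, 3, -1),
                   g = s2 / 8 * c(-1, 3, -3, 1)),
    bior3.3 = list(h = s2 / 64 * c(3, -9, -7, 45, 45, -7, -9, 3),
                   g = s2 / 8 * c(0, 0, -1, 3, -3, 1, 0, 0)),
    bior3.5 = list(h = s2 / 512 * c(-5, 15, 19, -97, -26, 350,
                                    350, -26, -97, 19, 15, -5),
                   g = s2 / 8 * c(0, 0, 0, 0, -1, 3, -3, 1, 0, 0, 0, 0)),
    spline2.2 = list(h = s2 / 8 * c(0, -1, 2, 6, 2, -1),
                     g = s2 / 4 * c(0, 1, -2, 1, 0, 0)))
  structure(list(name = name, h = bank$h, g = bank$g),
            class = "wavelet_filter")
}

as_wavelet_filter <- function(x) {
  if (inherits(x, "wavelet_filter")) x else wavelet_filter(x)
}

#' One dyadic decomposition step
#'
#' Splits a coefficient array into half-length scaling (approximation) and
#' detail arrays:
#' \deqn{c_{j+1}[k] = \sum_m h[m]\, c_j[2k+m], \qquad
#'       d_{j+1}[k] = \sum_m g[m]\, c_j[2k+m]}
#' (0-based `k`, `m`), i.e. a windowed dot product advancing by two, with
#' zero-padding beyond the end of the array. Output length is
#' `ceiling(length(c) / 2)`.
#'
#' @param c Non-empty numeric coefficient array.
#' @param filter A [wavelet_filter()] or its name.
#' @return List with numeric `scaling` and `detail` arrays.
#' @examples
#' dwt_step(c(1, 0), "haar")  # scaling sqrt(2)/2, detail -sqrt(2)/2
#' @export
dwt_step <- function(c, filter = wavelet_filter("haar")) {
  if (!length(c)) stop("empty coefficient array", call. = FALSE)
  filter <- as_wavelet_filter(filter)
  n_out <- ceiling(length(c) / 2)
  L <- length(filter$h)
  cpad <- c(c, numeric(2 * n_out + L - length(c)))
  scaling <- numeric(n_out)
  detail <- numeric(n_out)
  base <- 2 * (seq_len(n_out) - 1)
  for (m in seq_len(L)) {
    cm <- cpad[base + m]
    scaling <- scaling + filter$h[m] * cm
    detail <- detail + filter$g[m] * cm
  }
  list(scaling = scaling, detail = detail)
}

max_dwt_level <- function(n) {
  if (n < 1) stop("empty signal", call. = FALSE)
  as.integer(ceiling(log2(n)))
}

#' Dyadic multiresolution transform of a methylation signal
#'
#' Applies [dwt_step()] `level` times, each step feeding its scaling output
#' into the next, so one level-`j` coefficient summarizes `2^j` consecutive
#' genomic positions. Two normalizations are offered:
#' * `"mean"` (detection default): each step's scaling output is multiplied
#'   by \eqn{2^{-1/2}}, so with the Haar filter level-`j` coefficients are
#'   exactly the block means over `2^j`-position windows and stay on the
#'   `[0, 1]` ratio scale, making one detection threshold comparable across
#'   levels.
#' * `"orthonormal"`: the raw filter bank, preserving squared-coefficient
#'   energy at each step (Haar, even lengths).
#'
#' Level 0 returns the input values unchanged.
#'
#' @param signal A `methylation_signal` (see [build_signal()]) or a bare
#'   numeric vector.
#' @param filter A [wavelet_filter()] or its name.
#' @param level Number of decomposition steps, `>= 0`. Requesting more steps
#'   than needed to reduce the signal to a single coefficient is an error.
#' @param normalization `"mean"` or `"orthonormal"`.
#' @param keep_detail Retain the final step's detail coefficients.
#' @param chunk_size Optional maximum number of level-0 positions transformed
#'   per block; must be a positive multiple of `2^level`. Exact (identical to
#'   whole-signal transform) for filters of support 2 such as Haar.
#' @return A `transformed_signal`: list with `level`, `scaling`, optional
#'   `detail`, `normalization`, `filter`, and `origin` (chromosome, start,
#'   end, sample_id when transforming a `methylation_signal`).
#' @export
dwt_transform <- function(signal, filter = wavelet_filter("haar"), level,
                      normalization = c("mean", "orthonormal"),
                      keep_detail = FALSE, chunk_size = NULL) {
  normalization <- match.arg(normalization)
  filter <- as_wavelet_filter(filter)
  if (inherits(signal, "methylation_signal")) {
    values <- signal$values
    origin <- list(chromosome = signal$chromosome, start = signal$start,
                   end = signal$end, sample_id = signal$sample_id)
  } else {
    values <- as.numeric(signal)
    origin <- list(chromosome = NA_character_, start = 1L,
                   end = length(values), sample_id = NA_character_)
  }
  if (length(level) != 1L || level < 0 || level != as.integer(level)) {
    stop("level must be a single integer >= 0", call. = FALSE)
  }
  level <- as.integer(level)
  n <- length(values)
  if (level > max(max_dwt_level(n), 0L)) {
    stop("level ", level, " reduces a length-", n,
         " signal below one coefficient", call. = FALSE)
  }
  if (!is.null(chunk_size)) {
    if (chunk_size < 2^level || chunk_size %% 2^level != 0) {
      stop("chunk_size must be a positive multiple of 2^level", call. = FALSE)
    }
    if (length(filter$h) > 2L && chunk_size < n) {
      stop("chunked transform is only exact for filters of support 2; ",
           "use chunk_size >= signal length for ", filter$name, call. = FALSE)
    }
  }
  step_scale <- if (normalization == "mean") 2^(-0.5) else 1

  transform_block <- function(x) {
    detail <- NULL
    if (level > 0) {
      for (j in seq_len(level)) {
        st <- dwt_step(x, filter)
        x <- st$scaling * step_scale
        detail <- st$detail * step_scale
      }
    }
    list(scaling = x, detail = detail)
  }

  if (is.null(chunk_size) || chunk_size >= n) {
    res <- transform_block(values)
  } else {
    starts <- seq.int(1L, n, by = chunk_size)
    pieces <- lapply(starts, function(s) {
      transform_block(values[s:min(s + chunk_size - 1L, n)])
    })
    res <- list(scaling = unlist(lapply(pieces, `[[`, "scaling")),
                detail = if (level > 0)
                  unlist(lapply(pieces, `[[`, "detail")) else NULL)
  }
  structure(list(level = level, scaling = res$scaling,
                 detail = if (keep_detail) res$detail else NULL,
                 normalization = normalization, filter = filter$name,
                 origin = origin),
            class = "transformed_signal")
}

#' Genomic span of one scaling coefficient
#'
#' The level-`j` coefficient with (0-based) index `k` summarizes the `2^j`
#' original positions starting at `signal_start + k * 2^j`.
#'
#' @param level Decomposition level `>= 0`.
#' @param index 0-based coefficient index.
#' @param signal_start 1-based genomic coordinate of the signal's first
#'   position.
#' @return Integer vector `c(genomic_start, genomic_end)`, 1-based inclusive.
#' @examples
#' coefficient_span(2, 0, 1001)  # 1001 1004
#' @export
coefficient_span <- function(level, index, signal_start) {
  stopifnot(level >= 0, all(index >= 0))
  w <- 2^level
  start <- signal_start + index * w
  c(start, start + w - 1)
}

#' Export a multiresolution view of a signal
#'
#' One row per scaling coefficient per requested level (mean normalization),
#' with the genomic window each coefficient summarizes — the data behind
#' stacked resolution-level panels.
#'
#' @param signal A `methylation_signal`.
#' @param filter A [wavelet_filter()] or its name.
#' @param levels Ascending integer levels (`0` = raw ratios).
#' @return data.frame with columns `level`, `genomic_start`, `genomic_end`,
#'   `value`.
#' @export
export_multiresolution <- function(signal, filter = wavelet_filter("haar"),
                                   levels = 0:4) {
  stopifnot(!is.unsorted(levels))
  rows <- lapply(levels, function(j) {
    tr <- dwt_transform(signal, filter, level = j, normalization = "mean")
    idx <- seq_along(tr$scaling) - 1
    w <- 2^j
    data.frame(level = j,
               genomic_start = signal$start + idx * w,
               genomic_end = signal$start + (idx + 1) * w - 1,
               value = tr$scaling)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a multiresolution export as TSV
#'
#' @param table Output of [export_multiresolution()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_multiresolution_tsv <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}
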