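#' Batch configuration
#'
#' Describes a batch run over chromosomes. Each case/control directory holds
#' one sample, with one CSV per chromosome and strand named
#' `<chromosome>.<strand>.csv` (e.g. `chr1.forward.csv`).
#'
#' @param case_dirs,control_dirs Character vectors of sample directories
#'   (at least one each).
#' @param detection A [detection_config()].
#' @param output_dir Directory for per-chromosome report CSVs and the run
#'   manifest.
#' @param chromosomes Explicit chromosome names, or `"all"` to use every
#'   chromosome seen in any sample directory.
#' @param strands Subset of `c("forward", "reverse")`; strands are processed
#'   as independent files, never merged.
#' @param dialect A [meth_dialect()] for the input CSVs.
#' @param genes Optional gene annotation data.frame ([read_gene_bed()]).
#' @param chunk_size Maximum positions transformed per block; must be at
#'   least `2^level` (boundaries are aligned to multiples of `2^level`, so
#'   chunking never changes results with the Haar filter). `Inf` disables
#'   chunking.
#' @param workers Maximum concurrent chromosome tasks. Results are
#'   deterministic and identical for any worker count.
#' @return A `batch_config` list.
#' @export
batch_config <- function(case_dirs, control_dirs, detection, output_dir,
                         chromosomes = "all",
                         strands = "forward",
                         dialect = meth_dialect(), genes = NULL,
                         chunk_size = Inf, workers = 1L) {
  stopifnot(inherits(detection, "detection_config"))
  if (!length(case_dirs) || !length(control_dirs)) {
    stop("need at least one case and one control directory", call. = FALSE)
  }
  strands <- match.arg(strands, c("forward", "reverse"), several.ok = TRUE)
  if (is.finite(chunk_size) && chunk_size < 2^detection$level) {
    stop("chunk_size must be >= 2^level", call. = FALSE)
  }
  structure(list(case_dirs = case_dirs, control_dirs = control_dirs,
                 detection = detection, output_dir = output_dir,
                 chromosomes = chromosomes, strands = strands,
                 dialect = dialect, genes = genes,
                 chunk_size = chunk_size, workers = as.integer(workers)),
            class = "batch_config")
}

#' Load a batch configuration from a JSON file
#'
#' The JSON object mirrors [batch_config()]: top-level keys `case_dirs`,
#' `control_dirs`, `output_dir`, optional `chromosomes`, `strands`,
#' `chunk_size`, `workers`, `genes_bed`, and a `detection` object mirroring
#' [detection_config()].
#'
#' @param path Path to a JSON file.
#' @return A `batch_config`.
#' @export
read_batch_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- do.call(detection_config, as.list(cfg$detection))
  args <- cfg[setdiff(names(cfg), c("detection", "genes_bed"))]
  args$detection <- det
  if (!is.null(cfg$genes_bed)) args$genes <- read_gene_bed(cfg$genes_bed)
  do.call(batch_config, args)
}

discover_chromosomes <- function(dirs, strands) {
  found <- character()
  for (d in dirs) {
    files <- list.files(d, pattern = "\\.csv$")
    base <- tools::file_path_sans_ext(files)
    for (s in strands) {
      suf <- paste0(".", s)
      hit <- base[endsWith(base, suf)]
      found <- c(found, substr(hit, 1L, nchar(hit) - nchar(suf)))
    }
  }
  sort(unique(found))
}

map_path <- function(dir, chrom, strand) {
  file.path(dir, paste0(chrom, ".", strand, ".csv"))
}

process_chromosome <- function(chrom, strand, config) {
  all_dirs <- c(config$case_dirs, config$control_dirs)
  paths <- vapply(all_dirs, map_path, "", chrom = chrom, strand = strand)
  if (!all(file.exists(paths))) {
    warning("skipping ", chrom, " (", strand, "): missing map for sample(s) ",
            paste(basename(all_dirs)[!file.exists(paths)], collapse = ", "),
            call. = FALSE)
    return(NULL)
  }
  maps <- lapply(paths, read_methylation_csv, dialect = config$dialect,
                 chromosome = chrom, strand = strand)
  for (i in seq_along(maps)) maps[[i]]$sample_id <- basename(all_dirs[i])
  pos <- unlist(lapply(maps, function(m) m$records$position))
  # no data-bearing positions anywhere: an empty but valid report
  start <- if (length(pos)) min(pos) else 1L
  end <- if (length(pos)) max(pos) else 2^config$detection$level
  signals <- lapply(maps, build_signal, start = start, end = end,
                    analysis_type = config$detection$analysis_type)
  n_case <- length(config$case_dirs)
  chunk <- if (is.finite(config$chunk_size)) config$chunk_size else NULL
  if (!is.null(chunk) &&
      length(wavelet_filter(config$detection$filter)$h) > 2L) {
    message("chunking disabled for filter ", config$detection$filter,
            " (exact only for support-2 filters)")
    chunk <- NULL
  }
  detect_dmrs(signals[seq_len(n_case)], signals[-seq_len(n_case)],
              config$detection, genes = config$genes, chunk_size = chunk)
}

#' Run batch DMR detection over chromosomes
#'
#' For each selected chromosome and strand: reads one map per sample, builds
#' signals over the union interval of all samples, transforms them in
#' `2^level`-aligned chunks, detects DMRs, and writes one report CSV named
#' `<chromosome>_<strand>_<analysis>.csv` into the output directory, plus a
#' `manifest.json` recording the configuration, per-chromosome DMR counts and
#' wall time. A chromosome whose map is missing in any sample is skipped with
#' a warning; if every selected chromosome fails, the run errors. Report
#' files are byte-identical for any `workers` and any aligned `chunk_size`.
#'
#' @param config A [batch_config()].
#' @return Invisibly, the manifest list.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  t0 <- Sys.time()
  chroms <- config$chromosomes
  if (identical(chroms, "all")) {
    chroms <- discover_chromosomes(c(config$case_dirs, config$control_dirs),
                                   config$strands)
  }
  if (!length(chroms)) stop("no chromosomes selected", call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tasks <- expand.grid(chrom = chroms, strand = config$strands,
                       stringsAsFactors = FALSE)
  worker <- function(i) {
    warns <- character()
    regions <- withCallingHandlers(
      tryCatch(process_chromosome(tasks$chrom[i], tasks$strand[i], config),
               error = function(e) {
                 warns <<- c(warns, conditionMessage(e))
                 NULL
               }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(regions = regions, warnings = warns)
  }
  results <- if (config$workers > 1L) {
    parallel::mclapply(seq_len(nrow(tasks)), worker,
                       mc.cores = config$workers)
  } else {
    lapply(seq_len(nrow(tasks)), worker)
  }
  counts <- list()
  n_ok <- 0L
  for (i in seq_len(nrow(tasks))) {
    res <- results[[i]]
    label <- paste0(tasks$chrom[i], "_", tasks$strand[i])
    for (w in res$warnings) warning(w, call. = FALSE)
    regions <- res$regions
    if (is.null(regions)) {
      counts[[label]] <- NA_integer_
      next
    }
    n_ok <- n_ok + 1L
    out <- file.path(config$output_dir,
                     paste0(label, "_", config$detection$analysis_type,
                            ".csv"))
    write_dmr_csv(regions, out)
    counts[[label]] <- nrow(regions)
    message(label, ": ", nrow(regions), " DMRs -> ", out)
  }
  if (n_ok == 0L) stop("all selected chromosomes failed", call. = FALSE)
  manifest <- list(
    detection = unclass(config$detection),
    case_dirs = config$case_dirs, control_dirs = config$control_dirs,
    chromosomes = chroms, strands = config$strands,
    chunk_size = if (is.finite(config$chunk_size)) config$chunk_size else
      "none",
    workers = config$workers,
    dmr_counts = counts,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
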