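#' Simulation parameters
#'
#' The generator emulates one chromosome segment of per-position bisulfite
#' read counts with planted differentially methylated regions. Methylated
#' read counts follow a beta-binomial: at a data-bearing position with true
#' proportion \eqn{\pi} and read depth \eqn{n \sim \mathrm{Poisson}(\mu)},
#' the methylated count is \eqn{\mathrm{Binomial}(n, p)} with
#' \eqn{p \sim \mathrm{Beta}(\pi(1/\rho - 1), (1-\pi)(1/\rho - 1))}; the
#' dispersion \eqn{\rho \in [0, 1)} degenerates to a plain binomial at 0.
#'
#' Defaults state a realistic desk-scale world: most positions data-bearing
#' (`cpg_density` 0.9, emulating a consecutive-CpG coordinate frame with
#' dropout), lowly methylated background (0.1), planted effect +0.4,
#' mean depth 50, moderate overdispersion 0.1, planted lengths 64-256,
#' two samples per group.
#'
#' @param n_positions Segment length in positions.
#' @param cpg_density Probability a position carries data.
#' @param base_methylation Mean control methylation proportion.
#' @param effect_size Signed proportion difference (case minus control)
#'   inside planted regions; `base + effect` must stay in `[0, 1]`.
#' @param dmr_lengths Length-2 vector: min and max planted region length.
#' @param n_dmrs Number of planted regions (disjoint, non-adjacent).
#' @param coverage_mean Mean read depth per data-bearing position.
#' @param overdispersion Beta-binomial dispersion `rho` in `[0, 1)`.
#' @param n_case,n_control Samples per group.
#' @param hmc_fraction Fraction of methylated reads reported as
#'   hydroxymethylated (exercises the 5hmC path). Default 0.
#' @param noc_rate Expected non-C reads per position (ignored by detection).
#' @param chromosome Chromosome name written into the fixtures.
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_positions = 20000L, cpg_density = 0.9,
                              base_methylation = 0.1, effect_size = 0.4,
                              dmr_lengths = c(64L, 256L), n_dmrs = 10L,
                              coverage_mean = 50, overdispersion = 0.1,
                              n_case = 2L, n_control = 2L,
                              hmc_fraction = 0, noc_rate = 0.5,
                              chromosome = "chrS", seed = 1L) {
  if (base_methylation < 0 || base_methylation > 1 ||
      base_methylation + effect_size < 0 ||
      base_methylation + effect_size > 1) {
    stop("base_methylation and base_methylation + effect_size must lie ",
         "in [0, 1]", call. = FALSE)
  }
  if (coverage_mean <= 0) stop("coverage_mean must be > 0", call. = FALSE)
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("overdispersion must be in [0, 1)", call. = FALSE)
  }
  if (cpg_density <= 0 || cpg_density > 1) {
    stop("cpg_density must be in (0, 1]", call. = FALSE)
  }
  stopifnot(length(dmr_lengths) == 2L, dmr_lengths[1L] <= dmr_lengths[2L],
            n_dmrs >= 0, n_case >= 1, n_control >= 1,
            hmc_fraction >= 0, hmc_fraction <= 1)
  structure(list(n_positions = as.integer(n_positions),
                 cpg_density = cpg_density,
                 base_methylation = base_methylation,
                 effect_size = effect_size,
                 dmr_lengths = as.integer(dmr_lengths),
                 n_dmrs = as.integer(n_dmrs),
                 coverage_mean = coverage_mean,
                 overdispersion = overdispersion,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 hmc_fraction = hmc_fraction, noc_rate = noc_rate,
                 chromosome = chromosome, seed = as.integer(seed)),
            class = "simulation_params")
}

rbetabinom <- function(n_draws, size, prob, rho) {
  if (rho == 0) return(stats::rbinom(n_draws, size, prob))
  shape <- 1 / rho - 1
  p <- stats::rbeta(n_draws, prob * shape, (1 - prob) * shape)
  stats::rbinom(n_draws, size, p)
}

plant_regions <- function(params) {
  if (params$n_dmrs == 0L) {
    return(data.frame(start = integer(), end = integer(), effect = numeric()))
  }
  gap <- 50L  # keep planted regions clearly separated
  lens <- sample(seq.int(params$dmr_lengths[1L], params$dmr_lengths[2L]),
                 params$n_dmrs, replace = TRUE)
  need <- sum(lens) + gap * (params$n_dmrs + 1L)
  if (need > params$n_positions) {
    stop("segment too short for ", params$n_dmrs, " planted regions",
         call. = FALSE)
  }
  # spread the remaining slack over the inter-region gaps
  slack <- params$n_positions - need
  cuts <- sort(sample.int(slack + 1L, params$n_dmrs, replace = TRUE) - 1L)
  extra <- diff(c(0L, cuts))
  starts <- integer(params$n_dmrs)
  cursor <- 1L
  for (i in seq_len(params$n_dmrs)) {
    cursor <- cursor + gap + extra[i]
    starts[i] <- cursor
    cursor <- cursor + lens[i]
  }
  data.frame(start = starts, end = starts + lens - 1L,
             effect = rep(params$effect_size, params$n_dmrs))
}

#' Generate a synthetic methylation dataset with planted DMRs
#'
#' Writes one map CSV per sample in the default [meth_dialect()] under
#' per-sample directories (`case_1/ ... control_1/ ...`, each holding
#' `<chromosome>.forward.csv`, the batch layout), plus a BED-like truth TSV.
#' Identical seeds produce byte-identical files.
#'
#' @param params A [simulation_params()].
#' @param dir Output directory (created if needed).
#' @return A list: `truth` (a `truth_set`: `regions` data.frame with
#'   `start`, `end`, `effect`; `positions` data.frame with `position`,
#'   `p_case`, `p_control`), `case_dirs`, `control_dirs`, `case_files`,
#'   `control_files`, `truth_file`.
#' @export
generate_dataset <- function(params, dir = tempfile("dmrsim")) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  regions <- plant_regions(params)
  sites <- which(stats::runif(params$n_positions) < params$cpg_density)
  in_dmr <- rep(FALSE, params$n_positions)
  for (i in seq_len(nrow(regions))) {
    in_dmr[regions$start[i]:regions$end[i]] <- TRUE
  }
  p_control <- rep(params$base_methylation, length(sites))
  p_case <- p_control + ifelse(in_dmr[sites], params$effect_size, 0)
  positions <- data.frame(position = sites, p_case = p_case,
                          p_control = p_control)

  write_sample <- function(subdir, p_true) {
    depth <- stats::rpois(length(sites), params$coverage_mean)
    mc <- rbetabinom(length(sites), depth, p_true, params$overdispersion)
    hmc <- if (params$hmc_fraction > 0) {
      stats::rbinom(length(sites), mc, params$hmc_fraction)
    } else {
      integer(length(sites))
    }
    noc <- stats::rpois(length(sites), params$noc_rate)
    rec <- data.frame(pos = sites, c = depth - mc, noc = noc, mc = mc,
                      hmc = hmc)
    rec <- rec[rec$c + rec$noc + rec$mc + rec$hmc > 0, , drop = FALSE]
    d <- file.path(dir, subdir)
    dir.create(d, showWarnings = FALSE)
    path <- file.path(d, paste0(params$chromosome, ".forward.csv"))
    data.table::fwrite(rec, path)
    path
  }
  case_files <- vapply(seq_len(params$n_case), function(i) {
    write_sample(paste0("case_", i), p_case)
  }, "")
  control_files <- vapply(seq_len(params$n_control), function(i) {
    write_sample(paste0("control_", i), p_control)
  }, "")

  truth_file <- file.path(dir, "truth.tsv")
  truth_bed <- data.frame(chrom = rep(params$chromosome, nrow(regions)),
                          start = regions$start, end = regions$end,
                          effect = regions$effect)
  data.table::fwrite(truth_bed, truth_file, sep = "\t")

  truth <- structure(list(regions = regions, positions = positions,
                          chromosome = params$chromosome),
                     class = "truth_set")
  list(truth = truth,
       case_dirs = dirname(case_files), control_dirs = dirname(control_files),
       case_files = case_files, control_files = control_files,
       truth_file = truth_file)
}

#' Score detected regions against the planted truth
#'
#' A found region is a true positive iff it covers at least one truly
#' differentially methylated position (a data-bearing position inside a
#' planted region with a non-zero effect). The hit rate is the number of
#' true-positive regions over the number of regions found (0 when nothing
#' was found); `precision` is the same region-level quantity. Sensitivity is
#' the fraction of truly differentially methylated positions covered by any
#' found region.
#'
#' @param found Region data.frame from [detect_dmrs()] (or any data.frame
#'   with `start` and `end`).
#' @param truth A `truth_set` from [generate_dataset()].
#' @return List with `sensitivity`, `precision`, `hit_rate`, `n_found`,
#'   `n_true_positive`.
#' @export
evaluate_detection <- function(found, truth) {
  stopifnot(inherits(truth, "truth_set"))
  dm_pos <- truth$positions$position[truth$positions$p_case !=
                                       truth$positions$p_control]
  n_found <- nrow(found)
  if (n_found == 0L) {
    return(list(sensitivity = 0, precision = 0, hit_rate = 0,
                n_found = 0L, n_true_positive = 0L))
  }
  covered <- rep(FALSE, length(dm_pos))
  tp <- logical(n_found)
  for (i in seq_len(n_found)) {
    inside <- dm_pos >= found$start[i] & dm_pos <= found$end[i]
    tp[i] <- any(inside)
    covered <- covered | inside
  }
  hit <- sum(tp) / n_found
  list(sensitivity = if (length(dm_pos)) mean(covered) else 0,
       precision = hit, hit_rate = hit,
       n_found = n_found, n_true_positive = sum(tp))
}
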