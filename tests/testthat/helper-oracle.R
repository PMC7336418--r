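# Independent brute-force oracles. These deliberately avoid the package's
# wavelet path: block means are computed directly from the raw ratio arrays,
# and region grouping is a sequential scan rather than run-length encoding.

# mean of each 2^level-position window, zero-padded at the end
oracle_block_means <- function(values, level) {
  w <- 2^level
  npad <- ceiling(length(values) / w) * w
  values <- c(values, numeric(npad - length(values)))
  colSums(matrix(values, nrow = w)) / w
}

# direct reimplementation of the three-stage caller on raw arrays
oracle_detect <- function(case_values, control_values, coverages, config,
                          signal_start = 1) {
  w <- 2^config$level
  avg_case <- rowMeans(sapply(case_values, oracle_block_means,
                              level = config$level))
  avg_control <- rowMeans(sapply(control_values, oracle_block_means,
                                 level = config$level))
  d <- avg_case - avg_control
  marked <- abs(d) > config$dmr_threshold

  n <- length(coverages[[1]])
  hits <- lapply(coverages, function(cv) cv >= config$coverage_threshold)
  pos_ok <- if (config$validation_mode == "all") Reduce(`&`, hits)
            else Reduce(`|`, hits)
  need <- max(1, floor(config$min_valid_fraction * w))
  n_win <- length(d)
  valid <- logical(n_win)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1) * w + 1):min(k * w, n)
    valid[k] <- sum(pos_ok[idx]) >= need
  }
  keep <- marked & valid

  # sequential scan with sign-change splitting
  out <- list()
  open <- FALSE
  first <- NA
  for (k in seq_len(n_win + 1)) {
    cur_sign <- if (k <= n_win && keep[k]) sign(d[k]) else 0
    if (open && (cur_sign == 0 || cur_sign != sign(d[first]))) {
      last <- k - 1
      out[[length(out) + 1]] <- data.frame(
        start = signal_start + (first - 1) * w,
        end = signal_start + last * w - 1,
        direction = if (d[first] > 0) "hyper" else "hypo",
        mean_difference = mean(d[first:last]))
      open <- FALSE
    }
    if (!open && cur_sign != 0) {
      open <- TRUE
      first <- k
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      direction = character(), mean_difference = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# run both callers on the same randomly built instance and compare
expect_oracle_agreement <- function(seed, n_max = 4096, level_max = 6) {
  set.seed(seed)
  n <- sample.int(n_max - 64, 1) + 64
  level <- sample.int(level_max, 1)
  n_case <- sample.int(3, 1)
  n_control <- sample.int(3, 1)
  mk_signal <- function(id) {
    vals <- numeric(n)
    cov <- numeric(n)
    sites <- which(runif(n) < 0.6)
    vals[sites] <- runif(length(sites))
    cov[sites] <- rpois(length(sites), 20)
    structure(list(chromosome = "chrX", start = 1, end = n, values = vals,
                   coverage = cov, analysis_type = "5mC", sample_id = id,
                   records = make_records(integer())),
              class = "methylation_signal")
  }
  cases <- lapply(paste0("case", seq_len(n_case)), mk_signal)
  controls <- lapply(paste0("ctl", seq_len(n_control)), mk_signal)
  config <- detection_config(level = level,
                             dmr_threshold = runif(1, 0.05, 0.4),
                             coverage_threshold = sample.int(30, 1),
                             min_valid_fraction = runif(1, 0.05, 1))
  got <- detect_dmrs(cases, controls, config)
  want <- oracle_detect(lapply(cases, `[[`, "values"),
                        lapply(controls, `[[`, "values"),
                        lapply(c(cases, controls), `[[`, "coverage"),
                        config)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$direction, want$direction)
  expect_equal(got$mean_difference, want$mean_difference, tolerance = 1e-9)
  invisible(nrow(got))
}
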