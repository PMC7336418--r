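cfg4 <- detection_config(level = 4, dmr_threshold = 0.25)

test_that("detection_config validates its ranges and demands a level", {
  expect_error(detection_config(), "level")
  expect_error(detection_config(level = 0), "integer >= 1")
  expect_error(detection_config(level = 2, dmr_threshold = 0), "\\(0, 1\\]")
  expect_error(detection_config(level = 2, min_valid_fraction = 1.2),
               "\\(0, 1\\]")
  expect_equal(detection_config(level = 3)$dmr_threshold, 0.25)  # default
})

test_that("group averaging is an element-wise mean with guarded inputs", {
  t1 <- dwt_transform(c(0.2, 0.2, 0.2, 0.2), level = 1)
  t2 <- dwt_transform(c(0.8, 0.8, 0.8, 0.8), level = 1)
  expect_equal(group_average(list(t1, t2)), c(0.5, 0.5))
  expect_equal(group_average(list(t1)), t1$scaling)       # group of one
  expect_equal(group_average(list(t2, t2)), t2$scaling)   # idempotent mean
  expect_error(group_average(list()), "empty")
  t3 <- dwt_transform(c(0.8, 0.8, 0.8, 0.8), level = 2)
  expect_error(group_average(list(t1, t3)), "share level")
})

test_that("marking uses a strict threshold on absolute differences", {
  expect_true(mark_dm(0.8, 0.2, 0.5))
  expect_false(mark_dm(0.7, 0.2, 0.5))   # exactly equal: not marked
  expect_equal(mark_dm(c(0.5, 0.5), c(0.5, 0.5), 0.01), c(FALSE, FALSE))
  expect_error(mark_dm(1:3 / 10, 1:2 / 10, 0.1), "length")
})

test_that("required covered positions floor the fraction with a minimum of 1", {
  expect_equal(required_covered(2, 0.25), 1L)
  expect_equal(required_covered(6, 0.07), 4L)   # floor(4.48)
  expect_equal(required_covered(1, 0.25), 1L)   # floor(0.5) clamped
  expect_equal(required_covered(6, 0.25), 16L)
})

test_that("coverage validation keeps marked windows with enough covered positions", {
  cfg <- detection_config(level = 2, dmr_threshold = 0.1,
                          coverage_threshold = 50)
  cov <- c(60, 0, 0, 0)  # one of four positions covered in every sample
  expect_equal(validate_coverage(TRUE, list(cov, cov), cfg), TRUE)
  expect_equal(validate_coverage(TRUE, list(numeric(4)), cfg), FALSE)
  # pooling: a position counts only when all samples reach the threshold
  expect_equal(validate_coverage(TRUE, list(cov, numeric(4)), cfg), FALSE)
  cfg_any <- detection_config(level = 2, dmr_threshold = 0.1,
                              coverage_threshold = 50,
                              validation_mode = "any")
  expect_equal(validate_coverage(TRUE, list(cov, numeric(4)), cfg_any), TRUE)
  expect_error(validate_coverage(c(TRUE, TRUE), list(cov), cfg), "mask length")

  # relaxing the coverage threshold retains at least as many windows
  set.seed(21)
  for (i in 1:10) {
    covs <- replicate(3, rpois(64, 20), simplify = FALSE)
    mask <- runif(4) < 0.8
    kept <- sapply(c(1, 10, 50), function(thr) {
      c2 <- detection_config(level = 4, dmr_threshold = 0.1,
                             coverage_threshold = thr)
      sum(validate_coverage(mask, covs, c2))
    })
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("adjacent marked windows group into window-aligned regions", {
  got <- group_adjacent(c(TRUE, TRUE, FALSE, TRUE), 2, 1001)
  expect_equal(got$start, c(1001, 1013))
  expect_equal(got$end, c(1008, 1016))
  expect_equal(got$n_windows, c(2L, 1L))
  expect_equal(nrow(group_adjacent(logical(5), 2, 1)), 0L)
  all_true <- group_adjacent(rep(TRUE, 6), 3, 1)
  expect_equal(all_true$end - all_true$start + 1, 6 * 8)
})

test_that("direction is the sign of the windowed mean difference", {
  expect_equal(classify_direction(0, 0.9, 0.2),
               list(direction = "hyper", mean_difference = 0.7))
  expect_equal(classify_direction(0, 0.1, 0.8),
               list(direction = "hypo", mean_difference = -0.7))
  got <- classify_direction(c(0, 1), c(0.8, 0.6), c(0.2, 0.2))
  expect_equal(got$direction, "hyper")
  expect_equal(got$mean_difference, 0.5)
})

test_that("per-sample statistics cover informative positions only", {
  map <- make_map(rbind(make_records(10, c_count = 2, mc_count = 2),
                        make_records(14, c_count = 6, mc_count = 4)))
  st <- sample_stats(c(8, 16), map)
  expect_equal(st$n_informative, 2L)
  expect_equal(c(st$coverage_min, st$coverage_avg, st$coverage_max),
               c(4, 7, 10))
  expect_equal(st$reads_c, 8)
  expect_equal(st$reads_mc, 6)
  expect_equal(c(st$gap_min, st$gap_avg, st$gap_max), c(4, 4, 4))

  none <- sample_stats(c(100, 120), map)
  expect_equal(none$n_informative, 0L)
  expect_equal(none$coverage_max, 0)

  single <- sample_stats(c(8, 12), map)  # one record: degenerate gaps
  expect_equal(single$n_informative, 1L)
  expect_equal(c(single$gap_min, single$gap_avg, single$gap_max), c(0, 0, 0))
})

test_that("nearest gene reporting handles overlap, gaps and ties", {
  genes <- data.frame(gene_name = c("A", "B"), chromosome = "chr1",
                      start = c(100, 600), end = c(200, 700))
  expect_equal(nearest_gene(c(150, 160), genes),
               list(gene_name = "A", distance = 0))
  expect_equal(nearest_gene(c(300, 310), genes),
               list(gene_name = "A", distance = 100))  # 100 bp downstream of A
  expect_equal(nearest_gene(c(400, 400), genes),
               list(gene_name = "A", distance = 200))  # tie -> smaller start
  expect_equal(nearest_gene(c(1, 2), genes[0, ])$gene_name, NA_character_)
})

test_that("detect_dmrs composes the stages end to end", {
  # identical groups: nothing to call
  m <- planted_map(64, 17:32, 0.5, 0.5)
  s <- build_signal(m, 1, 64, "5mC")
  expect_equal(nrow(detect_dmrs(list(s), list(s), cfg4)), 0L)

  # a planted window-aligned block at full coverage: exactly one hyper DMR
  mc <- planted_map(64, 17:32, 0.5, 1, sample_id = "case")
  m0 <- planted_map(64, 17:32, 0.5, 0, sample_id = "ctl")
  sc <- build_signal(mc, 1, 64, "5mC")
  s0 <- build_signal(m0, 1, 64, "5mC")
  got <- detect_dmrs(list(sc), list(s0), cfg4)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$start, got$end), c(17, 32))
  expect_equal(got$direction, "hyper")
  expect_equal(got$mean_difference, 1)
  expect_equal(got$end - got$start + 1, got$n_windows * 2^cfg4$level)
  expect_equal(nrow(got$per_sample[[1]]), 2)

  # genes annotate; mismatched intervals are rejected
  genes <- data.frame(gene_name = "G", chromosome = "chr1",
                      start = 40, end = 60)
  expect_equal(detect_dmrs(list(sc), list(s0), cfg4, genes)$closest_gene, "G")
  short <- build_signal(m0, 1, 32, "5mC")
  expect_error(detect_dmrs(list(sc), list(short), cfg4), "share")
  expect_error(detect_dmrs(list(), list(s0), cfg4), "non-empty")
})

test_that("swapping groups flips directions and negates differences", {
  set.seed(31)
  for (i in 1:10) {
    n <- 512
    mk <- function(id) {
      m <- random_map(n, density = 0.7, sample_id = id)
      build_signal(m, 1, n, "5mC")
    }
    a <- list(mk("a1"), mk("a2"))
    b <- list(mk("b1"), mk("b2"))
    cfg <- detection_config(level = 3, dmr_threshold = 0.15)
    ab <- detect_dmrs(a, b, cfg)
    ba <- detect_dmrs(b, a, cfg)
    expect_equal(ab$start, ba$start)
    expect_equal(ab$end, ba$end)
    expect_equal(ab$mean_difference, -ba$mean_difference)
    expect_equal(ab$direction == "hyper", ba$direction == "hypo")
    expect_true(all(ab$end - ab$start + 1 >= 2^cfg$level))
  }
})

test_that("the DWT path agrees with the brute-force block-mean caller", {
  for (seed in 1:40) expect_oracle_agreement(seed, n_max = 1024, level_max = 6)
})

test_that("DMR count is monotone in both thresholds", {
  set.seed(33)
  sim <- generate_dataset(simulation_params(n_positions = 8000, n_dmrs = 6,
                                            seed = 33))
  maps <- lapply(c(sim$case_files, sim$control_files), read_methylation_csv)
  pos <- unlist(lapply(maps, function(m) m$records$position))
  sigs <- lapply(maps, build_signal, start = min(pos), end = max(pos),
                 analysis_type = "5mC")
  case <- sigs[1:2]
  ctl <- sigs[3:4]
  dm_windows <- function(thr, cov) {
    sum(detect_dmrs(case, ctl, detection_config(
      level = 4, dmr_threshold = thr, coverage_threshold = cov))$n_windows)
  }
  by_thr <- sapply(seq(0.05, 0.5, by = 0.05), dm_windows, cov = 1)
  expect_true(all(diff(by_thr) <= 0))
  by_cov <- sapply(c(1, 10, 25, 40, 50), dm_windows, thr = 0.2)
  expect_true(all(diff(by_cov) <= 0))
})
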