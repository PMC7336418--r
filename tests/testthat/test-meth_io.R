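test_that("methylation CSV rows parse into validated, position-sorted maps", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("pos,c,noc,mc,hmc", "20,1,0,3,1", "10,2,0,2,0"), path)
  map <- read_methylation_csv(path, sample_id = "s1", chromosome = "chr1")
  expect_s3_class(map, "methylation_map")
  expect_equal(map$records$position, c(10, 20))  # sorted on load
  expect_equal(unlist(map$records[1, ]),
               c(position = 10, c_count = 2, noc_count = 0, mc_count = 2,
                 hmc_count = 0))
  # purity: reading twice yields identical maps
  expect_identical(map, read_methylation_csv(path, sample_id = "s1",
                                             chromosome = "chr1"))
})

test_that("header-only files give empty maps and all-zero rows are dropped", {
  path <- tempfile(fileext = ".csv")
  writeLines("pos,c,noc,mc,hmc", path)
  expect_equal(nrow(read_methylation_csv(path)$records), 0L)

  writeLines(c("pos,c,noc,mc,hmc", "5,0,0,0,0", "7,1,0,1,0"), path)
  map <- read_methylation_csv(path)
  expect_equal(map$records$position, 7)
})

test_that("invalid rows are rejected with the offending line number", {
  write_rows <- function(...) {
    p <- tempfile(fileext = ".csv")
    writeLines(c("pos,c,noc,mc,hmc", ...), p)
    p
  }
  expect_error(read_methylation_csv(write_rows("10,2,0,2,0", "11,x,0,1,0")),
               "line 3")
  expect_error(read_methylation_csv(write_rows("10,2,0,1,2")),
               "hmc_count exceeds mc_count")
  expect_error(read_methylation_csv(write_rows("10,-1,0,1,0")), "line 2")
  expect_error(read_methylation_csv(write_rows("10,2,0,2,0", "10,1,0,1,0")),
               "duplicate position 10")
  expect_error(read_methylation_csv(tempfile()), "no such file")
})

test_that("the dialect maps arbitrary column layouts", {
  # reordered named columns
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("mC;hmC;position;C;noC", "4;1;100;6;2"), p1)
  d1 <- meth_dialect(columns = c(position = "position", c_count = "C",
                                 noc_count = "noC", mc_count = "mC",
                                 hmc_count = "hmC"), delim = ";")
  map <- read_methylation_csv(p1, d1)
  expect_equal(map$records$mc_count, 4)
  expect_equal(map$records$noc_count, 2)

  # headerless file addressed by index
  p2 <- tempfile(fileext = ".csv")
  writeLines("7,3,0,2,1", p2)
  d2 <- meth_dialect(columns = c(position = 1, c_count = 2, noc_count = 3,
                                 mc_count = 4, hmc_count = 5), header = FALSE)
  expect_equal(read_methylation_csv(p2, d2)$records$hmc_count, 1)

  # unknown column name is a config error
  expect_error(
    read_methylation_csv(p1, meth_dialect(
      columns = c(position = "position", c_count = "C", noc_count = "noC",
                  mc_count = "nope", hmc_count = "hmC"), delim = ";")),
    "absent")
  expect_error(meth_dialect(columns = c(position = "pos")), "must map")
})

test_that("BED gene annotations convert to 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tNBPF1",
               "chr1\t150\t300\tAKT3",
               "chr1\t10\t50\tKMT2C"), bed)
  genes <- read_gene_bed(bed)
  expect_equal(genes$gene_name, c("KMT2C", "NBPF1", "AKT3"))  # start-sorted
  expect_equal(genes$start[genes$gene_name == "NBPF1"], 100)
  expect_equal(genes$end[genes$gene_name == "NBPF1"], 200)
  expect_equal(nrow(genes), 3)  # overlapping genes both retained

  empty <- tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_gene_bed(empty)), 0L)
})

test_that("DMR report round-trips and keeps the two-level layout", {
  stats <- rbind(
    data.frame(sample_id = "case_1", n_informative = 12L, coverage_min = 4,
               coverage_avg = 7.25, coverage_max = 11, reads_c = 40,
               reads_mc = 47, reads_hmc = 3, reads_noc = 1, gap_min = 1,
               gap_avg = 1.3636363636363635, gap_max = 3),
    data.frame(sample_id = "ctl_1", n_informative = 0L, coverage_min = 0,
               coverage_avg = 0, coverage_max = 0, reads_c = 0, reads_mc = 0,
               reads_hmc = 0, reads_noc = 0, gap_min = 0, gap_avg = 0,
               gap_max = 0))
  regions <- data.frame(chromosome = "chr1", start = 1001L, end = 1016L,
                        direction = "hyper",
                        mean_difference = 0.4125678901234567,
                        n_windows = 1L, closest_gene = "NBPF1",
                        gene_distance = 84)
  regions$per_sample <- list(stats)
  regions <- rbind(regions, within(regions, {
    start <- 2001L; end <- 2032L; direction <- "hypo"
    mean_difference <- -0.3; n_windows <- 2L
    closest_gene <- NA_character_; gene_distance <- NA_real_
  }))

  path <- tempfile(fileext = ".csv")
  write_dmr_csv(regions, path)
  lines <- readLines(path)
  data <- lines[!startsWith(lines, "#")]
  expect_equal(sum(startsWith(data, "DMR")), 2)     # one header line per DMR
  expect_equal(sum(startsWith(data, "SAMPLE")), 4)  # one line per sample

  back <- read_dmr_csv(path)
  expect_equal(back$start, regions$start)
  expect_equal(back$direction, regions$direction)
  expect_equal(back$closest_gene, regions$closest_gene)
  expect_equal(back$mean_difference, regions$mean_difference)
  expect_equal(back$per_sample[[1]], regions$per_sample[[1]])

  # empty list -> comment-only file
  empty <- regions[0, ]
  empty$per_sample <- list()
  write_dmr_csv(empty, path)
  expect_true(all(startsWith(readLines(path), "#")))
  expect_equal(nrow(read_dmr_csv(path)), 0L)

  # one chromosome per file
  bad <- regions
  bad$chromosome <- c("chr1", "chr2")
  expect_error(write_dmr_csv(bad, path), "one chromosome")
})

test_that("fuzzed CSVs always load into maps satisfying the invariants", {
  set.seed(71)
  for (i in 1:25) {
    map <- random_map(n = 300, density = runif(1, 0.05, 0.9))
    path <- write_map_csv(map)
    got <- read_methylation_csv(path)
    expect_silent(validate_methylation_map(got))
    r <- got$records
    expect_false(is.unsorted(r$position, strictly = TRUE))
    expect_true(all(r$hmc_count <= r$mc_count))
    expect_true(all(as.matrix(r) >= 0))
  }
})
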