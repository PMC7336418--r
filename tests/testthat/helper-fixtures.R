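# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

make_records <- function(position, c_count = 0, noc_count = 0, mc_count = 0,
                         hmc_count = 0) {
  n <- length(position)
  data.frame(position = position,
             c_count = rep_len(c_count, n), noc_count = rep_len(noc_count, n),
             mc_count = rep_len(mc_count, n), hmc_count = rep_len(hmc_count, n))
}

make_map <- function(records, chromosome = "chr1", strand = "forward",
                     sample_id = "s1") {
  records <- records[order(records$position), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(chromosome = chromosome, strand = strand,
                 sample_id = sample_id, records = records),
            class = "methylation_map")
}

# random sparse map over [1, n]; counts keep hmc <= mc
random_map <- function(n = 200, density = 0.5, max_depth = 30,
                       sample_id = "s1") {
  pos <- which(runif(n) < density)
  if (!length(pos)) pos <- sample.int(n, 1)
  depth <- rpois(length(pos), max_depth / 2) + 1L
  mc <- rbinom(length(pos), depth, runif(1))
  hmc <- rbinom(length(pos), mc, 0.3)
  noc <- rpois(length(pos), 0.3)
  make_map(make_records(pos, c_count = depth - mc, noc_count = noc,
                        mc_count = mc, hmc_count = hmc),
           sample_id = sample_id)
}

write_map_csv <- function(map, path = tempfile(fileext = ".csv")) {
  df <- map$records
  names(df) <- c("pos", "c", "noc", "mc", "hmc")
  data.table::fwrite(df, path)
  path
}

# a full-coverage constant-ratio map over [1, n] with a planted block
planted_map <- function(n, block, ratio_bg, ratio_block, depth = 50,
                        sample_id = "s1") {
  mc <- round(depth * ratio_bg) + integer(n)
  mc[block] <- round(depth * ratio_block)
  make_map(make_records(1:n, c_count = depth - mc, mc_count = mc),
           sample_id = sample_id)
}
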