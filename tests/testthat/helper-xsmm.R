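# Shared fixtures and independent oracles, built in code.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force sliding-window Hamming oracle: leftmost window with the fewest
# mismatches, plus the mismatching probe coordinates there. Independent of
# the package aligner.
hamming_oracle <- function(probe, consensus) {
  pr <- strsplit(probe, "")[[1]]
  cs <- strsplit(consensus, "")[[1]]
  w <- length(cs) - length(pr) + 1
  counts <- vapply(seq_len(w), function(j) {
    sum(cs[j:(j + length(pr) - 1)] != pr)
  }, numeric(1))
  j <- which.min(counts)
  list(
    start = j,
    k = counts[j],
    mismatch_positions = which(cs[j:(j + length(pr) - 1)] != pr)
  )
}

# Plant a probe copy with `n_sub` substitutions into a random consensus;
# returns the probe, consensus and the true (position, type) list.
plant_probe <- function(consensus_length = 120, n_sub = 1) {
  cons <- random_dna(consensus_length)
  start <- sample.int(consensus_length - 24, 1)
  probe <- substr(cons, start, start + 24)
  pos <- if (n_sub > 0) sort(sample.int(25, n_sub)) else integer(0)
  types <- character(0)
  for (p in pos) {
    old <- substr(probe, p, p)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(probe, p, p) <- new
    types <- c(types, paste0(old, "-", new))
  }
  list(probe = probe, consensus = cons, start = start, positions = pos, types = types)
}

# Small intensity fixture: `values` for the given probe ids with arbitrary
# positive entries over tissues x replicates on one platform.
make_intensity <- function(probe_ids, platform, tissues, replicates,
                           values_matrix) {
  meta <- tidyr::expand_grid(tissue = tissues, replicate = seq_len(replicates))
  meta$platform <- platform
  meta$array_id <- sprintf("%s_%s_r%d", platform, meta$tissue, meta$replicate)
  meta <- meta[, c("array_id", "platform", "tissue", "replicate")]
  colnames(values_matrix) <- meta$array_id
  vals <- tibble::as_tibble(values_matrix)
  vals <- dplyr::bind_cols(tibble::tibble(probe_id = probe_ids), vals)
  list(values = vals, metadata = meta)
}

# Cache expensive synthetic runs so several test files can share them.
.xsmm_test_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .xsmm_test_cache)) {
    assign(name, force(expr), envir = .xsmm_test_cache)
  }
  get(name, envir = .xsmm_test_cache)
}

# A moderate end-to-end synthetic run (~10k probes) with default fractions.
medium_run <- function() {
  cached("medium_run", {
    truth <- simulation_truth(seed = 424242L)
    designs <- generate_designs(truth, n_probesets = 910L, probes_per_set = 11L)
    list(truth = truth, designs = designs)
  })
}
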