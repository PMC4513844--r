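# Shared fixtures and independent brute-force oracles.

# Build a coverage track directly from per-chromosome depth vectors.
make_track <- function(...) {
  mesasim:::.new_coverage(list(...))
}

# Independent oracle: per-base coverage by naive counting.
naive_coverage <- function(reads, chrom_len, chrom = "c1") {
  depth <- integer(chrom_len)
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    idx <- (r$start[i] + 1L):r$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# Independent oracle: window means by explicit re-summation.
naive_window_means <- function(depth, w, step) {
  starts <- seq.int(0L, length(depth) - w, by = step)
  vapply(starts, function(s) mean(depth[(s + 1L):(s + w)]), numeric(1))
}

# Small random genome for fuzzing.
tiny_genome <- function(len = 10000, n_loci = 1, seed = 1,
                        min_spacing = 2000) {
  build_genome(c(c1 = len), n_loci = n_loci, min_spacing = min_spacing,
               seed = seed)
}

# One cached pair of test-preset pipeline runs, reused across test files.
.run_cache <- new.env(parent = emptyenv())
cached_paired_runs <- function(seed = 101) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- mesa_config("test", seed = seed)
    .run_cache[[key]] <- list(
      enriched = suppressMessages(run_pipeline(cfg, "enriched")),
      reference = suppressMessages(run_pipeline(cfg, "reference")))
  }
  .run_cache[[key]]
}
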