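# Independent brute-force affine-gap local alignment oracle (score only).
# Written as a plain three-matrix DP, deliberately separate from the package's
# compiled implementation.
r_affine_sw <- function(q, t, match = 1, mismatch = 3, open = 5, extend = 2) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  m <- length(qs); n <- length(ts)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      s <- if (qs[i - 1] == ts[j - 1]) match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# minimal placement row for filter-rule fixtures (gap-free, Watson strand)
make_placement <- function(read_id = "r1", tag = "a", contig = "chr1",
                           strand = "W", start = 0L, end = 60L,
                           score = end - start, bases = NULL) {
  len <- end - start
  tibble::tibble(
    read_id = read_id, tag = tag, contig = contig, strand = strand,
    ref_start = as.integer(start), ref_end = as.integer(end),
    aln_start = as.integer(start), aln_end = as.integer(end),
    qstart = 0L, qend = as.integer(len), score = as.integer(score),
    cigar = paste0(len, "M"), n_aligned = as.integer(len),
    n_match = as.integer(len),
    bases = if (is.null(bases)) strrep("A", len) else bases)
}

# memoised small simulated pipeline run shared across test files
.fixture_env <- new.env(parent = emptyenv())

tiny_run <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- sim_config(genome_length = 5000, n_reads = 120, len_mean = 120,
                      len_sd = 40, len_max = 300, error_rate = 0, seed = 42)
    ds <- simulate_dataset(cfg)
    res <- run_pipeline(pipeline_config(reads = ds$reads, genome = ds$genome,
                                        repeats = ds$repeats))
    .fixture_env$tiny <- list(cfg = cfg, ds = ds, res = res)
  }
  .fixture_env$tiny
}
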