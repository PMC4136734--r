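test_that("local alignment handles the boundary cases exactly", {
  a <- local_align("ACGT", "ACGT")
  expect_equal(a$score, 4L)
  expect_equal(a$cigar, "4M")
  expect_equal(a$n_aligned, 4L)
  expect_equal(local_align("AAAA", "TTTT")$score, 0L)
  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("alignment scores match the brute-force DP and Biostrings", {
  set.seed(21)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:40) {
    q <- random_seq(sample(5:30, 1))
    t <- random_seq(sample(5:30, 1))
    ours <- local_align(q, t)$score
    expect_equal(ours, r_affine_sw(q, t))
    bs <- max(0, Biostrings::pairwiseAlignment(
      q, t, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE))
    expect_equal(ours, bs)
    # score symmetry
    expect_equal(local_align(t, q)$score, ours)
  }
})

test_that("planted error-free reads are recovered at their true locus", {
  set.seed(33)
  genome <- c(g1 = random_seq(10000))
  cref <- build_converted_reference(genome)
  n_ok <- 0L
  for (i in 1:40) {
    len <- sample(40:200, 1)
    s <- sample.int(10000 - len, 1)
    read <- convert_ct(substr(genome[[1]], s, s + len - 1L))  # Watson C->T copy
    tg <- tag_reads(tibble::tibble(id = "p", bases = read))
    hits <- map_reads(tg, cref, use_seeds = TRUE)
    top <- hits[which.max(hits$score), ]
    if (nrow(top) == 1 && top$strand == "W" && top$tag == "a" &&
        abs(top$ref_start - (s - 1L)) <= 2) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / 40, 0.95)
})

test_that("reverse-complemented converted Crick segments map to Crick", {
  set.seed(34)
  genome <- c(g1 = random_seq(4000))
  cref <- build_converted_reference(genome)
  L <- 4000L
  for (i in 1:5) {
    len <- 80L
    cstart <- sample.int(L - len, 1) - 1L  # 0-based on Crick axis
    read <- substr(cref$crick_ct[[1]], cstart + 1L, cstart + len)
    hits <- map_reads(tag_reads(tibble::tibble(id = "p", bases = read)), cref)
    top <- hits[which.max(hits$score), ]
    expect_equal(top$strand, "C")
    expect_equal(top$ref_start, L - (cstart + len))
  }
})

test_that("random 40-mers rarely reach the reporting threshold", {
  set.seed(55)
  genome <- c(g1 = random_seq(1000))
  cref <- build_converted_reference(genome)
  mapped <- 0L
  for (i in 1:100) {
    hits <- map_reads(tag_reads(tibble::tibble(id = "r", bases = random_seq(40))),
                      cref, use_seeds = FALSE)
    if (nrow(hits) > 0) mapped <- mapped + 1L
  }
  expect_lt(mapped / 100, 0.05)
})

test_that("every placement's CIGAR M count equals its aligned-base count", {
  run <- tiny_run()
  pl <- run$res$placements
  m_from_cigar <- vapply(pl$cigar, function(cg) {
    ops <- bisulfitr:::cigar_ops(cg)
    sum(ops$len[ops$op == "M"])
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(m_from_cigar, pl$n_aligned)
  # aligned read positions stay within [qstart, qend)
  expect_true(all(pl$qend - pl$qstart >= pl$n_aligned))
  expect_true(all(pl$ref_end > pl$ref_start))
})

test_that("the external aligner adapter errors without a binary and agrees on loci", {
  expect_error(
    map_with_bwa(tibble::tibble(id = "r", bases = "ACGT"), c(c1 = "ACGT"),
                 bwa = "no-such-aligner-binary"),
    class = "bisulfitr_feature_unavailable")

  set.seed(77)
  genome <- c(g1 = random_seq(3000))
  cref <- build_converted_reference(genome)
  starts <- seq(100, 2500, by = 300)
  reads <- tibble::tibble(
    id = paste0("p", seq_along(starts)),
    bases = vapply(starts, function(s)
      convert_ct(substr(genome[[1]], s, s + 119L)), character(1)))
  internal <- map_filter_reads(reads, cref)$placements
  external <- map_with_bwa(reads, genome)
  agree <- 0L
  for (i in seq_along(starts)) {
    int_i <- internal[internal$parent_id == reads$id[i], ]
    ext_i <- external[external$read_id == reads$id[i], ]
    if (nrow(ext_i) > 0) {
      best <- ext_i[order(-ifelse(is.na(ext_i$score), 0, ext_i$score)), ][1, ]
      if (nrow(int_i) >= 1 &&
          abs(best$ref_start - int_i$ref_start[1]) <= 5) agree <- agree + 1L
    }
  }
  expect_gte(agree, length(starts) - 1L)
})
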