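# Hand-worked example: reference TACGTCA; read (tag 'a', Watson) with original
# bases TACGTTA aligned at 0. Position 2 is a CpG cytosine (C then G), read
# keeps C -> methylated. Position 5 is a CpA cytosine (C then A), read shows
# T -> unmethylated. Cross-checked by an independent per-base walk below.
test_that("calls follow the strand-decision table on a hand-worked example", {
  genome <- c(chr1 = "TACGTCA")
  p <- make_placement(contig = "chr1", start = 0L, end = 7L, bases = "TACGTTA")
  calls <- call_methylation(p, genome)
  w <- calls[calls$strand == "W", ]
  expect_equal(nrow(w), 2L)
  expect_equal(w$pos, c(2L, 5L))
  expect_equal(w$context, c("CpG", "CpA"))
  expect_equal(w$state, c("methylated", "unmethylated"))

  # independent per-base walk over Watson cytosines
  ref <- strsplit(genome[[1]], "")[[1]]
  red <- strsplit("TACGTTA", "")[[1]]
  for (i in which(ref == "C")) {
    expected <- if (red[i] == "C") "methylated" else
      if (red[i] == "T") "unmethylated" else "uninformative"
    expect_equal(w$state[w$pos == i - 1L], expected)
  }
})

test_that("all four phase-strand combinations read out the correct strand", {
  genome <- c(chr1 = "TTACGGTACGTT")
  L <- nchar(genome[[1]])
  sites <- site_table(genome)
  # (b, Watson): informs Crick sites at Watson G positions via G/A
  p <- make_placement(tag = "b", start = 0L, end = L, bases = "TTACGATACGTT")
  calls <- call_methylation(p, genome)
  expect_true(all(calls$strand == "C"))
  g5 <- calls[calls$pos == 4L, ]   # G retained -> methylated Crick C
  expect_equal(g5$state, "methylated")
  g6 <- calls[calls$pos == 5L, ]   # G read as A -> unmethylated
  expect_equal(g6$state, "unmethylated")

  # (a, Crick): read in Crick orientation informs Crick sites via C/T
  crick <- revcomp(genome[[1]])
  pc <- make_placement(tag = "a", strand = "C", start = 0L, end = L, bases = crick)
  pc$aln_start <- 0L; pc$aln_end <- L
  calls_c <- call_methylation(pc, genome)
  expect_true(all(calls_c$strand == "C"))
  expect_true(all(calls_c$state == "methylated"))  # unconverted Crick copy
})

test_that("N bases and windows without cytosines are uninformative", {
  genome <- c(chr1 = "TACGTCA")
  p <- make_placement(contig = "chr1", start = 0L, end = 7L, bases = "TANGTTA")
  calls <- call_methylation(p, genome)
  expect_equal(calls$state[calls$pos == 2L], "uninformative")

  g2 <- c(chr1 = "ATTATTA")
  p2 <- make_placement(contig = "chr1", start = 0L, end = 7L, bases = "ATTATTA")
  expect_equal(nrow(call_methylation(p2, g2)[call_methylation(p2, g2)$strand == "W", ]), 0L)

  expect_error(call_methylation(make_placement(start = 0L, end = 999L), g2),
               "outside contig")
})

fake_calls <- function(states, context = "other", strand = "W",
                       pos = seq_along(states), read = paste0("r", seq_along(states))) {
  tibble::tibble(read_id = read, tag = "a", contig = "chr1", pos = as.integer(pos),
                 strand = strand, context = context, state = states)
}

test_that("conversion rate is the converted fraction with its complement exposed", {
  calls <- fake_calls(c(rep("unmethylated", 97), rep("methylated", 3)))
  cr <- conversion_rate(calls)
  expect_equal(cr$conversion_rate, 97)
  expect_equal(cr$unconverted_rate, 3)
  expect_equal(cr$conversion_rate + cr$unconverted_rate, 100)

  expect_equal(conversion_rate(fake_calls(rep("unmethylated", 10)))$conversion_rate, 100)
  expect_true(is.na(conversion_rate(fake_calls("methylated", context = "CpG"))$conversion_rate))
  # CpG- and CpA-context calls are excluded by default, CpA kept on request
  mix <- dplyr::bind_rows(fake_calls(rep("unmethylated", 50)),
                          fake_calls(rep("methylated", 50), context = "CpA", pos = 51:100))
  expect_equal(conversion_rate(mix)$conversion_rate, 100)
  expect_equal(conversion_rate(mix, contexts_excluded = "CpG")$conversion_rate, 50)
})

test_that("pooled context rates and SMP rates compute from call counts", {
  calls <- fake_calls(c("methylated", "methylated", "unmethylated"),
                      context = "CpG", pos = c(1, 1, 2))
  r <- context_methylation_rate(calls, "CpG", "W")
  expect_equal(r$rate, 200 / 3, tolerance = 1e-10)
  expect_equal(context_methylation_rate(fake_calls(rep("unmethylated", 5),
                                                   context = "CpA"), "CpA", "W")$rate, 0)
  expect_true(is.na(context_methylation_rate(calls, "CpA", "C")$rate))

  # SMP: 10 eligible sites, 3 mixed
  states <- c(rep(list(c("methylated", "methylated")), 4),
              rep(list(c("unmethylated", "unmethylated")), 3),
              rep(list(c("methylated", "unmethylated")), 2),
              list(c("methylated", "methylated", "unmethylated")))
  calls <- dplyr::bind_rows(lapply(seq_along(states), function(i)
    fake_calls(states[[i]], context = "CpG", pos = rep(i, length(states[[i]])),
               read = paste0("r", i, "_", seq_along(states[[i]])))))
  smp <- smp_rate(calls, "CpG")
  expect_equal(smp$rate[smp$strand == "W"], 30)
  expect_equal(smp$eligible_sites[smp$strand == "W"], 10L)
  hom <- smp_rate(fake_calls(c("methylated", "methylated"), context = "CpG",
                             pos = c(1, 1)), "CpG")
  expect_equal(hom$rate[hom$strand == "W"], 0)
  expect_true(is.na(hom$rate[hom$strand == "C"]))
})

test_that("dyad symmetry splits into symmetric and asymmetric fractions", {
  dyad_calls <- function(i, w_state, c_state) {
    dplyr::bind_rows(
      fake_calls(w_state, context = "CpG", strand = "W", pos = rep(10 * i, length(w_state)),
                 read = paste0("w", i, "_", seq_along(w_state))),
      fake_calls(c_state, context = "CpG", strand = "C", pos = rep(10 * i + 1, length(c_state)),
                 read = paste0("c", i, "_", seq_along(c_state))))
  }
  calls <- dplyr::bind_rows(
    dyad_calls(1, "methylated", "methylated"),
    dyad_calls(2, "methylated", "methylated"),
    dyad_calls(3, "methylated", "unmethylated"),
    dyad_calls(4, "unmethylated", "unmethylated"))
  r <- symmetric_asymmetric_rates(calls)
  expect_equal(r$eligible_dyads, 4L)
  expect_equal(r$symmetric_rate, 50)
  expect_equal(r$asymmetric_rate, 25)
  # a tied strand counts as unmethylated
  tied <- dyad_calls(1, c("methylated", "unmethylated"), "methylated")
  expect_equal(symmetric_asymmetric_rates(tied)$asymmetric_rate, 100)
  expect_true(is.na(symmetric_asymmetric_rates(fake_calls("methylated"))$symmetric_rate))
})

test_that("coverage statistics follow their definitions", {
  genome <- c(chr1 = random_seq(1000))
  p <- make_placement(start = 100L, end = 200L)
  p$bases <- substr(genome[[1]], 101, 200)
  p$unique <- TRUE
  cov <- coverage_stats(p, genome)
  expect_equal(cov$covered_fraction, 0.1)
  expect_equal(cov$mean_depth, 1.0)
  expect_equal(cov$consistency_rate, 100)

  two <- dplyr::bind_rows(make_placement(start = 100L, end = 150L),
                          make_placement(read_id = "r2", start = 150L, end = 200L))
  two$unique <- TRUE
  cov <- coverage_stats(two, genome)
  expect_equal(cov$covered_fraction, 0.1)
  expect_equal(cov$mean_depth, 1.0)

  mm <- make_placement(start = 0L, end = 100L)
  mm$n_match <- 98L
  mm$unique <- TRUE
  expect_equal(coverage_stats(mm, genome)$consistency_rate, 98)
})

test_that("calls partition and Watson/Crick agree under a symmetric truth", {
  cfg <- sim_config(genome_length = 30000, n_reads = 400,
                    p_meth = c(cpg_w = 0.5, cpg_c = 0.5, cpa_w = 0.2,
                               cpa_c = 0.2, other = 0),
                    error_rate = 0, seed = 19)
  ds <- simulate_dataset(cfg)
  res <- run_pipeline(pipeline_config(reads = ds$reads, genome = ds$genome))
  calls <- res$calls
  expect_equal(sum(calls$state %in% c("methylated", "unmethylated", "uninformative")),
               nrow(calls))
  mr <- bisulfitr:::meth_rates(calls)
  w <- mr[mr$context == "CpG" & mr$strand == "W", ]
  cc <- mr[mr$context == "CpG" & mr$strand == "C", ]
  se <- 100 * sqrt(0.5 * 0.5 / w$n_eff + 0.5 * 0.5 / cc$n_eff)
  expect_lt(abs(w$rate - cc$rate), 3 * se)
})
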