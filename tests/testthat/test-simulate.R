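test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 10000, n_reads = 60, seed = 7)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$reads, d2$reads)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$methylome, d2$methylome)
})

test_that("genome composition follows the configuration", {
  g0 <- simulate_genome(sim_config(genome_length = 5000, gc = 0, seed = 2))
  expect_false(grepl("[CG]", g0$genome[[1]]))

  cfg_small <- sim_config(seed = 1)
  cfg_small$genome_length <- 500
  expect_error(simulate_genome(cfg_small), "1 kb")

  gr <- simulate_genome(sim_config(genome_length = 50000, repeat_frac = 0.1, seed = 3))
  frac <- sum(gr$repeats$end - gr$repeats$start) / 50000
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)
  expect_true(all(gr$repeats$repeat_class %in% sim_config()$repeat_classes))
})

test_that("the methylome realises its context-strand probabilities", {
  cfg1 <- sim_config(genome_length = 20000,
                     p_meth = c(cpg_w = 1, cpg_c = 0, cpa_w = 0, cpa_c = 0, other = 0),
                     seed = 4)
  g <- simulate_genome(cfg1)
  m <- assign_methylome(g$genome, cfg1)
  expect_true(all(m$methylated[m$context == "CpG" & m$strand == "W"]))
  expect_false(any(m$methylated[m$context != "CpG" | m$strand != "W"]))

  cfg2 <- sim_config(genome_length = 30000,
                     p_meth = c(cpg_w = 0.65, cpg_c = 0.65, cpa_w = 0,
                                cpa_c = 0, other = 0), seed = 5)
  g2 <- simulate_genome(cfg2)
  m2 <- assign_methylome(g2$genome, cfg2)
  cw <- m2[m2$context == "CpG" & m2$strand == "W", ]
  expect_gte(nrow(cw), 500)
  p_hat <- mean(cw$methylated)
  expect_lt(abs(p_hat - 0.65), 3 * sqrt(0.65 * 0.35 / nrow(cw)))
})

test_that("bisulfite chemistry boundaries behave as expected", {
  # complete conversion of a fully unmethylated genome: template-state reads
  # carry no C, complement-state reads no G
  cfg <- sim_config(genome_length = 5000, n_reads = 80, conversion = 1,
                    p_meth = c(cpg_w = 0, cpg_c = 0, cpa_w = 0, cpa_c = 0, other = 0),
                    error_rate = 0, len_mean = 100, len_sd = 20, len_max = 200,
                    seed = 6)
  ds <- simulate_dataset(cfg)
  st <- ds$truth$state[match(ds$reads$id, ds$truth$read_id)]
  expect_false(any(grepl("C", ds$reads$bases[st %in% c("W", "C")])))
  expect_false(any(grepl("G", ds$reads$bases[st %in% c("Wc", "Cc")])))

  # no conversion: Watson-template reads reproduce the untreated genome
  cfg0 <- cfg; cfg0$conversion <- 0
  ds0 <- simulate_dataset(cfg0)
  wi <- which(ds0$truth$state == "W")[1:5]
  for (i in wi) {
    tr <- ds0$truth[i, ]
    expect_equal(ds0$reads$bases[ds0$reads$id == tr$read_id],
                 substr(ds0$genome[[tr$contig]], tr$start + 1, tr$end))
  }
})

test_that("bisulfite asymmetry depletes C in 'a'-state and G in 'b'-state reads", {
  cfg <- sim_config(genome_length = 20000, n_reads = 150, error_rate = 0, seed = 14)
  ds <- simulate_dataset(cfg)
  st <- ds$truth$state[match(ds$reads$id, ds$truth$read_id)]
  frac <- function(ch, x) sum(stringr::str_count(x, ch)) / sum(nchar(x))
  g_frac <- frac("C", ds$genome)
  expect_lt(frac("C", ds$reads$bases[st %in% c("W", "C")]), 0.5 * g_frac)
  expect_lt(frac("G", ds$reads$bases[st %in% c("Wc", "Cc")]), 0.5 * g_frac)
})

test_that("read lengths follow the truncated normal distribution", {
  cfg <- sim_config(genome_length = 100000, n_reads = 5000, error_rate = 0, seed = 16)
  ds <- simulate_dataset(cfg)
  lens <- nchar(ds$reads$bases)
  expect_gte(min(lens), 40)
  expect_lte(max(lens), 745)
  # numeric-integration oracle for the truncated mean
  mu <- 312.60; sg <- 136.83
  z <- stats::integrate(function(x) stats::dnorm(x, mu, sg), 40, 745)$value
  m_theory <- stats::integrate(function(x) x * stats::dnorm(x, mu, sg), 40, 745)$value / z
  expect_lt(abs(mean(lens) - m_theory), 3 * sd(lens) / sqrt(length(lens)))
})

test_that("chimeric reads carry two-part truth records", {
  cfg <- sim_config(genome_length = 20000, n_reads = 60, chimera_frac = 1,
                    len_mean = 200, len_sd = 20, len_min = 80, len_max = 400,
                    error_rate = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  parts <- table(ds$truth$read_id)
  # reads too short to yield two viable fragments stay single-locus
  expect_true(all(parts %in% c(1L, 2L)))
  expect_gt(sum(parts == 2L), 40L)
  two_part <- names(parts)[parts == 2L]
  expect_true(all(ds$truth$chimera[ds$truth$read_id %in% two_part]))
  expect_false(any(ds$truth$chimera[!ds$truth$read_id %in% two_part]))
})

test_that("truth scoring rejects mismatched read ids", {
  run <- tiny_run()
  bad_truth <- run$ds$truth
  bad_truth$read_id <- paste0("x_", bad_truth$read_id)
  expect_error(score_against_truth(run$res, bad_truth, run$cfg), "id mismatch")

  rec <- score_against_truth(run$res, run$ds$truth, run$cfg)
  expect_s3_class(rec$parameters, "tbl_df")
  expect_gte(rec$accuracy$accuracy, 0.95)
})
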