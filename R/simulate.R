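# Synthetic genomes, methylomes and FFPE-degraded bisulfite reads with known
# truth, so every pipeline stage has a parameter-recovery test without
# external data.
#
# Generative model, per read: sample a locus and one of the four bisulfite
# strand states (bisulfite-converted Watson or Crick template, or the PCR
# complement of either, as whole-genome amplification produces all four);
# unmethylated cytosines on the template convert C->T with probability
# `conversion`, methylated cytosines never convert; uniform substitution
# errors are injected afterwards. Read lengths follow a truncated normal.
# Conversion failure is i.i.d. per cytosine per read.

# run code under a fixed seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults emulate the archival-FFPE 454 study conditions: ~100 kb reference,
#' 5,000 reads with length distribution mean 312.60 / sd 136.83, range 40-745
#' bp, bisulfite conversion efficiency 96.7%, and per-context per-strand
#' methylation probabilities CpG 65.1%/42.7% and CpA 16.4%/21.7%
#' (Watson/Crick). Degradation is modelled only through the length
#' distribution and the substitution error rate.
#'
#' @param genome_length Total reference length in bp (minimum 1,000).
#' @param n_contigs Number of contigs (length split evenly).
#' @param gc GC fraction of the random genome.
#' @param cpg_factor CpG enrichment factor (1 = i.i.d. base expectation;
#'   above 1 plants extra CpG dinucleotides, below 1 destroys a fraction).
#' @param p_meth Named methylation probabilities: `cpg_w`, `cpg_c`, `cpa_w`,
#'   `cpa_c`, `other`.
#' @param conversion Bisulfite conversion efficiency in `[0, 1]`.
#' @param n_reads Number of reads.
#' @param len_mean,len_sd,len_min,len_max Truncated-normal read-length
#'   distribution (bp); `len_min` must be at least 40.
#' @param error_rate Per-base uniform substitution error probability.
#' @param strand_mix Probabilities of the four bisulfite strand states
#'   `W`, `C`, `Wc`, `Cc` (template Watson/Crick, `*c` = PCR complement).
#' @param chimera_frac Fraction of reads joining two random loci.
#' @param repeat_frac Fraction of the genome covered by synthetic repeat
#'   intervals (disjoint, 150-500 bp, labelled from `repeat_classes`).
#' @param repeat_classes Labels for synthetic repeat intervals.
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   configuration and seed.
#' @return An object of class `bs_sim_config` (a list).
#' @export
sim_config <- function(genome_length = 1e5, n_contigs = 1, gc = 0.41,
                       cpg_factor = 1,
                       p_meth = c(cpg_w = 0.651, cpg_c = 0.427,
                                  cpa_w = 0.164, cpa_c = 0.217, other = 0),
                       conversion = 0.967, n_reads = 5000,
                       len_mean = 312.60, len_sd = 136.83,
                       len_min = 40, len_max = 745,
                       error_rate = 0.01,
                       strand_mix = c(W = 0.25, C = 0.25, Wc = 0.25, Cc = 0.25),
                       chimera_frac = 0, repeat_frac = 0,
                       repeat_classes = c("Alu", "L1M", "simple repeats"),
                       seed = 1) {
  stopifnot(all(p_meth >= 0 & p_meth <= 1), conversion >= 0, conversion <= 1,
            len_min >= 40, gc >= 0, gc <= 1, error_rate >= 0, error_rate < 1,
            chimera_frac >= 0, chimera_frac <= 1, repeat_frac >= 0, repeat_frac < 1)
  nm <- c("cpg_w", "cpg_c", "cpa_w", "cpa_c", "other")
  if (!all(nm %in% names(p_meth))) {
    bs_abort(sprintf("p_meth must name all of: %s", paste(nm, collapse = ", ")))
  }
  structure(list(genome_length = genome_length, n_contigs = n_contigs, gc = gc,
                 cpg_factor = cpg_factor, p_meth = p_meth[nm],
                 conversion = conversion, n_reads = n_reads,
                 len_mean = len_mean, len_sd = len_sd, len_min = len_min,
                 len_max = len_max, error_rate = error_rate,
                 strand_mix = strand_mix / sum(strand_mix),
                 chimera_frac = chimera_frac, repeat_frac = repeat_frac,
                 repeat_classes = repeat_classes, seed = as.integer(seed)),
            class = "bs_sim_config")
}

#' Simulate a reference genome and synthetic repeat annotation
#'
#' @param config [sim_config()].
#' @return List: `genome` (named character vector) and `repeats` (tibble:
#'   `contig`, `start`, `end`, `repeat_class`; empty when `repeat_frac` is 0).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "bs_sim_config"))
  if (config$genome_length < 1000) {
    bs_abort("genome_length below 1 kb is too small for meaningful simulation")
  }
  with_seed_(config$seed, {
    per <- rep(floor(config$genome_length / config$n_contigs), config$n_contigs)
    per[1] <- per[1] + config$genome_length - sum(per)
    probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
               G = config$gc / 2, T = (1 - config$gc) / 2)
    genome <- character(config$n_contigs)
    names(genome) <- paste0("contig", seq_len(config$n_contigs))
    repeats <- list()
    for (ci in seq_len(config$n_contigs)) {
      L <- per[ci]
      ch <- sample(names(probs), L, replace = TRUE, prob = probs)
      if (config$cpg_factor > 1) {
        n_cur <- sum(ch[-L] == "C" & ch[-1] == "G")
        n_extra <- round((config$cpg_factor - 1) * n_cur)
        if (n_extra > 0) {
          at <- sample.int(L - 1L, min(n_extra, L - 1L))
          ch[at] <- "C"; ch[at + 1L] <- "G"
        }
      } else if (config$cpg_factor < 1) {
        cpg_at <- which(ch[-L] == "C" & ch[-1] == "G")
        n_kill <- round((1 - config$cpg_factor) * length(cpg_at))
        if (n_kill > 0) ch[sample(cpg_at, n_kill) + 1L] <- "A"
      }
      genome[ci] <- paste(ch, collapse = "")
      if (config$repeat_frac > 0) {
        target <- config$repeat_frac * L
        placed <- IRanges::IRanges()
        rows <- list(); total <- 0; tries <- 0
        while (total < target && tries < 10000) {
          tries <- tries + 1
          w <- sample(150:500, 1)
          s <- sample.int(max(1L, L - w), 1) - 1L
          cand <- IRanges::IRanges(start = s + 1L, end = s + w)
          if (length(placed) > 0 &&
              length(IRanges::findOverlaps(cand, placed)) > 0) next
          placed <- c(placed, cand)
          total <- total + w
          rows[[length(rows) + 1]] <- tibble::tibble(
            contig = names(genome)[ci], start = s, end = s + w,
            repeat_class = sample(config$repeat_classes, 1))
        }
        repeats[[length(repeats) + 1]] <- dplyr::bind_rows(rows)
      }
    }
    repeats <- if (length(repeats)) {
      dplyr::arrange(dplyr::bind_rows(repeats), .data$contig, .data$start)
    } else {
      tibble::tibble(contig = character(), start = integer(), end = integer(),
                     repeat_class = character())
    }
    list(genome = genome, repeats = repeats)
  })
}

#' Assign a ground-truth methylome
#'
#' Every cytosine site (both strands) is independently methylated with its
#' context-strand probability from the configuration.
#'
#' @param genome Named character vector of contig sequences.
#' @param config [sim_config()].
#' @return [site_table()] tibble with added `p` and logical `methylated`.
#' @export
assign_methylome <- function(genome, config) {
  sites <- site_table(genome)
  p <- unname(config$p_meth[ifelse(sites$context == "CpG",
                                   ifelse(sites$strand == "W", "cpg_w", "cpg_c"),
                                   ifelse(sites$context == "CpA",
                                          ifelse(sites$strand == "W", "cpa_w", "cpa_c"),
                                          "other"))])
  with_seed_(config$seed + 1L, {
    sites$p <- p
    sites$methylated <- runif(nrow(sites)) < p
    sites
  })
}

# truncated-normal draw (rejection), rounded to integer bp
rtrunc_len <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate bisulfite reads with truth records
#'
#' @param genome Named character vector of contig sequences.
#' @param methylome [assign_methylome()] output.
#' @param config [sim_config()].
#' @return List: `reads` (tibble `id`, `bases`, `quality`) and `truth`
#'   (tibble `read_id`, `contig`, `start`, `end`, `state`, `part`,
#'   `chimera`).
#' @export
generate_reads <- function(genome, methylome, config) {
  if (config$n_reads < 1) bs_abort("n_reads must be at least 1")
  lengths <- setNames(nchar(genome), names(genome))
  chars <- lapply(genome, function(s) strsplit(s, "")[[1]])
  # per-contig site state lookup: NA = not a site, TRUE/FALSE = methylated
  meth_w <- lapply(names(genome), function(cn) {
    v <- rep(NA, lengths[[cn]])
    m <- methylome[methylome$contig == cn & methylome$strand == "W", ]
    v[m$pos + 1L] <- m$methylated
    v
  })
  meth_c <- lapply(names(genome), function(cn) {
    v <- rep(NA, lengths[[cn]])
    m <- methylome[methylome$contig == cn & methylome$strand == "C", ]
    v[m$pos + 1L] <- m$methylated
    v
  })
  names(meth_w) <- names(meth_c) <- names(genome)

  with_seed_(config$seed + 2L, {
    ids <- sprintf("read%05d", seq_len(config$n_reads))
    lens <- rtrunc_len(config$n_reads, config$len_mean, config$len_sd,
                       config$len_min, min(config$len_max, max(lengths)))
    states <- sample(names(config$strand_mix), config$n_reads, replace = TRUE,
                     prob = config$strand_mix)
    chim <- runif(config$n_reads) < config$chimera_frac
    bases_out <- character(config$n_reads)
    truth <- list()

    one_part <- function(plen, state) {
      contig <- sample(names(genome), 1, prob = lengths / sum(lengths))
      L <- lengths[[contig]]
      plen <- min(plen, L)
      s <- sample.int(L - plen + 1L, 1) - 1L
      idx <- (s + 1L):(s + plen)
      w <- chars[[contig]][idx]
      if (state %in% c("W", "Wc")) {
        st <- meth_w[[contig]][idx]
        conv <- which(!is.na(st) & !st)
        conv <- conv[runif(length(conv)) < config$conversion]
        w[conv] <- "T"
      } else {
        st <- meth_c[[contig]][idx]
        conv <- which(!is.na(st) & !st)
        conv <- conv[runif(length(conv)) < config$conversion]
        w[conv] <- "A"
      }
      seq <- if (state %in% c("C", "Wc")) {
        chartr("ACGTN", "TGCAN", paste(rev(w), collapse = ""))
      } else {
        paste(w, collapse = "")
      }
      list(seq = seq, contig = contig, start = s, end = s + plen)
    }

    for (i in seq_len(config$n_reads)) {
      state <- states[i]
      if (chim[i] && lens[i] >= 2 * config$len_min) {
        l1 <- lens[i] %/% 2L; l2 <- lens[i] - l1
        p1 <- one_part(l1, state); p2 <- one_part(l2, state)
        seq <- paste0(p1$seq, p2$seq)
        truth[[length(truth) + 1]] <- tibble::tibble(
          read_id = ids[i], contig = c(p1$contig, p2$contig),
          start = c(p1$start, p2$start), end = c(p1$end, p2$end),
          state = state, part = 1:2, chimera = TRUE)
      } else {
        p1 <- one_part(lens[i], state)
        seq <- p1$seq
        truth[[length(truth) + 1]] <- tibble::tibble(
          read_id = ids[i], contig = p1$contig, start = p1$start, end = p1$end,
          state = state, part = 1L, chimera = FALSE)
      }
      if (config$error_rate > 0) {
        ch <- strsplit(seq, "")[[1]]
        err <- which(runif(length(ch)) < config$error_rate)
        for (e in err) ch[e] <- sample(setdiff(c("A", "C", "G", "T"), ch[e]), 1)
        seq <- paste(ch, collapse = "")
      }
      bases_out[i] <- seq
    }
    list(reads = tibble::tibble(id = ids, bases = bases_out,
                                quality = vector("list", config$n_reads)),
         truth = dplyr::bind_rows(truth))
  })
}

#' Simulate a complete dataset
#'
#' @param config [sim_config()].
#' @return List: `genome`, `repeats`, `methylome`, `reads`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_genome(config)
  methylome <- assign_methylome(g$genome, config)
  rr <- generate_reads(g$genome, methylome, config)
  list(genome = g$genome, repeats = g$repeats, methylome = methylome,
       reads = rr$reads, truth = rr$truth, config = config)
}

#' Score pipeline output against simulation truth
#'
#' @param result A [run_pipeline()] result (or a list with `placements`,
#'   `fates`, `calls` and `summary_stats`).
#' @param truth Truth tibble from [generate_reads()] / [simulate_dataset()].
#' @param config The generating [sim_config()].
#' @return List of class `bs_recovery`: `accuracy` (one-row tibble:
#'   `n_unique`, `n_correct`, `accuracy` of unique placements at the true
#'   locus +/- 5 bp) and `parameters` (tibble per generating parameter:
#'   `truth`, `estimate`, `error`, `se`, `within_3se`). Conversion-corrected
#'   rates are compared for the methylation parameters.
#' @export
score_against_truth <- function(result, truth, config) {
  fates <- result$fates
  miss_out <- setdiff(fates$read_id, unique(truth$read_id))
  miss_tr <- setdiff(unique(truth$read_id), fates$read_id)
  if (length(miss_out) > 0 || length(miss_tr) > 0) {
    bs_abort(sprintf("read id mismatch between pipeline output and truth (e.g. '%s')",
                     c(miss_out, miss_tr)[1]))
  }
  pl <- result$placements
  uniq <- pl[pl$unique, , drop = FALSE]
  correct <- 0L
  for (i in seq_len(nrow(uniq))) {
    tr <- truth[truth$read_id == uniq$parent_id[i], , drop = FALSE]
    hit <- any(tr$contig == uniq$contig[i] &
                 uniq$ref_start[i] >= tr$start - 5L &
                 uniq$ref_end[i] <= tr$end + 5L)
    if (hit) correct <- correct + 1L
  }
  accuracy <- tibble::tibble(
    n_unique = nrow(uniq), n_correct = correct,
    accuracy = if (nrow(uniq) == 0) NA_real_ else correct / nrow(uniq))

  s <- result$summary_stats
  conv <- conversion_rate(result$calls)
  mr <- meth_rates(result$calls)
  n_conv <- conv$converted + conv$unconverted
  c_ <- config$conversion
  row_for <- function(name, truth_p, est, se) {
    tibble::tibble(parameter = name, truth = truth_p, estimate = est,
                   error = est - truth_p, se = se,
                   within_3se = is.finite(est) && abs(est - truth_p) <= 3 * se)
  }
  rate_row <- function(name, ctx, strand, key) {
    p <- unname(config$p_meth[[key]])
    m <- mr[mr$context == ctx & mr$strand == strand, ]
    se <- if (m$n_eff > 0) 100 * sqrt(max(p * (1 - p), 1e-6) / m$n_eff) / c_ else Inf
    est <- s[[paste0(tolower(ctx), "_", ifelse(strand == "W", "watson", "crick"),
                     "_corrected")]]
    row_for(name, 100 * p, est, se)
  }
  parameters <- dplyr::bind_rows(
    row_for("conversion_rate", 100 * c_, s$conversion_rate,
            if (n_conv > 0) 100 * sqrt(max(c_ * (1 - c_), 1e-6) / n_conv) else Inf),
    rate_row("cpg_watson", "CpG", "W", "cpg_w"),
    rate_row("cpg_crick", "CpG", "C", "cpg_c"),
    rate_row("cpa_watson", "CpA", "W", "cpa_w"),
    rate_row("cpa_crick", "CpA", "C", "cpa_c"))
  structure(list(accuracy = accuracy, parameters = parameters),
            class = "bs_recovery")
}

#' @export
print.bs_recovery <- function(x, ...) {
  cat("<bs_recovery> mapping accuracy:",
      formatC(x$accuracy$accuracy, format = "f", digits = 3), "\n")
  print(x$parameters)
  invisible(x)
}
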