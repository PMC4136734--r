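# Read-level methylation calls and the summary statistics: bisulfite
# conversion rate, per-context per-strand methylation rates (raw and
# conversion-corrected), single-methylation-polymorphism rates, symmetric and
# asymmetric CpG dyad rates, and coverage statistics.
#
# Readout table (read version x aligned strand):
#   ('a', Watson) -> Watson cytosines, read C = methylated / T = unmethylated
#   ('a', Crick)  -> Crick cytosines (Watson G positions), read C/T in Crick
#                    orientation
#   ('b', Watson) -> Crick cytosines via G/A at Watson G positions
#   ('b', Crick)  -> Watson cytosines via G/A in Crick orientation
# After whole-genome amplification all four bisulfite strand states exist;
# only the read's ORIGINAL (unconverted) bases inform the calls.

#' Cytosine site table of a genome
#'
#' Enumerates every Watson-strand cytosine and every Crick-strand cytosine
#' (Watson guanine position), with the dinucleotide context on the site's own
#' strand: CpG (next base G), CpA (next base A), or other.
#'
#' @param genome Named character vector of contig sequences.
#' @return Tibble: `contig`, `pos` (0-based Watson), `strand` (`"W"`/`"C"`),
#'   `context` (`"CpG"`, `"CpA"`, `"other"`).
#' @export
site_table <- function(genome) {
  purrr::imap(genome, function(seq, contig) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    cw <- which(ch == "C")
    gw <- which(ch == "G")
    nxt <- ch[cw + 1L]                       # NA past the end
    prv <- rep(NA_character_, length(gw))
    prv[gw > 1L] <- ch[gw[gw > 1L] - 1L]
    dplyr::bind_rows(
      tibble::tibble(contig = contig, pos = cw - 1L, strand = "W",
                     context = dplyr::case_when(nxt == "G" ~ "CpG",
                                                nxt == "A" ~ "CpA",
                                                TRUE ~ "other")),
      tibble::tibble(contig = contig, pos = gw - 1L, strand = "C",
                     context = dplyr::case_when(prv == "C" ~ "CpG",
                                                prv == "T" ~ "CpA",
                                                TRUE ~ "other"))
    )
  }) |> dplyr::bind_rows()
}

empty_calls <- function() {
  tibble::tibble(read_id = character(), tag = character(), contig = character(),
                 pos = integer(), strand = character(), context = character(),
                 state = character())
}

#' Call per-read methylation states at cytosine sites
#'
#' For every aligned read position over a genomic cytosine of the strand the
#' placement informs (see the readout table in the module header), a call is
#' emitted from the read's original base: the retained base (C or G) means
#' methylated, the converted base (T or A) unmethylated, anything else
#' uninformative.
#'
#' @param placements Surviving placements ([map_filter_reads()] or
#'   [map_reads()] output; must carry `bases`).
#' @param genome Named character vector of contig sequences.
#' @param sites Optional precomputed [site_table()] (recomputed otherwise).
#' @return Tibble of calls: `read_id`, `tag`, `contig`, `pos` (0-based
#'   Watson), `strand` (site strand), `context`, `state`.
#' @export
call_methylation <- function(placements, genome, sites = NULL) {
  if (nrow(placements) == 0) return(empty_calls())
  lengths <- setNames(nchar(genome), names(genome))
  bad <- which(!(placements$contig %in% names(genome)) |
                 placements$ref_start < 0 |
                 placements$ref_end > lengths[placements$contig])
  if (length(bad) > 0) {
    bs_abort(sprintf("placement of read '%s' lies outside contig '%s'",
                     placements$read_id[bad[1]], placements$contig[bad[1]]))
  }
  if (is.null(sites)) sites <- site_table(genome)

  # aligned (read position, target position) pairs per placement
  p_idx <- list(); p_q <- list(); p_t <- list()
  for (i in seq_len(nrow(placements))) {
    ops <- cigar_ops(placements$cigar[i])
    qpos <- placements$qstart[i]; tpos <- placements$aln_start[i]
    qs <- integer(0); ts <- integer(0)
    for (j in seq_along(ops$op)) {
      len <- ops$len[j]
      if (ops$op[j] == "M") {
        qs <- c(qs, seq.int(qpos, length.out = len))
        ts <- c(ts, seq.int(tpos, length.out = len))
        qpos <- qpos + len; tpos <- tpos + len
      } else if (ops$op[j] == "I") {
        qpos <- qpos + len
      } else {
        tpos <- tpos + len
      }
    }
    p_idx[[i]] <- rep.int(i, length(qs)); p_q[[i]] <- qs; p_t[[i]] <- ts
  }
  pidx <- unlist(p_idx); qpos <- unlist(p_q); tpos <- unlist(p_t)

  contig <- placements$contig[pidx]
  strand <- placements$strand[pidx]
  tag <- placements$tag[pidx]
  L <- unname(lengths[contig])
  wpos <- ifelse(strand == "C", L - 1L - tpos, tpos)
  site_strand <- ifelse((tag == "a" & strand == "W") | (tag == "b" & strand == "C"),
                        "W", "C")
  read_base <- stringr::str_sub(placements$bases[pidx], qpos + 1L, qpos + 1L)

  pairs <- tibble::tibble(read_id = placements$read_id[pidx], tag = tag,
                          contig = contig, pos = wpos, strand = site_strand,
                          read_base = read_base)
  calls <- dplyr::inner_join(pairs, sites, by = c("contig", "pos", "strand"))
  meth_base <- ifelse(calls$tag == "a", "C", "G")
  unmeth_base <- ifelse(calls$tag == "a", "T", "A")
  calls$state <- dplyr::case_when(
    calls$read_base == meth_base ~ "methylated",
    calls$read_base == unmeth_base ~ "unmethylated",
    TRUE ~ "uninformative")
  calls$read_base <- NULL
  dplyr::arrange(calls, .data$contig, .data$pos, .data$strand, .data$read_id)
}

#' Bisulfite conversion rate
#'
#' Fraction (%) of informative cytosine observations, at sites outside the
#' excluded contexts, that were converted (read as T/A). By default both CpG
#' and CpA contexts are excluded, since both are quantified as potentially
#' methylated; `contexts_excluded = "CpG"` restricts the exclusion to CpG
#' only. The complementary unconverted quotient is also returned.
#'
#' @param calls Calls tibble from [call_methylation()].
#' @param contexts_excluded Contexts whose cytosines are not used.
#' @return One-row tibble: `conversion_rate` (%), `unconverted_rate` (%),
#'   `converted`, `unconverted` (counts). Rates are `NA` with no informative
#'   calls.
#' @export
conversion_rate <- function(calls, contexts_excluded = c("CpG", "CpA")) {
  sub <- calls[!(calls$context %in% contexts_excluded) & calls$state != "uninformative", ]
  conv <- sum(sub$state == "unmethylated")
  unconv <- sum(sub$state == "methylated")
  rate <- if (conv + unconv == 0) NA_real_ else 100 * conv / (conv + unconv)
  tibble::tibble(conversion_rate = rate,
                 unconverted_rate = if (is.na(rate)) NA_real_ else 100 - rate,
                 converted = conv, unconverted = unconv)
}

#' Pooled methylation rate of one context and strand
#'
#' Call-level pooling: 100 x methylated calls / informative calls over all
#' sites of the given context and strand.
#'
#' @param calls Calls tibble.
#' @param context `"CpG"` or `"CpA"`.
#' @param strand `"W"` or `"C"`.
#' @return One-row tibble: `context`, `strand`, `n_methylated`,
#'   `n_unmethylated`, `n_sites` (distinct informative sites), `n_eff`
#'   (effective independent sites, `(sum d)^2 / sum d^2` over site depths),
#'   `rate` (%; `NA` with no informative calls).
#' @export
context_methylation_rate <- function(calls, context, strand) {
  sub <- calls[calls$context == context & calls$strand == strand &
                 calls$state != "uninformative", ]
  nm <- sum(sub$state == "methylated")
  nu <- sum(sub$state == "unmethylated")
  d <- as.integer(table(paste(sub$contig, sub$pos)))
  tibble::tibble(context = context, strand = strand,
                 n_methylated = nm, n_unmethylated = nu,
                 n_sites = length(d),
                 n_eff = if (length(d) == 0) 0 else sum(d)^2 / sum(d^2),
                 rate = if (nm + nu == 0) NA_real_ else 100 * nm / (nm + nu))
}

# all four context x strand combinations at once
meth_rates <- function(calls) {
  dplyr::bind_rows(
    context_methylation_rate(calls, "CpG", "W"),
    context_methylation_rate(calls, "CpG", "C"),
    context_methylation_rate(calls, "CpA", "W"),
    context_methylation_rate(calls, "CpA", "C"))
}

# conversion-corrected methylation rate (%): inverts the observation model
# m = p + (1 - p)(1 - c), where unmethylated cytosines escape conversion with
# probability 1 - c and then read as methylated.
correct_rate <- function(raw_pct, conversion_pct) {
  m <- raw_pct / 100; c <- conversion_pct / 100
  p <- (m - (1 - c)) / c
  100 * pmin(1, pmax(0, p))
}

#' Single-methylation-polymorphism rate
#'
#' Over sites of one context with at least 2 informative calls on the same
#' strand: the percentage of such sites showing both methylated and
#' unmethylated calls.
#'
#' @param calls Calls tibble.
#' @param context `"CpG"` or `"CpA"`.
#' @return Tibble with one row per strand: `context`, `strand`,
#'   `eligible_sites`, `mixed_sites`, `rate` (%; `NA` with no eligible site).
#' @export
smp_rate <- function(calls, context) {
  sub <- calls[calls$context == context & calls$state != "uninformative", ]
  purrr::map(c("W", "C"), function(s) {
    ss <- sub[sub$strand == s, ]
    if (nrow(ss) == 0) {
      return(tibble::tibble(context = context, strand = s, eligible_sites = 0L,
                            mixed_sites = 0L, rate = NA_real_))
    }
    per_site <- ss |>
      dplyr::count(.data$contig, .data$pos, .data$state) |>
      tidyr::pivot_wider(names_from = "state", values_from = "n", values_fill = 0L)
    if (!"methylated" %in% names(per_site)) per_site$methylated <- 0L
    if (!"unmethylated" %in% names(per_site)) per_site$unmethylated <- 0L
    depth <- per_site$methylated + per_site$unmethylated
    elig <- depth >= 2L
    mixed <- elig & per_site$methylated > 0L & per_site$unmethylated > 0L
    tibble::tibble(context = context, strand = s,
                   eligible_sites = sum(elig), mixed_sites = sum(mixed),
                   rate = if (sum(elig) == 0) NA_real_ else 100 * sum(mixed) / sum(elig))
  }) |> dplyr::bind_rows()
}

#' Symmetric and asymmetric CpG dyad methylation rates
#'
#' A CpG dyad pairs a Watson CpG cytosine at position i with the Crick CpG
#' cytosine at i+1. Dyads with at least one informative call on each strand
#' are eligible; a strand is methylated at the dyad if a strict majority of
#' its calls are methylated (ties count as unmethylated).
#'
#' @param calls Calls tibble.
#' @return One-row tibble: `eligible_dyads`, `symmetric_rate` (%; both strands
#'   methylated), `asymmetric_rate` (%; exactly one). `NA` with no eligible
#'   dyad.
#' @export
symmetric_asymmetric_rates <- function(calls) {
  cpg <- calls[calls$context == "CpG" & calls$state != "uninformative", ]
  agg <- cpg |>
    dplyr::group_by(.data$contig, .data$pos, .data$strand) |>
    dplyr::summarise(n_meth = sum(.data$state == "methylated"),
                     n_inf = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(meth = .data$n_meth * 2L > .data$n_inf)
  w <- agg[agg$strand == "W", ]
  c_ <- agg[agg$strand == "C", ]
  dyads <- dplyr::inner_join(
    dplyr::transmute(w, contig = .data$contig, pos = .data$pos, meth_w = .data$meth),
    dplyr::transmute(c_, contig = .data$contig, pos = .data$pos - 1L, meth_c = .data$meth),
    by = c("contig", "pos"))
  n <- nrow(dyads)
  if (n == 0) {
    return(tibble::tibble(eligible_dyads = 0L, symmetric_rate = NA_real_,
                          asymmetric_rate = NA_real_))
  }
  both <- sum(dyads$meth_w & dyads$meth_c)
  one <- sum(xor(dyads$meth_w, dyads$meth_c))
  tibble::tibble(eligible_dyads = n, symmetric_rate = 100 * both / n,
                 asymmetric_rate = 100 * one / n)
}

#' Coverage statistics of unique placements
#'
#' @param placements Placements with a logical `unique` column (only unique
#'   rows are used) or any placements tibble (then all rows are used).
#' @param genome Named character vector of contig sequences.
#' @return One-row tibble: `covered_positions`, `covered_fraction` (of the
#'   genome), `mean_depth` (aligned bases per covered position; `NA` when
#'   nothing is covered), `consistency_rate` (% of aligned bases matching the
#'   phase-converted reference).
#' @export
coverage_stats <- function(placements, genome) {
  if ("unique" %in% names(placements)) {
    placements <- placements[placements$unique, , drop = FALSE]
  }
  glen <- sum(nchar(genome))
  if (nrow(placements) == 0) {
    return(tibble::tibble(covered_positions = 0L, covered_fraction = 0,
                          mean_depth = NA_real_, consistency_rate = NA_real_))
  }
  lengths <- setNames(nchar(genome), names(genome))
  runs <- placement_m_runs(placements, lengths)
  runs$contig <- placements$contig[runs$pidx]
  covered <- sum(vapply(split(runs, runs$contig), function(rc) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = rc$wstart + 1L,
                                                        end = rc$wend))))
  }, numeric(1)))
  tot_aligned <- sum(placements$n_aligned)
  tibble::tibble(
    covered_positions = as.integer(covered),
    covered_fraction = covered / glen,
    mean_depth = if (covered == 0) NA_real_ else tot_aligned / covered,
    consistency_rate = 100 * sum(placements$n_match) / tot_aligned)
}

#' Per-site methylation counts
#'
#' @param calls Calls tibble.
#' @return Tibble per site: `contig`, `pos` (0-based Watson), `strand`,
#'   `context`, `n_methylated`, `n_unmethylated`, `pct_methylation`.
#' @export
per_site_summary <- function(calls) {
  inf <- calls[calls$state != "uninformative", ]
  if (nrow(inf) == 0) {
    return(tibble::tibble(contig = character(), pos = integer(), strand = character(),
                          context = character(), n_methylated = integer(),
                          n_unmethylated = integer(), pct_methylation = double()))
  }
  inf |>
    dplyr::group_by(.data$contig, .data$pos, .data$strand, .data$context) |>
    dplyr::summarise(n_methylated = sum(.data$state == "methylated"),
                     n_unmethylated = sum(.data$state == "unmethylated"),
                     .groups = "drop") |>
    dplyr::mutate(pct_methylation = 100 * .data$n_methylated /
                    (.data$n_methylated + .data$n_unmethylated)) |>
    dplyr::arrange(.data$contig, .data$pos, .data$strand)
}

#' Full methylation summary of a pipeline run
#'
#' @param calls Calls tibble from [call_methylation()].
#' @param placements Surviving placements (for coverage statistics).
#' @param genome Named character vector of contig sequences.
#' @param conversion_contexts_excluded See [conversion_rate()].
#' @return One-row tibble with conversion rate, raw and conversion-corrected
#'   per-context per-strand methylation rates, SMP rates, symmetric and
#'   asymmetric CpG rates, and coverage statistics.
#' @export
methylation_summary <- function(calls, placements, genome,
                                conversion_contexts_excluded = c("CpG", "CpA")) {
  conv <- conversion_rate(calls, conversion_contexts_excluded)
  mr <- meth_rates(calls)
  rate_of <- function(ctx, s) mr$rate[mr$context == ctx & mr$strand == s]
  smp_g <- smp_rate(calls, "CpG"); smp_a <- smp_rate(calls, "CpA")
  smp_of <- function(tbl, s) tbl$rate[tbl$strand == s]
  sym <- symmetric_asymmetric_rates(calls)
  cov <- coverage_stats(placements, genome)
  tibble::tibble(
    conversion_rate = conv$conversion_rate,
    unconverted_rate = conv$unconverted_rate,
    cpg_watson = rate_of("CpG", "W"), cpg_crick = rate_of("CpG", "C"),
    cpa_watson = rate_of("CpA", "W"), cpa_crick = rate_of("CpA", "C"),
    cpg_watson_corrected = correct_rate(rate_of("CpG", "W"), conv$conversion_rate),
    cpg_crick_corrected = correct_rate(rate_of("CpG", "C"), conv$conversion_rate),
    cpa_watson_corrected = correct_rate(rate_of("CpA", "W"), conv$conversion_rate),
    cpa_crick_corrected = correct_rate(rate_of("CpA", "C"), conv$conversion_rate),
    smp_cpg_watson = smp_of(smp_g, "W"), smp_cpg_crick = smp_of(smp_g, "C"),
    smp_cpa_watson = smp_of(smp_a, "W"), smp_cpa_crick = smp_of(smp_a, "C"),
    symmetric_cpg = sym$symmetric_rate, asymmetric_cpg = sym$asymmetric_rate,
    eligible_dyads = sym$eligible_dyads,
    covered_positions = cov$covered_positions,
    covered_fraction = cov$covered_fraction,
    mean_depth = cov$mean_depth,
    consistency_rate = cov$consistency_rate)
}
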