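# End-to-end orchestration: conversion -> mapping -> filtering -> remapping ->
# methylation calling -> report tables, with file-based stages that compose
# byte-identically with the monolithic run.

#' Pipeline configuration
#'
#' All referenced paths are validated at construction time. Reads may be
#' given as a file (FASTA/FASTQ by extension) or as an in-memory tibble.
#'
#' @param reads_path,reference_path,repeats_path Input files (`repeats_path`
#'   optional). Alternatively pass `reads` / `genome` / `repeats` in memory.
#' @param reads,genome,repeats In-memory inputs (override the paths).
#' @param params [align_params()].
#' @param policy [repeat_policy()].
#' @param out_dir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param min_read_length Reads shorter than this are dropped before mapping
#'   (emulating the instrument's short-read filtration).
#' @param bin_width Bin width for the length-binned profile.
#' @param sd_form Standard-deviation form for the read-length summary.
#' @param raw_wells,key_pass_wells Instrument-level counts for the
#'   read-length report; they cannot be computed from read files and render
#'   as `NA` unless provided.
#' @param sample_name Column label used in report tables.
#' @param conversion_contexts_excluded See [conversion_rate()].
#' @param use_seeds Passed to [map_reads()].
#' @return An object of class `bs_pipeline_config`.
#' @export
pipeline_config <- function(reads_path = NULL, reference_path = NULL,
                            repeats_path = NULL, reads = NULL, genome = NULL,
                            repeats = NULL, params = align_params(),
                            policy = repeat_policy(), out_dir = NULL, seed = 1,
                            min_read_length = 40, bin_width = 40,
                            sd_form = "population", raw_wells = NA,
                            key_pass_wells = NA, sample_name = "sample",
                            conversion_contexts_excluded = c("CpG", "CpA"),
                            use_seeds = NA) {
  for (p in c(reads_path, reference_path, repeats_path)) {
    if (!is.null(p) && !file.exists(p)) bs_abort(sprintf("input path not found: %s", p))
  }
  if (is.null(reads) && is.null(reads_path)) bs_abort("reads or reads_path required")
  if (is.null(genome) && is.null(reference_path)) bs_abort("genome or reference_path required")
  structure(list(reads_path = reads_path, reference_path = reference_path,
                 repeats_path = repeats_path, reads = reads, genome = genome,
                 repeats = repeats, params = params, policy = policy,
                 out_dir = out_dir, seed = as.integer(seed),
                 min_read_length = min_read_length, bin_width = bin_width,
                 sd_form = sd_form, raw_wells = raw_wells,
                 key_pass_wells = key_pass_wells, sample_name = sample_name,
                 conversion_contexts_excluded = conversion_contexts_excluded,
                 use_seeds = use_seeds),
            class = "bs_pipeline_config")
}

load_reads_file <- function(path) {
  if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) read_fastq(path)
  else read_fasta(path, as = "reads")
}

# ---- report table builders --------------------------------------------------

fmt_median <- function(x) {
  if (is.na(x)) "NA" else if (x == round(x)) fmt_int(x) else formatC(x, format = "f", digits = 1)
}

build_table1 <- function(len_sum, raw_wells, key_pass_wells) {
  tibble::tibble(row = TABLE1_ROWS, value = c(
    fmt_int(raw_wells), fmt_int(key_pass_wells), fmt_int(len_sum$n_reads),
    fmt_int(len_sum$total_bases), fmt_num2(len_sum$mean_length),
    fmt_num2(len_sum$sd_length), fmt_int(len_sum$longest),
    fmt_int(len_sum$shortest), fmt_median(len_sum$median_length)))
}

build_table2 <- function(reads, fates, placements, cov) {
  n <- nrow(reads)
  mapped_ids <- fates$read_id[fates$fate %in% c("unique", "multi")]
  uniq_ids <- fates$read_id[fates$fate == "unique"]
  len <- setNames(nchar(reads$bases), reads$id)
  tot_len <- sum(len)
  uniq_len <- sum(len[uniq_ids])
  uniq_bases <- sum(placements$n_aligned[placements$unique])
  pct <- function(a, b) if (b == 0) "NA" else fmt_pct1(100 * a / b, percent_sign = TRUE)
  tibble::tibble(row = TABLE2_ROWS, value = c(
    fmt_int(n), fmt_int(length(mapped_ids)), pct(length(mapped_ids), n),
    fmt_int(length(uniq_ids)), pct(length(uniq_ids), n),
    fmt_int(tot_len), fmt_int(uniq_len), pct(uniq_len, tot_len),
    fmt_int(tot_len), fmt_int(uniq_bases), pct(uniq_bases, tot_len),
    fmt_pct1(cov$consistency_rate, percent_sign = TRUE),
    if (is.na(cov$covered_fraction)) "NA" else formatC(cov$covered_fraction, format = "e", digits = 2),
    fmt_num2(cov$mean_depth)))
}

build_table3 <- function(s) {
  tibble::tibble(row = TABLE3_ROWS, value = fmt_pct1(c(
    s$conversion_rate, s$unconverted_rate,
    s$cpg_watson, s$cpg_crick, s$cpa_watson, s$cpa_crick,
    s$symmetric_cpg, s$asymmetric_cpg,
    s$smp_cpg_watson, s$smp_cpg_crick, s$smp_cpa_watson, s$smp_cpa_crick)))
}

# ---- writers / readers for the stage interfaces -----------------------------

write_mapping_tsv <- function(placements, path) {
  out <- placements
  out$id <- paste0(out$read_id, "/", out$tag)
  out$start <- out$ref_start + 1L
  out$end <- out$ref_end
  cols <- c("id", "read_id", "tag", "contig", "strand", "start", "end", "score",
            "cigar", "qstart", "qend", "aln_start", "aln_end", "n_aligned",
            "n_match")
  extra <- intersect(c("n_classes", "marked_bp", "repeat_overlap_bp", "classes",
                       "unmarked_m", "score_gap", "parent_id", "round", "unique"),
                     names(out))
  readr::write_tsv(out[, c(cols, extra)], path, progress = FALSE)
  invisible(path)
}

read_mapping_tsv <- function(path) {
  type_of <- c(id = "c", read_id = "c", tag = "c", contig = "c", strand = "c",
               start = "i", end = "i", score = "i", cigar = "c", qstart = "i",
               qend = "i", aln_start = "i", aln_end = "i", n_aligned = "i",
               n_match = "i", n_classes = "i", marked_bp = "i",
               repeat_overlap_bp = "i", classes = "c", unmarked_m = "i",
               score_gap = "d", parent_id = "c", round = "i", unique = "l")
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  spec <- paste(unname(type_of[hdr]), collapse = "")
  x <- readr::read_tsv(path, col_types = spec, progress = FALSE, na = "NA")
  x$ref_start <- x$start - 1L
  x$ref_end <- x$end
  x$id <- NULL; x$start <- NULL; x$end <- NULL
  if ("classes" %in% names(x)) x$classes[is.na(x$classes)] <- ""
  tibble::as_tibble(x)
}

write_calls_tsv <- function(calls, path) {
  out <- calls
  out$pos <- out$pos + 1L   # human-facing 1-based
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_calls_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", tag = "c", contig = "c", pos = "i", strand = "c",
    context = "c", state = "c"), progress = FALSE)
  x$pos <- x$pos - 1L
  tibble::as_tibble(x)
}

write_manifest <- function(config, path, n_reads) {
  kv <- c(
    tool = "bisulfitr", version = as.character(utils::packageVersion("bisulfitr")),
    seed = config$seed, n_reads = n_reads,
    min_read_length = config$min_read_length,
    match = config$params$match, mismatch = config$params$mismatch,
    gap_open = config$params$gap_open, gap_extend = config$params$gap_extend,
    min_score = config$params$min_score, unique_margin = config$params$unique_margin,
    z = config$params$z, seed_k = config$params$seed_k,
    min_unmarked_m = config$policy$min_unmarked_m,
    overlap_residual = config$policy$overlap_residual,
    remap_min_len = config$policy$remap_min_len,
    bin_width = config$bin_width, sd_form = config$sd_form,
    conversion_contexts_excluded = paste(config$conversion_contexts_excluded,
                                         collapse = ","))
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

# ---- the pipeline -----------------------------------------------------------

# shared core: everything after inputs are in memory
pipeline_core <- function(reads, genome, repeats, config, cands1 = NULL) {
  reads <- reads[nchar(reads$bases) >= config$min_read_length, , drop = FALSE]
  cref <- build_converted_reference(genome)
  if (is.null(cands1)) {
    cands1 <- if (nrow(reads) > 0) {
      map_reads(tag_reads(reads), cref, config$params, config$use_seeds)
    } else empty_placements()
  }
  mf <- map_filter_reads(reads, cref, repeats, config$params, config$policy,
                         config$use_seeds, cands1 = cands1)
  sites <- site_table(genome)
  calls <- call_methylation(mf$placements, genome, sites)
  summary_stats <- methylation_summary(calls, mf$placements, genome,
                                       config$conversion_contexts_excluded)
  len_sum <- summarize_lengths(reads, config$sd_form)
  profile <- if (nrow(reads) > 0) bin_profile(reads, mf$fates, config$bin_width) else NULL
  cov <- coverage_stats(mf$placements, genome)
  summaries <- list(
    read_length = build_table1(len_sum, config$raw_wells, config$key_pass_wells),
    alignment = build_table2(reads, mf$fates, mf$placements, cov),
    methylation = build_table3(summary_stats))
  structure(list(reads = reads, placements = mf$placements, fates = mf$fates,
                 audit = mf$audit, calls = calls,
                 per_site = per_site_summary(calls),
                 summary_stats = summary_stats, read_length = len_sum,
                 bin_profile = profile, summaries = summaries,
                 candidates = cands1, config = config),
            class = "bs_result")
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mapping_tsv(result$placements, file.path(out_dir, "mapping.tsv"))
  readr::write_tsv(result$fates, file.path(out_dir, "fates.tsv"), progress = FALSE)
  readr::write_tsv(result$audit, file.path(out_dir, "filter_audit.tsv"), progress = FALSE)
  write_calls_tsv(result$calls, file.path(out_dir, "calls.tsv"))
  ps <- result$per_site
  ps$pos <- ps$pos + 1L
  readr::write_tsv(ps, file.path(out_dir, "per_site.tsv"), progress = FALSE)
  if (!is.null(result$bin_profile)) {
    readr::write_tsv(tibble::as_tibble(result$bin_profile),
                     file.path(out_dir, "bin_profile.tsv"), progress = FALSE)
  }
  tmp <- list(summaries = result$summaries)
  class(tmp) <- "bs_result"
  write_report_tables(setNames(list(tmp), result$config$sample_name), out_dir)
  write_manifest(result$config, file.path(out_dir, "manifest.tsv"),
                 nrow(result$reads))
  invisible(out_dir)
}

#' Run the full pipeline
#'
#' Executes conversion, dual-phase mapping, repeat/overlap filtering,
#' iterative remapping, methylation calling and report generation. With
#' `config$out_dir` set, writes the full report bundle (mapping TSV, filter
#' audit, fates, per-site and call TSVs, the three summary tables, the
#' length-bin profile and a run manifest). Deterministic: identical inputs
#' and configuration give byte-identical reports.
#'
#' @param config [pipeline_config()].
#' @return An object of class `bs_result`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bs_pipeline_config"))
  reads <- if (!is.null(config$reads)) config$reads else load_reads_file(config$reads_path)
  genome <- if (!is.null(config$genome)) config$genome else
    read_fasta(config$reference_path, as = "genome")
  repeats <- if (!is.null(config$repeats)) config$repeats else
    if (!is.null(config$repeats_path)) read_repeat_bed(config$repeats_path) else NULL
  result <- pipeline_core(reads, genome, repeats, config)
  if (!is.null(config$out_dir)) write_bundle(result, config$out_dir)
  result
}

#' @export
print.bs_result <- function(x, ...) {
  cat("<bs_result>", nrow(x$reads), "reads;",
      sum(x$fates$fate == "unique"), "unique,",
      sum(x$fates$fate == "multi"), "multi,",
      sum(x$fates$fate == "filtered"), "filtered,",
      sum(x$fates$fate == "unmapped"), "unmapped\n")
  cat("conversion rate:", fmt_pct1(x$summary_stats$conversion_rate), "%\n")
  invisible(x)
}

#' Tidy a pipeline result into the per-site methylation table
#'
#' @param x A `bs_result`.
#' @param ... Unused.
#' @return Per-site tibble (see [per_site_summary()]).
#' @export
tidy.bs_result <- function(x, ...) x$per_site

#' One-row summary of a pipeline result
#'
#' @param x A `bs_result`.
#' @param ... Unused.
#' @return One-row tibble combining read counts, fates and the methylation
#'   summary statistics.
#' @export
glance.bs_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_reads = nrow(x$reads),
                   n_unique = sum(x$fates$fate == "unique"),
                   n_multi = sum(x$fates$fate == "multi"),
                   n_filtered = sum(x$fates$fate == "filtered"),
                   n_unmapped = sum(x$fates$fate == "unmapped")),
    x$summary_stats)
}

# ---- file-based stages (compose byte-identically with run_pipeline) ---------

#' Pipeline stages as file-based subcommands
#'
#' Each stage consumes and produces the documented TSV/FASTQ/BED interfaces
#' so the pipeline can run as independent steps; composing
#' `stage_simulate() |> stage_map() |> stage_filter() |> stage_call() |>
#' stage_report()` writes byte-identical reports to a monolithic
#' [run_pipeline()] call on the same inputs.
#'
#' @param config A [sim_config()] (for `stage_simulate`) — other stages take
#'   explicit paths.
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
stage_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config)
  write_fastq(ds$reads, file.path(out_dir, "reads.fastq"))
  write_fasta(ds$genome, file.path(out_dir, "genome.fa"))
  write_repeat_bed(ds$repeats, file.path(out_dir, "repeats.bed"))
  readr::write_tsv(ds$truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(ds$methylome, file.path(out_dir, "methylome.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' @rdname stage_simulate
#' @param reads_path,reference_path,repeats_path,mapping_path,candidates_path,calls_path
#'   Stage input files.
#' @param params [align_params()].
#' @param min_read_length Reads shorter than this are dropped before mapping.
#' @param use_seeds Passed to [map_reads()].
#' @export
stage_map <- function(reads_path, reference_path, out_dir,
                      params = align_params(), min_read_length = 40,
                      use_seeds = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- load_reads_file(reads_path)
  reads <- reads[nchar(reads$bases) >= min_read_length, , drop = FALSE]
  genome <- read_fasta(reference_path, as = "genome")
  cref <- build_converted_reference(genome)
  cands <- if (nrow(reads) > 0) {
    map_reads(tag_reads(reads), cref, params, use_seeds)
  } else empty_placements()
  write_mapping_tsv(cands, file.path(out_dir, "candidates.tsv"))
  invisible(out_dir)
}

#' @rdname stage_simulate
#' @param policy [repeat_policy()].
#' @export
stage_filter <- function(candidates_path, reads_path, reference_path, out_dir,
                         repeats_path = NULL, params = align_params(),
                         policy = repeat_policy(), min_read_length = 40,
                         use_seeds = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- load_reads_file(reads_path)
  reads <- reads[nchar(reads$bases) >= min_read_length, , drop = FALSE]
  genome <- read_fasta(reference_path, as = "genome")
  repeats <- if (!is.null(repeats_path) && file.size(repeats_path) > 0) {
    read_repeat_bed(repeats_path)
  } else NULL
  cref <- build_converted_reference(genome)
  cands <- read_mapping_tsv(candidates_path)
  cands$bases <- reads$bases[match(cands$read_id, reads$id)]
  res <- map_filter_reads(reads, cref, repeats, params, policy, use_seeds,
                          cands1 = cands)
  write_mapping_tsv(res$placements, file.path(out_dir, "mapping.tsv"))
  readr::write_tsv(res$fates, file.path(out_dir, "fates.tsv"), progress = FALSE)
  readr::write_tsv(res$audit, file.path(out_dir, "filter_audit.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' @rdname stage_simulate
#' @export
stage_call <- function(mapping_path, reads_path, reference_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!file.exists(mapping_path)) {
    bs_abort("stage contract violation: mapping output required before calling")
  }
  placements <- read_mapping_tsv(mapping_path)
  reads <- load_reads_file(reads_path)
  frag_base <- function(ids) {
    # fragment ids look like <id>:s<round>f<1|2>; recover bases by re-splitting
    out <- character(length(ids))
    plain <- !grepl(":s[0-9]+f[12]$", ids)
    out[plain] <- reads$bases[match(ids[plain], reads$id)]
    for (i in which(!plain)) {
      parts <- regmatches(ids[i], regexec("^(.*):s([0-9]+)f([12])$", ids[i]))[[1]]
      root <- parts[2]
      b <- frag_base(root)
      # reconstruct the split chain one level at a time
      mid <- nchar(b) %/% 2L
      out[i] <- if (parts[4] == "1") substr(b, 1L, mid) else
        substr(b, mid + 1L, nchar(b))
    }
    out
  }
  placements$bases <- frag_base(placements$read_id)
  genome <- read_fasta(reference_path, as = "genome")
  calls <- call_methylation(placements, genome)
  write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))
  ps <- per_site_summary(calls)
  ps$pos <- ps$pos + 1L
  readr::write_tsv(ps, file.path(out_dir, "per_site.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' @rdname stage_simulate
#' @param fates_path Fates TSV from `stage_filter`.
#' @param sample_name,bin_width,sd_form,raw_wells,key_pass_wells,conversion_contexts_excluded,seed
#'   Report options, as in [pipeline_config()].
#' @export
stage_report <- function(mapping_path, fates_path, calls_path, reads_path,
                         reference_path, out_dir, sample_name = "sample",
                         bin_width = 40, sd_form = "population",
                         raw_wells = NA, key_pass_wells = NA,
                         conversion_contexts_excluded = c("CpG", "CpA"),
                         min_read_length = 40, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- load_reads_file(reads_path)
  reads <- reads[nchar(reads$bases) >= min_read_length, , drop = FALSE]
  genome <- read_fasta(reference_path, as = "genome")
  placements <- read_mapping_tsv(mapping_path)
  fates <- readr::read_tsv(fates_path, col_types = readr::cols(
    read_id = "c", n_placements = "i", fate = "c", reason = "c"), progress = FALSE)
  calls <- read_calls_tsv(calls_path)
  summary_stats <- methylation_summary(calls, placements, genome,
                                       conversion_contexts_excluded)
  len_sum <- summarize_lengths(reads, sd_form)
  cov <- coverage_stats(placements, genome)
  summaries <- list(read_length = build_table1(len_sum, raw_wells, key_pass_wells),
                    alignment = build_table2(reads, fates, placements, cov),
                    methylation = build_table3(summary_stats))
  tmp <- structure(list(summaries = summaries), class = "bs_result")
  write_report_tables(setNames(list(tmp), sample_name), out_dir)
  if (nrow(reads) > 0) {
    readr::write_tsv(tibble::as_tibble(bin_profile(reads, fates, bin_width)),
                     file.path(out_dir, "bin_profile.tsv"), progress = FALSE)
  }
  invisible(out_dir)
}
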