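# Step 1 of the pipeline: map both tagged versions of each read against both
# strands of the phase-converted reference. The core is an exact affine-gap
# Smith-Waterman (compiled); genome-scale references are mapped by exact
# k-mer seeding followed by the same exact DP inside each candidate window.

#' Alignment parameters
#'
#' Default scoring mirrors the defaults of the long-read external aligner the
#' pipeline can optionally delegate to: match 1, mismatch 3, gap open 5, gap
#' extend 2, minimum reported score 30. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch penalty (positive).
#' @param gap_open Gap-open penalty (positive).
#' @param gap_extend Gap-extend penalty (positive).
#' @param min_score Minimum alignment score for a candidate placement.
#' @param unique_margin A surviving placement is "unique" only if its score
#'   exceeds every alternative-locus candidate by more than this margin.
#' @param z Heuristic band parameter recorded for the external-aligner
#'   adapter (forwarded as its `-z`); it has no effect on the exact DP.
#' @param seed_k Seed k-mer length for genome-scale mapping.
#' @param max_windows Maximum candidate windows examined per query and target.
#' @param band Seed diagonals within this many bp are clustered into one window.
#' @param pad Window padding (bp) around the seeded diagonal range.
#' @param min_seeds Clusters with at least this many seeds are preferred;
#'   if none qualifies the best-supported clusters are examined anyway.
#' @param max_occ Seed k-mers occurring more often than this in the target
#'   (low-complexity sequence in converted space) are skipped.
#' @param seed_min_len References at least this long are mapped with seeding;
#'   shorter ones get a single full DP over the whole contig.
#' @return An object of class `bs_align_params` (a list).
#' @export
align_params <- function(match = 1, mismatch = 3, gap_open = 5, gap_extend = 2,
                         min_score = 30, unique_margin = 0, z = 50,
                         seed_k = 16, max_windows = 8, band = 32, pad = 64,
                         min_seeds = 2, max_occ = 32, seed_min_len = 5000) {
  stopifnot(mismatch > 0, gap_open > 0, gap_extend > 0, min_score >= 0,
            unique_margin >= 0, seed_k >= 4, max_windows >= 1, min_seeds >= 1,
            max_occ >= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score,
                 unique_margin = unique_margin, z = z, seed_k = seed_k,
                 max_windows = max_windows, band = band, pad = pad,
                 min_seeds = min_seeds, max_occ = max_occ,
                 seed_min_len = seed_min_len),
            class = "bs_align_params")
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman local alignment with affine gaps. Deterministic: ties
#' in the recurrence prefer diagonal over gap-in-query over gap-in-read, and
#' the best cell is the first reached in row-major order.
#'
#' @param query,target Non-empty uppercase DNA strings.
#' @param params [align_params()].
#' @return A list: `score`, `qstart`/`qend` and `tstart`/`tend` (0-based
#'   half-open), `cigar` (M/I/D; I = query base not aligned), `n_aligned`
#'   (aligned query bases) and `n_match` (identical aligned bases). A score of
#'   0 denotes the empty alignment.
#' @export
local_align <- function(query, target, params = align_params()) {
  if (!is.character(query) || length(query) != 1 || nchar(query) == 0 ||
      !is.character(target) || length(target) != 1 || nchar(target) == 0) {
    bs_abort("local_align() requires non-empty query and target strings")
  }
  if ((nchar(query) + 1) * (nchar(target) + 1) > 5e7) {
    bs_abort("local_align() inputs too large for full DP; use map_reads() with seeding")
  }
  .cpp_local_align(toupper(query), toupper(target), params$match, params$mismatch,
                   params$gap_open, params$gap_extend)
}

# target spec for the 4 (phase x strand) combinations
phase_targets <- function() {
  tibble::tibble(
    slot = c("watson_ct", "crick_ct", "watson_ga", "crick_ga"),
    tag = c("a", "a", "b", "b"),
    strand = c("W", "C", "W", "C")
  )
}

#' Map tagged reads against a converted reference
#'
#' Each phase-'a' read version is aligned to the C-to-T-converted Watson and
#' Crick strands, each phase-'b' version to the G-to-A-converted strands.
#' Every candidate placement with score at least `params$min_score` is
#' returned, with coordinates on the Watson axis.
#'
#' @param tagged Tibble from [tag_reads()] (`id`, `tag`, `bases`, `converted`).
#' @param cref [build_converted_reference()] output.
#' @param params [align_params()].
#' @param use_seeds `NA` (auto: seed when the contig is at least
#'   `params$seed_min_len` bp), `TRUE`, or `FALSE` (full DP per contig).
#' @return Tibble of candidate placements: `read_id`, `tag`, `contig`,
#'   `strand` (`"W"`/`"C"`), `ref_start`/`ref_end` (0-based half-open, Watson
#'   axis), `aln_start`/`aln_end` (coordinates on the aligned strand),
#'   `qstart`/`qend`, `score`, `cigar`, `n_aligned`, `n_match`, `bases`.
#'   An empty tibble means no read mapped.
#' @export
map_reads <- function(tagged, cref, params = align_params(), use_seeds = NA) {
  stopifnot(inherits(cref, "bs_converted_ref"))
  targets <- phase_targets()
  out <- list()
  for (contig in names(cref$lengths)) {
    L <- unname(cref$lengths[[contig]])
    seeded <- if (is.na(use_seeds)) L >= params$seed_min_len else isTRUE(use_seeds)
    k <- if (seeded) params$seed_k else 0L
    for (r in seq_len(nrow(targets))) {
      sub <- tagged[tagged$tag == targets$tag[r], , drop = FALSE]
      if (nrow(sub) == 0) next
      hits <- .cpp_map_to_target(sub$converted, cref[[targets$slot[r]]][[contig]],
                                 k, params$max_windows, params$band, params$pad,
                                 params$min_score, params$min_seeds, params$max_occ,
                                 params$match, params$mismatch,
                                 params$gap_open, params$gap_extend)
      if (nrow(hits) == 0) next
      str_r <- targets$strand[r]
      out[[length(out) + 1]] <- tibble::tibble(
        read_id = sub$id[hits$query],
        tag = targets$tag[r],
        contig = contig,
        strand = str_r,
        ref_start = if (str_r == "W") hits$tstart else L - hits$tend,
        ref_end = if (str_r == "W") hits$tend else L - hits$tstart,
        aln_start = hits$tstart, aln_end = hits$tend,
        qstart = hits$qstart, qend = hits$qend,
        score = hits$score, cigar = hits$cigar,
        n_aligned = hits$n_aligned, n_match = hits$n_match,
        bases = sub$bases[hits$query]
      )
    }
  }
  if (length(out) == 0) return(empty_placements())
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$read_id, .data$tag, dplyr::desc(.data$score),
                   .data$contig, .data$ref_start,
                   match(.data$strand, c("W", "C")))
}

empty_placements <- function() {
  tibble::tibble(read_id = character(), tag = character(), contig = character(),
                 strand = character(), ref_start = integer(), ref_end = integer(),
                 aln_start = integer(), aln_end = integer(),
                 qstart = integer(), qend = integer(), score = integer(),
                 cigar = character(), n_aligned = integer(), n_match = integer(),
                 bases = character())
}

# ---- external aligner adapter ----------------------------------------------

#' Map reads with the external BWA-SW aligner
#'
#' Optional adapter around `bwa bwasw`, run separately per conversion phase
#' against a FASTA containing both converted strands of every contig. Only
#' forward-orientation hits are kept (reverse-complement alignments mix the
#' two bisulfite spaces and are not meaningful here). The heuristic band
#' parameter `params$z` is forwarded as `-z`. The adapter is never used
#' implicitly; a missing binary is an explicit error, not a silent fallback.
#'
#' @param reads Reads tibble (`id`, `bases`).
#' @param genome Named character vector of contig sequences.
#' @param params [align_params()].
#' @param bwa Path to the `bwa` executable.
#' @param workdir Scratch directory for index and FASTA files.
#' @return Tibble: `read_id`, `tag`, `contig`, `strand`, `ref_start`,
#'   `ref_end` (Watson axis, 0-based half-open), `score` (AS tag, `NA` if
#'   absent), `cigar`.
#' @export
map_with_bwa <- function(reads, genome, params = align_params(),
                         bwa = "bwa", workdir = tempfile("bwa_")) {
  if (Sys.which(bwa) == "" && !file.exists(bwa)) {
    bs_abort(sprintf("external aligner unavailable: '%s' not found", bwa),
             class = "bisulfitr_feature_unavailable")
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  cref <- build_converted_reference(genome)
  tagged <- tag_reads(reads)
  out <- list()
  for (phase in c("a", "b")) {
    slots <- if (phase == "a") c("watson_ct", "crick_ct") else c("watson_ga", "crick_ga")
    ref <- c(setNames(cref[[slots[1]]], paste0(names(genome), "|W")),
             setNames(cref[[slots[2]]], paste0(names(genome), "|C")))
    ref_fa <- file.path(workdir, paste0("ref_", phase, ".fa"))
    reads_fa <- file.path(workdir, paste0("reads_", phase, ".fa"))
    write_fasta(ref, ref_fa)
    sub <- tagged[tagged$tag == phase, ]
    write_fasta(tibble::tibble(id = sub$id, bases = sub$converted), reads_fa)
    system2(bwa, c("index", ref_fa), stdout = FALSE, stderr = FALSE)
    sam <- system2(bwa, c("bwasw", "-z", params$z, ref_fa, reads_fa),
                   stdout = TRUE, stderr = FALSE)
    sam <- sam[!startsWith(sam, "@")]
    for (line in sam) {
      f <- strsplit(line, "\t")[[1]]
      flag <- as.integer(f[2])
      if (bitwAnd(flag, 4L) != 0 || bitwAnd(flag, 16L) != 0) next
      rname <- f[3]
      contig <- sub("\\|[WC]$", "", rname)
      strand <- sub("^.*\\|", "", rname)
      pos0 <- as.integer(f[4]) - 1L
      ops <- cigar_ops(f[6])
      ref_len <- sum(ops$len[ops$op %in% c("M", "D")])
      L <- nchar(genome[[contig]])
      as_tag <- regmatches(line, regexpr("AS:i:[0-9]+", line))
      out[[length(out) + 1]] <- tibble::tibble(
        read_id = f[1], tag = phase, contig = contig, strand = strand,
        ref_start = if (strand == "W") pos0 else L - (pos0 + ref_len),
        ref_end = if (strand == "W") pos0 + ref_len else L - pos0,
        score = if (length(as_tag)) as.integer(sub("AS:i:", "", as_tag)) else NA_integer_,
        cigar = f[6])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(read_id = character(), tag = character(), contig = character(),
                          strand = character(), ref_start = integer(), ref_end = integer(),
                          score = integer(), cigar = character()))
  }
  dplyr::bind_rows(out)
}

# parse a CIGAR string into op lengths/types
cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[A-Z]", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z]", "", parts)),
       op = sub("[0-9]+", "", parts))
}
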