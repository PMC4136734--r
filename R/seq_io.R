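# Readers and writers for the formats the pipeline touches: FASTA, FASTQ
# (Phred+33), BED4 repeat annotations, and the pipeline's own TSV report tables.

#' Read a FASTA file as reads or as a reference genome
#'
#' Sequences are uppercased on input; lowercase FASTA is accepted. With
#' `as = "reads"` the record order of the file is preserved.
#'
#' @param path Path to a FASTA file.
#' @param as Either `"reads"` (a tibble with one row per record) or
#'   `"genome"` (a named character vector of contig sequences).
#' @return For `"reads"`, a tibble with columns `id`, `bases` and a `quality`
#'   list-column (always `NULL` entries for FASTA). For `"genome"`, a named
#'   uppercase character vector over `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path, as = c("reads", "genome")) {
  as <- match.arg(as)
  if (!file.exists(path)) bs_abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) bs_format_error(sprintf("empty FASTA file: %s", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    bs_format_error(sprintf("line %d of %s: expected FASTA header starting with '>'", first, path))
  }
  hdr <- which(startsWith(lines, ">"))
  empty_hdr <- hdr[!nzchar(trimws(sub("^>", "", lines[hdr])))]
  if (length(empty_hdr) > 0L) {
    bs_format_error(sprintf("line %d of %s: empty FASTA header", empty_hdr[1], path))
  }
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  bases <- toupper(as.character(seqs))
  names(bases) <- NULL
  for (i in seq_along(bases)) check_bases(bases[i], sprintf("record '%s'", ids[i]))
  if (as == "genome") {
    if (anyDuplicated(ids)) bs_format_error("duplicate contig names in reference FASTA")
    return(setNames(bases, ids))
  }
  tibble::tibble(id = ids, bases = bases, quality = vector("list", length(ids)))
}

#' Read a FASTQ file (Sanger/Phred+33)
#'
#' Records are 4-line; the '+' line may be bare or repeat the id.
#'
#' @param path Path to a FASTQ file.
#' @return Tibble with columns `id`, `bases`, and `quality` (list-column of
#'   integer Phred scores, one per base).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) bs_abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0 && !nzchar(tail(lines, 1))) lines <- head(lines, -1)
  if (length(lines) %% 4 != 0) {
    bs_format_error(sprintf("truncated FASTQ record %d in %s", length(lines) %/% 4 + 1, path))
  }
  n <- length(lines) %/% 4
  if (n == 0L) return(tibble::tibble(id = character(), bases = character(), quality = list()))
  at <- lines[seq(1, length(lines), by = 4)]
  sq <- lines[seq(2, length(lines), by = 4)]
  pl <- lines[seq(3, length(lines), by = 4)]
  qu <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(at, "@"))
  if (length(bad) > 0L) {
    bs_format_error(sprintf("FASTQ record %d in %s: header does not start with '@'", bad[1], path))
  }
  bad <- which(!startsWith(pl, "+"))
  if (length(bad) > 0L) {
    bs_format_error(sprintf("FASTQ record %d in %s: separator line does not start with '+'", bad[1], path))
  }
  bad <- which(nchar(qu) != nchar(sq))
  if (length(bad) > 0L) {
    bs_format_error(sprintf(
      "FASTQ record %d in %s: quality length %d != sequence length %d",
      bad[1], path, nchar(qu[bad[1]]), nchar(sq[bad[1]])))
  }
  bases <- toupper(sq)
  for (i in seq_len(n)) check_bases(bases[i], sprintf("FASTQ record %d", i))
  ids <- vapply(strsplit(sub("^@", "", at), "\\s+"), `[`, character(1), 1)
  quality <- lapply(qu, function(q) utf8ToInt(q) - 33L)
  tibble::tibble(id = ids, bases = bases, quality = quality)
}

#' Write reads or a genome to FASTA / reads to FASTQ
#'
#' @param x A reads tibble (`id`, `bases`, optional `quality`) or a named
#'   character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    ids <- names(x); seqs <- unname(x)
  } else {
    ids <- x$id; seqs <- x$bases
  }
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(x, path) {
  qual <- if ("quality" %in% names(x)) {
    vapply(seq_len(nrow(x)), function(i) {
      q <- x$quality[[i]]
      if (is.null(q)) strrep("I", nchar(x$bases[i])) else intToUtf8(q + 33L)
    }, character(1))
  } else {
    strrep("I", nchar(x$bases))
  }
  writeLines(as.vector(rbind(paste0("@", x$id), x$bases, "+", qual)), path)
  invisible(path)
}

#' Read a BED4 repeat-annotation file
#'
#' Tab-separated with at least 4 columns: contig, start, end, repeat class.
#' BED convention: 0-based, half-open. Output is sorted by (contig, start);
#' class labels are kept verbatim.
#'
#' @param path Path to the BED file.
#' @return Tibble with columns `contig`, `start`, `end`, `repeat_class`.
#' @export
read_repeat_bed <- function(path) {
  if (!file.exists(path)) bs_abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), repeat_class = character()))
  }
  if (ncol(raw) < 4L) {
    bs_format_error(sprintf("%s: BED4 requires >= 4 columns, found %d", path, ncol(raw)))
  }
  start_c <- raw[[2]]; end_c <- raw[[3]]
  bad <- which(!grepl("^[0-9]+$", start_c) | !grepl("^[0-9]+$", end_c))
  if (length(bad) > 0L) {
    bs_format_error(sprintf("%s line %d: non-integer coordinates", path, bad[1]))
  }
  start <- as.integer(start_c); end <- as.integer(end_c)
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    bs_format_error(sprintf("%s line %d: start (%d) >= end (%d)", path, bad[1], start[bad[1]], end[bad[1]]))
  }
  tibble::tibble(contig = raw[[1]], start = start, end = end, repeat_class = raw[[4]]) |>
    dplyr::arrange(.data$contig, .data$start)
}

#' @rdname read_repeat_bed
#' @param repeats Tibble as returned by [read_repeat_bed()].
#' @export
write_repeat_bed <- function(repeats, path) {
  readr::write_tsv(repeats, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- report tables ----------------------------------------------------------

TABLE1_ROWS <- c("Raw wells", "Key pass wells", "Passed filter wells", "Total bases",
                 "Length average", "Length std deviation", "Longest read length",
                 "Shortest read length", "Median read length")

TABLE2_ROWS <- c("Total number of reads", "Total number of reads mapped",
                 "Total number of reads mapped/Total number of reads",
                 "Total number of reads uniquely mapped",
                 "Total number of reads uniquely mapped/Total number of reads",
                 "Total length (bp) of all reads", "Total length (bp) of unique mapped reads",
                 "Total length of unique mapped reads/Total length of all reads",
                 "Total bases of all reads", "Total bases of unique mapped reads",
                 "Total bases of unique mapped reads/Total bases of all reads",
                 "Consistency rate", "Total number of bases covered in the human genome",
                 "Depth (x-fold)")

TABLE3_ROWS <- c("Conversion rate", "Unconverted rate",
                 "Methylation rate of CpG on Watson", "Methylation rate of CpG on Crick",
                 "Methylation rate of CpA on Watson", "Methylation rate of CpA on Crick",
                 "Symmetrical methylation rate of CpG", "Asymmetrical methylation rate of CpG",
                 "Single methylation polymorphism rate of CpG on Watson",
                 "Single methylation polymorphism rate of CpG on Crick",
                 "Single methylation polymorphism rate of CpA on Watson",
                 "Single methylation polymorphism rate of CpA on Crick")

#' Write the three summary report tables
#'
#' Writes `read_length_summary.tsv`, `alignment_summary.tsv` and
#' `methylation_summary.tsv` into `out_dir`, one value column per sample.
#'
#' @param summaries Either a single pipeline result (see [run_pipeline()]) or
#'   a named list of them; names become the value-column headers.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_report_tables <- function(summaries, out_dir) {
  if (inherits(summaries, "bs_result")) summaries <- list(sample = summaries)
  if (is.null(names(summaries))) names(summaries) <- paste0("sample", seq_along(summaries))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) bs_abort(sprintf("cannot create output directory: %s", out_dir))

  grab <- function(which) {
    cols <- lapply(summaries, function(s) s$summaries[[which]]$value)
    labs <- summaries[[1]]$summaries[[which]]$row
    tibble::as_tibble(c(list(row = labs), setNames(cols, names(summaries))))
  }
  paths <- file.path(out_dir, c("read_length_summary.tsv", "alignment_summary.tsv",
                                "methylation_summary.tsv"))
  readr::write_tsv(grab("read_length"), paths[1], progress = FALSE)
  readr::write_tsv(grab("alignment"), paths[2], progress = FALSE)
  readr::write_tsv(grab("methylation"), paths[3], progress = FALSE)
  invisible(paths)
}
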