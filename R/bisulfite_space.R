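# The two in-silico bisulfite conversion phases. Phase 'a' collapses C->T,
# phase 'b' collapses G->A; both the reads and the reference are converted so
# that alignment happens in the reduced three-letter space where the
# methylation-dependent C/T (G/A) difference no longer penalises mapping.

#' Collapse cytosines / guanines for three-letter alignment
#'
#' `convert_ct()` replaces every `C` with `T`; `convert_ga()` replaces every
#' `G` with `A`. All other bases (including `N`) pass through unchanged.
#' Vectorised over sequences.
#'
#' @param seq Character vector of uppercase DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of converted sequences, same lengths.
#' @export
#' @examples
#' convert_ct("ACGT")  # "ATGT"
#' convert_ga("ACGT")  # "ACAT"
convert_ct <- function(seq) {
  stopifnot(is.character(seq))
  check_bases(seq)
  chartr("C", "T", seq)
}

#' @rdname convert_ct
#' @export
convert_ga <- function(seq) {
  stopifnot(is.character(seq))
  check_bases(seq)
  chartr("G", "A", seq)
}

#' Tag reads with both conversion phases
#'
#' Each read yields two versions: tag `'a'` (C-to-T converted) and tag `'b'`
#' (G-to-A converted). The original bases are retained alongside the converted
#' ones; the later methylation readout uses only the original bases.
#'
#' @param reads Reads tibble with columns `id` and `bases`.
#' @return Tibble with one row per (read, tag): columns `id`, `tag`
#'   (`"a"`/`"b"`), `bases` (original) and `converted`.
#' @export
tag_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "bases") %in% names(reads)))
  if (nrow(reads) > 0 && any(nchar(reads$bases) == 0L)) {
    bs_abort(sprintf("empty read: '%s'", reads$id[which(nchar(reads$bases) == 0L)[1]]))
  }
  dplyr::bind_rows(
    tibble::tibble(id = reads$id, tag = "a", bases = reads$bases,
                   converted = convert_ct(reads$bases)),
    tibble::tibble(id = reads$id, tag = "b", bases = reads$bases,
                   converted = convert_ga(reads$bases))
  ) |>
    dplyr::arrange(match(.data$id, reads$id), .data$tag)
}

#' Build the phase-converted reference
#'
#' For every contig, four sequences are derived: the Watson strand and the
#' Crick strand (reverse complement), each converted in both phases
#' (C-to-T and G-to-A).
#'
#' @param genome Named character vector of contig sequences (Watson strand).
#' @return An object of class `bs_converted_ref`: a list with named character
#'   vectors `watson_ct`, `watson_ga`, `crick_ct`, `crick_ga`, and integer
#'   `lengths` per contig.
#' @export
build_converted_reference <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  check_bases(genome)
  crick <- revcomp(genome)
  names(crick) <- names(genome)
  structure(list(
    watson_ct = convert_ct(genome),
    watson_ga = convert_ga(genome),
    crick_ct = convert_ct(crick),
    crick_ga = convert_ga(crick),
    lengths = setNames(nchar(genome), names(genome))
  ), class = "bs_converted_ref")
}

#' @export
print.bs_converted_ref <- function(x, ...) {
  cat("<bs_converted_ref>", length(x$lengths), "contig(s),",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  invisible(x)
}
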