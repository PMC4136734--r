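# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T", "N")

# abort with a class so tests can target format errors specifically
bs_abort <- function(msg, class = "bisulfitr_error") {
  rlang::abort(msg, class = class)
}

bs_format_error <- function(msg) bs_abort(msg, class = "bisulfitr_format_error")

check_bases <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  i <- which(bad > 0L)
  if (length(i) > 0L) {
    bs_abort(sprintf(
      "invalid character '%s' at position %d of %s",
      substr(seq[i[1]], bad[i[1]], bad[i[1]]), bad[i[1]], what))
  }
  invisible(seq)
}

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over `{A,C,G,T,N}`; `N` maps to `N`.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  check_bases(toupper(seq))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
  unname(out)
}

# format a percentage to 1 decimal, NA -> "NA"
fmt_pct1 <- function(x, percent_sign = FALSE) {
  ifelse(is.na(x), "NA",
         paste0(formatC(x, format = "f", digits = 1), if (percent_sign) "%" else ""))
}

fmt_num2 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 2))

fmt_int <- function(x) ifelse(is.na(x), "NA", format(x, scientific = FALSE, trim = TRUE))
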