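# Read-length summary statistics and length-binned mapped/unique profiles.

#' Read length summary
#'
#' @param reads Reads tibble (`id`, `bases`).
#' @param sd_form `"population"` (divide by N) or `"sample"` (N - 1).
#' @return One-row tibble: `n_reads`, `total_bases`, `mean_length`,
#'   `sd_length`, `longest`, `shortest`, `median_length`. With no reads the
#'   statistics are `NA` and `n_reads` is 0.
#' @export
summarize_lengths <- function(reads, sd_form = c("population", "sample")) {
  sd_form <- match.arg(sd_form)
  len <- nchar(reads$bases)
  n <- length(len)
  if (n == 0) {
    return(tibble::tibble(n_reads = 0L, total_bases = 0L, mean_length = NA_real_,
                          sd_length = NA_real_, longest = NA_integer_,
                          shortest = NA_integer_, median_length = NA_real_))
  }
  s <- if (n == 1) 0 else sd(len)
  if (sd_form == "population") s <- s * sqrt((n - 1) / n)
  tibble::tibble(n_reads = n, total_bases = sum(len), mean_length = mean(len),
                 sd_length = s, longest = max(len), shortest = min(len),
                 median_length = median(len))
}

#' Length-binned mapped / unique read profile
#'
#' Histogram over `[40, max length]` with fixed-width bins; reads shorter
#' than the first edge are counted in the first bin and the last bin is
#' closed, so no read is lost at the edges.
#'
#' @param reads Reads tibble (`id`, `bases`).
#' @param fates Fates tibble from [map_filter_reads()] (`read_id`, `fate`).
#' @param bin_width Bin width in bp.
#' @return A tibble of class `bs_bin_profile`: `bin_start`, `bin_end`,
#'   `n_all`, `n_mapped`, `n_unique`, `mapped_all` (mapped/all ratio),
#'   `unique_all`, `unique_mapped` (`NA` where the denominator is 0).
#' @export
bin_profile <- function(reads, fates, bin_width = 40) {
  stopifnot(bin_width >= 1)
  len <- nchar(reads$bases)
  fate <- fates$fate[match(reads$id, fates$read_id)]
  mapped <- fate %in% c("unique", "multi")
  uniq <- fate == "unique"
  lo <- 40L
  hi <- max(c(len, lo))
  edges <- seq(lo, hi + bin_width, by = bin_width)
  bin <- pmax(1L, findInterval(len, edges))
  nb <- length(edges) - 1L
  tab <- function(x) tabulate(bin[x], nbins = nb)
  out <- tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    n_all = tabulate(bin, nbins = nb),
    n_mapped = tab(mapped),
    n_unique = tab(uniq))
  out$mapped_all <- ifelse(out$n_all > 0, out$n_mapped / out$n_all, NA_real_)
  out$unique_all <- ifelse(out$n_all > 0, out$n_unique / out$n_all, NA_real_)
  out$unique_mapped <- ifelse(out$n_mapped > 0, out$n_unique / out$n_mapped, NA_real_)
  class(out) <- c("bs_bin_profile", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Plot a length-binned mapping profile
#'
#' @param object A [bin_profile()] result.
#' @param ratio Which ratio series to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bs_bin_profile <- function(object, ratio = c("mapped_all", "unique_all",
                                                      "unique_mapped"), ...) {
  ratio <- match.arg(ratio)
  labs <- c(mapped_all = "mapped / all reads", unique_all = "unique / all reads",
            unique_mapped = "unique / mapped reads")
  df <- as.data.frame(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data[[ratio]])) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9,
                      fill = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = "read length (bp)", y = labs[[ratio]]) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bs_bin_profile
#' @param profile A [bin_profile()] result.
#' @export
plot_bin_profile <- function(profile, ratio = "mapped_all") {
  autoplot(profile, ratio = ratio)
}
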