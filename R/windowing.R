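#' Place fully accessible windows under the mask
#'
#' Tiles each accessible mask interval from its start with non-overlapping
#' windows of `size` bp; a remainder shorter than `size` is discarded, and no
#' window ever spans two intervals or overlaps a non-accessible base.
#'
#' @param mask an [access_mask].
#' @param size window size in bp (default 10000).
#' @return A data.frame of windows with columns `chrom`, `start`, `end`,
#'   `accessible_bases` (= `size`), `scheme = "fully_accessible"`.
#' @export
place_accessible_windows <- function(mask, size = 10000) {
  if (size <= 0) stop("window size must be positive")
  out <- list()
  for (ch in names(mask)) {
    iv <- mask[[ch]]
    for (i in seq_len(nrow(iv))) {
      k <- (iv[i, 2L] - iv[i, 1L]) %/% size
      if (k < 1) next
      s <- iv[i, 1L] + size * (seq_len(k) - 1)
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start = s, end = s + size,
                   accessible_bases = size, scheme = "fully_accessible",
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), accessible_bases = numeric(0),
                      scheme = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Place fixed-size windows along whole chromosomes
#'
#' Tiles each chromosome from coordinate 0 with `size`-bp windows; the last
#' partial window is retained with its true extent. Each window records the
#' number of mask-accessible bases it contains, the per-site denominator for
#' downstream statistics (a fully masked-out window has 0 and its statistics
#' are reported missing).
#'
#' @param chromosome_sizes named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 100000).
#' @param mask an [access_mask].
#' @return A data.frame of windows with `scheme = "fixed"`.
#' @export
place_fixed_windows <- function(chromosome_sizes, size = 100000, mask) {
  if (size <= 0) stop("window size must be positive")
  if (any(chromosome_sizes <= 0)) stop("chromosome sizes must be positive")
  out <- list()
  for (ch in names(chromosome_sizes)) {
    len <- chromosome_sizes[[ch]]
    s <- seq(0, len - 1, by = size)
    e <- pmin(s + size, len)
    acc <- vapply(seq_along(s), function(i) accessible_bases(mask, ch, s[i], e[i]), 0)
    out[[length(out) + 1L]] <-
      data.frame(chrom = ch, start = s, end = e, accessible_bases = acc,
                 scheme = "fixed", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-window recombination rate from a genetic map
#'
#' (cM at window end - cM at window start) / window length in Mb, with cM
#' values obtained by linear interpolation ([interpolate_cM]); windows beyond
#' the map range clamp to terminal cM values and so get rate 0.
#'
#' @param map a [genetic_map].
#' @param windows a windows data.frame (`start`, `end`).
#' @return Numeric vector of cM/Mb, one per window.
#' @export
window_recomb_rate <- function(map, windows) {
  cm_s <- interpolate_cM(map, windows$start)
  cm_e <- interpolate_cM(map, windows$end)
  (cm_e - cm_s) / ((windows$end - windows$start) / 1e6)
}

#' Read UCSC-style chrom.sizes (two-column TSV)
#'
#' @param path path to a `chrom<TAB>size` table.
#' @return Named numeric vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$size, tab$chrom)
}
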