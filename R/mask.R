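#' Accessibility mask
#'
#' A per-chromosome set of genomic intervals (0-based, half-open) within which
#' short-read variant calling is considered reliable. Window placement and all
#' per-site denominators are restricted to accessible positions.
#'
#' @param intervals named list; one element per chromosome, each a two-column
#'   matrix or data.frame of `start`, `end` (0-based half-open). Intervals are
#'   sorted and merged (overlapping or book-ended runs collapse to one).
#' @return An object of class `access_mask`: a named list of normalized
#'   two-column integer matrices.
#' @export
access_mask <- function(intervals) {
  stopifnot(is.list(intervals))
  out <- lapply(intervals, function(iv) {
    iv <- as.matrix(iv)
    if (ncol(iv) < 2L) stop("mask intervals need start and end columns")
    storage.mode(iv) <- "double"
    if (nrow(iv) == 0L) {
      m <- matrix(numeric(0), ncol = 2L)
    } else {
      if (any(iv[, 1L] >= iv[, 2L]))
        stop("mask interval with start >= end")
      ir <- IRanges::reduce(IRanges::IRanges(start = iv[, 1L] + 1, end = iv[, 2L]))
      m <- cbind(IRanges::start(ir) - 1, IRanges::end(ir))
    }
    colnames(m) <- c("start", "end")
    m
  })
  structure(out, class = "access_mask")
}

#' Read an accessibility mask from a BED file
#'
#' BED intervals are 0-based half-open; per chromosome they are sorted and
#' merged so the stored mask is disjoint and non-adjacent.
#'
#' @param path path to a BED file (>= 3 columns).
#' @return An [access_mask] object.
#' @export
read_mask_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(access_mask(list()))
  fields <- strsplit(lines, "\t| +")
  chrom <- character(length(fields))
  start <- numeric(length(fields))
  end <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed BED line %d: non-numeric coordinates", i))
    if (s >= e)
      stop(sprintf("BED line %d: start >= end (%s >= %s)", i, f[2L], f[3L]))
    chrom[i] <- f[1L]; start[i] <- s; end[i] <- e
  }
  access_mask(split(data.frame(start = start, end = end), chrom))
}

#' @export
print.access_mask <- function(x, ...) {
  nb <- vapply(x, function(m) sum(m[, 2L] - m[, 1L]), numeric(1))
  cat(sprintf("Accessibility mask: %d chromosome(s), %.0f accessible bases\n",
              length(x), sum(nb)))
  for (ch in names(x))
    cat(sprintf("  %s: %d interval(s), %.0f bp\n", ch, nrow(x[[ch]]), nb[[ch]]))
  invisible(x)
}

## IRanges view of one chromosome's intervals (1-based closed, internal)
mask_ranges <- function(mask, chrom) {
  iv <- mask[[chrom]]
  if (is.null(iv) || nrow(iv) == 0L) return(IRanges::IRanges())
  IRanges::IRanges(start = iv[, 1L] + 1, end = iv[, 2L])
}

#' Count accessible bases within an interval
#'
#' @param mask an [access_mask].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Number of mask-accessible positions inside `[start, end)`.
#' @export
accessible_bases <- function(mask, chrom, start, end) {
  ir <- mask_ranges(mask, chrom)
  if (length(ir) == 0L) return(0)
  win <- IRanges::IRanges(start = start + 1, end = end)
  sum(IRanges::width(IRanges::intersect(ir, win)))
}

## logical accessibility of a vector of 0-based positions
is_accessible <- function(mask, chrom, pos) {
  iv <- mask[[chrom]]
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  ir <- mask_ranges(mask, chrom)
  IRanges::overlapsAny(IRanges::IRanges(pos + 1, pos + 1), ir)
}

## all accessible 0-based positions in [start, end)
accessible_positions <- function(mask, chrom, start, end) {
  iv <- mask[[chrom]]
  if (is.null(iv) || nrow(iv) == 0L) return(numeric(0))
  s <- pmax(iv[, 1L], start); e <- pmin(iv[, 2L], end)
  keep <- s < e
  if (!any(keep)) return(numeric(0))
  unlist(lapply(which(keep), function(i) seq(s[i], e[i] - 1)), use.names = FALSE)
}
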