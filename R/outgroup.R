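#' Outgroup alignment track
#'
#' Per-position outgroup allele calls derived from a pairwise reference-vs-
#' outgroup alignment. Positions are reference coordinates (0-based); a
#' position is "aligned" when the outgroup column holds an unambiguous base.
#'
#' @param chrom chromosome name.
#' @param offset reference coordinate of the first alignment column (0-based).
#' @param ref character vector of reference bases, one per reference position.
#' @param call character vector of outgroup calls (`NA` where unaligned).
#' @return An object of class `outgroup_track`.
#' @export
outgroup_track <- function(chrom, offset, ref, call) {
  stopifnot(length(ref) == length(call))
  structure(list(chrom = chrom, offset = offset, ref = ref, call = call),
            class = "outgroup_track")
}

#' @export
print.outgroup_track <- function(x, ...) {
  cat(sprintf("Outgroup track %s:[%d,%d): %d positions, %.1f%% aligned\n",
              x$chrom, x$offset, x$offset + length(x$ref), length(x$ref),
              100 * mean(!is.na(x$call))))
  invisible(x)
}

#' Convert a two-sequence pairwise alignment (MFA) to an outgroup track
#'
#' The first sequence is the reference species, the second the outgroup, both
#' over the same alignment columns. Columns with a reference gap consume no
#' reference coordinate; columns where the outgroup shows a gap or `N` are
#' recorded as unaligned. Soft-masked (lowercase) bases are valid calls.
#'
#' @param path path to a multi-FASTA file holding exactly two aligned
#'   sequences of equal length.
#' @param offset reference coordinate (0-based) of the first reference base.
#' @param chrom chromosome name for the track (default: first sequence name).
#' @return An [outgroup_track].
#' @export
pairwise_mfa_to_outgroup <- function(path, offset = 0, chrom = NULL) {
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) != 2L)
    stop(sprintf("expected exactly 2 aligned sequences, found %d", length(aln)))
  refs <- toupper(as.character(aln[[1L]]))
  outs <- toupper(as.character(aln[[2L]]))
  if (nchar(refs) != nchar(outs))
    stop("aligned sequences have unequal lengths")
  if (is.null(chrom)) chrom <- sub("\\s.*$", "", names(aln)[1L])
  rc <- strsplit(refs, "")[[1L]]
  oc <- strsplit(outs, "")[[1L]]
  keep <- rc != "-"                      # reference gaps consume no coordinate
  rc <- rc[keep]; oc <- oc[keep]
  call <- ifelse(oc %in% c("A", "C", "G", "T"), oc, NA_character_)
  outgroup_track(chrom, offset, ref = rc, call = call)
}

## outgroup call at 0-based positions (NA outside track or unaligned)
outgroup_call_at <- function(track, pos) {
  idx <- pos - track$offset + 1
  ok <- idx >= 1 & idx <= length(track$call)
  out <- rep(NA_character_, length(pos))
  out[ok] <- track$call[idx[ok]]
  out
}

## is each 0-based position covered by an unambiguous outgroup base
outgroup_aligned_at <- function(track, pos) {
  !is.na(outgroup_call_at(track, pos))
}
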