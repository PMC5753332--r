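#' Gene model
#'
#' One transcript of a protein-coding gene: exon and CDS segments plus derived
#' UTRs, all as 0-based half-open intervals on the forward strand, with the
#' coding strand recorded. A model whose total CDS length is not a multiple
#' of 3 is flagged non-codable and contributes only non-coding site classes.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds two-column matrices of 0-based half-open segments.
#' @param flank_size intergenic flank size in bp (default 500).
#' @return An object of class `gene_model` with fields `utr5`, `utr3`
#'   (derived from `exons` minus `cds`) and `codable`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons, cds,
                       flank_size = 500) {
  stopifnot(strand %in% c("+", "-"))
  exons <- norm_segments(exons)
  cds <- norm_segments(cds)
  utr <- segment_setdiff(exons, cds)
  if (nrow(cds)) {
    cds_start <- min(cds[, 1L]); cds_end <- max(cds[, 2L])
    left <- utr[utr[, 2L] <= cds_start, , drop = FALSE]
    right <- utr[utr[, 1L] >= cds_end, , drop = FALSE]
  } else {
    left <- utr; right <- utr[0, , drop = FALSE]
  }
  if (strand == "+") { utr5 <- left; utr3 <- right } else { utr5 <- right; utr3 <- left }
  codable <- nrow(cds) > 0L && sum(cds[, 2L] - cds[, 1L]) %% 3 == 0
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3, flank_size = flank_size,
                 codable = codable,
                 start = min(exons[, 1L]), end = max(exons[, 2L])),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s (%s) %s:%d-%d [%s], %d exon(s), CDS %d bp%s\n",
              x$gene_id, x$transcript_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), sum(x$cds[, 2L] - x$cds[, 1L]),
              if (x$codable) "" else " (non-codable)"))
  invisible(x)
}

norm_segments <- function(seg) {
  seg <- as.matrix(seg)
  if (length(seg) == 0L) seg <- matrix(numeric(0), ncol = 2L)
  storage.mode(seg) <- "double"
  seg <- seg[order(seg[, 1L]), , drop = FALSE]
  colnames(seg) <- c("start", "end")
  seg
}

## set difference of 0-based half-open segment lists
segment_setdiff <- function(a, b) {
  ia <- IRanges::IRanges(a[, 1L] + 1, a[, 2L])
  ib <- IRanges::IRanges(b[, 1L] + 1, b[, 2L])
  d <- IRanges::setdiff(ia, ib)
  norm_segments(cbind(IRanges::start(d) - 1, IRanges::end(d)))
}

## all 0-based positions covered by a segment matrix
segment_positions <- function(seg) {
  if (nrow(seg) == 0L) return(numeric(0))
  unlist(lapply(seq_len(nrow(seg)),
                function(i) seq(seg[i, 1L], seg[i, 2L] - 1)), use.names = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon/CDS features with `ID`/`Parent` links; 1-based
#' inclusive GFF3 coordinates are converted to 0-based half-open. One
#' [gene_model] is returned per transcript; UTRs are derived as exon minus
#' CDS. Transcripts whose CDS length is not divisible by 3 are retained but
#' flagged non-codable.
#'
#' @param path path to a GFF3 file.
#' @param flank_size intergenic flank in bp attached to each model.
#' @return A list of [gene_model] objects.
#' @export
read_gene_models <- function(path, flank_size = 500) {
  g <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(g)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(g))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_, "")
  } else rep(NA_character_, length(g))
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  models <- list()
  for (i in tx_idx) {
    tid <- ids[i]
    gid <- parents[i]
    if (is.na(gid)) gid <- tid
    child <- which(parents == tid)
    ex <- child[type[child] == "exon"]
    cd <- child[type[child] == "CDS"]
    seg <- function(idx) {
      if (length(idx) == 0L) return(matrix(numeric(0), ncol = 2L))
      cbind(GenomicRanges::start(g)[idx] - 1, GenomicRanges::end(g)[idx])
    }
    exseg <- seg(ex)
    if (nrow(exseg) == 0L) exseg <- cbind(GenomicRanges::start(g)[i] - 1,
                                          GenomicRanges::end(g)[i])
    models[[length(models) + 1L]] <-
      gene_model(gene_id = gid, transcript_id = tid,
                 chrom = as.character(GenomicRanges::seqnames(g)[i]),
                 strand = as.character(GenomicRanges::strand(g)[i]),
                 exons = exseg, cds = seg(cd), flank_size = flank_size)
  }
  models
}

#' Pick one transcript per gene: the longest codable one
#'
#' Deterministic collapse of multi-transcript genes: among each gene's
#' codable transcripts the one with the longest total CDS wins (ties broken
#' by transcript id); genes with no codable transcript keep their longest
#' transcript, flagged non-codable.
#'
#' @param models list of [gene_model] objects.
#' @return A list with one [gene_model] per `gene_id`.
#' @export
longest_transcript_per_gene <- function(models) {
  by_gene <- split(models, vapply(models, `[[`, "", "gene_id"))
  lapply(by_gene, function(ms) {
    codable <- vapply(ms, `[[`, TRUE, "codable")
    pool <- if (any(codable)) ms[codable] else ms
    len <- vapply(pool, function(m)
      if (nrow(m$cds)) sum(m$cds[, 2L] - m$cds[, 1L]) else m$end - m$start, 0)
    tid <- vapply(pool, `[[`, "", "transcript_id")
    pool[[order(-len, tid)[1L]]]
  })
}
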