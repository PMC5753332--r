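#' Phased haplotype panel
#'
#' The central polymorphism container: a binary matrix of phased haplotypes
#' (rows = 2N haplotypes, columns = biallelic SNP sites), with 0-based site
#' positions, REF/ALT alleles, a per-site ancestral state, and a
#' sample-to-population assignment.
#'
#' @param chrom chromosome name.
#' @param pos integer vector of 0-based site positions, strictly increasing.
#' @param hap binary matrix, `2 * length(samples)` rows by `length(pos)`
#'   columns; 0 = reference allele, 1 = alternate.
#' @param ref,alt single-base REF and ALT alleles per site.
#' @param ancestral per-site ancestral state, one of `"ref"`, `"alt"`,
#'   `"unknown"`.
#' @param samples ordered sample identifiers; haplotype rows `2i - 1` and
#'   `2i` belong to sample `i`.
#' @param pops named character vector mapping sample id to population label.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(chrom, pos, hap, ref, alt, ancestral, samples, pops) {
  pos <- as.numeric(pos)
  hap <- as.matrix(hap)
  if (length(pos) > 1L && any(diff(pos) <= 0))
    stop("site positions must be strictly increasing")
  if (ncol(hap) != length(pos))
    stop("haplotype matrix has ", ncol(hap), " columns for ", length(pos), " sites")
  if (nrow(hap) != 2L * length(samples))
    stop("haplotype matrix must have 2 rows per sample")
  if (length(pos) && !all(hap %in% c(0, 1)))
    stop("haplotype matrix entries must be 0/1")
  if (!all(samples %in% names(pops)))
    stop("samples missing from population map: ",
         paste(setdiff(samples, names(pops)), collapse = ", "))
  ancestral <- rep_len(as.character(ancestral), length(pos))
  if (length(pos) && !all(ancestral %in% c("ref", "alt", "unknown")))
    stop("ancestral states must be 'ref', 'alt' or 'unknown'")
  structure(list(chrom = chrom, pos = pos, hap = hap,
                 ref = rep_len(as.character(ref), length(pos)),
                 alt = rep_len(as.character(alt), length(pos)),
                 ancestral = ancestral,
                 samples = as.character(samples),
                 pops = pops[samples],
                 outgroup = rep(NA_character_, length(pos)),
                 three_state = rep(FALSE, length(pos)),
                 div_only = numeric(0)),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("Phased haplotype panel: %s, %d sites, %d samples (%d haplotypes)\n",
              x$chrom, length(x$pos), length(x$samples), nrow(x$hap)))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d)", names(table(x$pops)), table(x$pops)),
                    collapse = ", ")))
  cat(sprintf("  polarized sites: %d; outgroup-annotated: %d; divergence-only records: %d\n",
              sum(x$ancestral != "unknown"), sum(!is.na(x$outgroup)),
              length(x$div_only)))
  invisible(x)
}

#' Number of haplotypes in a panel (optionally one population)
#' @param panel a [hap_panel].
#' @param pop optional population label.
#' @return Integer haplotype count.
#' @export
n_haplotypes <- function(panel, pop = NULL) length(hap_rows(panel, pop))

## row indices of the haplotypes belonging to a population (NULL = all)
hap_rows <- function(panel, pop = NULL) {
  if (is.null(pop)) return(seq_len(nrow(panel$hap)))
  keep <- which(panel$pops == pop)
  if (length(keep) == 0L)
    stop("population not present in panel: ", pop)
  sort(c(2L * keep - 1L, 2L * keep))
}

## column indices of sites inside [start, end)
sites_in <- function(panel, start, end) {
  which(panel$pos >= start & panel$pos < end)
}

#' Read a phased VCF into a haplotype panel
#'
#' Retains biallelic SNPs only (multi-allelic records, indels and structural
#' variants are dropped), converts VCF 1-based positions to 0-based internal
#' coordinates, and polarizes sites from the `AA` INFO annotation when
#' present. Phasing is mandatory: any `/`-separated genotype among retained
#' samples is an error.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param panel sample-to-population assignment: a two-column data.frame
#'   (`sample`, `population`) or the path of a two-column TSV.
#' @param region optional `c(start, end)` 0-based half-open interval filter.
#' @param exclude_samples sample ids to drop before building the matrix
#'   (e.g. reportedly inbred individuals).
#' @return A [hap_panel].
#' @export
read_vcf_panel <- function(path, panel, region = NULL,
                           exclude_samples = character()) {
  pmap <- read_panel_table(panel)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no genotype columns")
  all_samples <- colnames(gt)[-1L]
  keep_samples <- setdiff(all_samples, exclude_samples)
  missing_pop <- setdiff(keep_samples, pmap$sample)
  if (length(missing_pop))
    stop("samples in VCF absent from panel table: ",
         paste(missing_pop, collapse = ", "))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  snp <- toupper(ref) %in% bases & toupper(alt) %in% bases   # drops multi-allelic (comma) and indels
  pos1 <- as.numeric(fix[, "POS"])
  keep_rec <- which(snp)
  if (!is.null(region))
    keep_rec <- keep_rec[pos1[keep_rec] - 1 >= region[1L] &
                         pos1[keep_rec] - 1 < region[2L]]
  chrom <- if (nrow(fix)) fix[1L, "CHROM"] else NA_character_
  n <- length(keep_samples)
  hap <- matrix(0L, nrow = 2L * n, ncol = length(keep_rec))
  gtk <- gt[keep_rec, keep_samples, drop = FALSE]
  id <- fix[, "ID"]
  for (j in seq_along(keep_rec)) {
    g <- sub(":.*$", "", gtk[j, ])
    bad <- grepl("/", g, fixed = TRUE)
    if (any(bad)) {
      rec <- keep_rec[j]
      stop(sprintf("unphased genotype at %s:%s (%s), sample %s; phased haplotypes are required",
                   chrom, fix[rec, "POS"],
                   ifelse(is.na(id[rec]) || id[rec] == ".", ".", id[rec]),
                   keep_samples[which(bad)[1L]]))
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    a1 <- as.integer(vapply(parts, `[`, "", 1L))
    a2 <- as.integer(vapply(parts, `[`, "", 2L))
    if (anyNA(a1) || anyNA(a2))
      stop(sprintf("missing or malformed genotype at %s:%s", chrom, fix[keep_rec[j], "POS"]))
    hap[seq(1L, 2L * n, by = 2L), j] <- a1
    hap[seq(2L, 2L * n, by = 2L), j] <- a2
  }
  aa <- parse_info_field(fix[keep_rec, "INFO"], "AA")
  aa <- toupper(substr(aa, 1L, 1L))
  anc <- rep("unknown", length(keep_rec))
  anc[!is.na(aa) & aa == toupper(ref[keep_rec])] <- "ref"
  anc[!is.na(aa) & aa == toupper(alt[keep_rec])] <- "alt"
  pops <- stats::setNames(pmap$population, pmap$sample)
  hap_panel(chrom = chrom, pos = pos1[keep_rec] - 1, hap = hap,
            ref = toupper(ref[keep_rec]), alt = toupper(alt[keep_rec]),
            ancestral = anc, samples = keep_samples, pops = pops)
}

read_panel_table <- function(panel) {
  if (is.character(panel) && length(panel) == 1L) {
    panel <- utils::read.table(panel, header = FALSE, sep = "\t",
                               col.names = c("sample", "population"),
                               colClasses = "character")
  }
  panel <- as.data.frame(panel)
  names(panel)[1:2] <- c("sample", "population")
  panel$sample <- as.character(panel$sample)
  panel$population <- as.character(panel$population)
  panel
}

parse_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  has <- grepl(pat, info, perl = TRUE)
  out[has] <- sub(pat, "\\1", regmatches(info, regexpr(pat, info, perl = TRUE)), perl = TRUE)
  out
}

#' Subset a panel to a region
#'
#' @param panel a [hap_panel].
#' @param start,end 0-based half-open interval.
#' @return A [hap_panel] restricted to sites (and divergence-only records)
#'   within the region.
#' @export
subset_panel <- function(panel, start, end) {
  j <- sites_in(panel, start, end)
  out <- panel
  out$pos <- panel$pos[j]
  out$hap <- panel$hap[, j, drop = FALSE]
  out$ref <- panel$ref[j]; out$alt <- panel$alt[j]
  out$ancestral <- panel$ancestral[j]
  out$outgroup <- panel$outgroup[j]
  out$three_state <- panel$three_state[j]
  out$div_only <- panel$div_only[panel$div_only >= start & panel$div_only < end]
  out
}

#' Annotate a panel with outgroup calls and divergence-only records
#'
#' Every panel site is annotated with the aligned outgroup allele. Sites where
#' the outgroup matches neither sample allele are flagged three-state and are
#' excluded from both polymorphism polarization and divergence counting.
#' Monomorphic reference positions where the aligned outgroup differs from the
#' reference become divergence-only records used by windowed divergence
#' counts. Where the VCF carried no ancestral annotation, the outgroup call
#' provides a fallback polarization.
#'
#' @param panel a [hap_panel].
#' @param outgroup an [outgroup_track] on the same chromosome.
#' @return The annotated [hap_panel].
#' @export
merge_outgroup_panel <- function(panel, outgroup) {
  call <- outgroup_call_at(outgroup, panel$pos)
  panel$outgroup <- call
  has <- !is.na(call)
  panel$three_state <- has & call != panel$ref & call != panel$alt
  fallback <- which(panel$ancestral == "unknown" & has & !panel$three_state)
  panel$ancestral[fallback] <-
    ifelse(call[fallback] == panel$ref[fallback], "ref", "alt")
  all_pos <- outgroup$offset + seq_along(outgroup$ref) - 1
  diverged <- !is.na(outgroup$call) & outgroup$call != outgroup$ref
  panel$div_only <- setdiff(all_pos[diverged], panel$pos)
  panel
}
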