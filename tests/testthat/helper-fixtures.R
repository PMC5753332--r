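## Small in-code builders used across the suite.

## panel from an explicit haplotype matrix (rows = haplotypes, even count)
make_panel <- function(hap, pos = NULL, ancestral = "ref",
                       ref = "A", alt = "G", chrom = "chr1") {
  hap <- as.matrix(hap)
  S <- ncol(hap)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = S)
  ns <- nrow(hap) / 2
  samples <- sprintf("S%02d", seq_len(ns))
  hap_panel(chrom = chrom, pos = pos, hap = hap,
            ref = rep_len(ref, S), alt = rep_len(alt, S),
            ancestral = rep_len(ancestral, S), samples = samples,
            pops = stats::setNames(rep("POP1", ns), samples))
}

## window covering the whole panel extent
whole_window <- function(panel, L = NULL) {
  end <- if (length(panel$pos)) max(panel$pos) + 100 else 1000
  list(start = 0, end = end,
       accessible_bases = if (is.null(L)) end else L)
}

## random segregating panel: n_hap haplotypes, up to S sites
random_panel <- function(n_hap, S, seed) {
  set.seed(seed)
  n_hap <- 2L * ceiling(n_hap / 2)      # panels carry diploid samples

  repeat {
    hap <- matrix(rbinom(n_hap * S, 1, runif(1, 0.2, 0.8)), nrow = n_hap)
    cnt <- colSums(hap)
    keep <- cnt > 0 & cnt < n_hap
    if (sum(keep) >= min(2, S)) break
  }
  make_panel(hap[, keep, drop = FALSE])
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## minimal phased VCF writer for IO tests
tiny_vcf <- function(records, samples) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), ".vcf")
}

tiny_panel_table <- function(samples, pops = "POP1") {
  data.frame(sample = samples, population = rep_len(pops, length(samples)))
}
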