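#' Codon degeneracy of one position
#'
#' Classifies a coding position by the standard genetic code: `"fourfold"`
#' when every substitution at the position is synonymous, `"zerofold"` when
#' every substitution changes the amino acid (stop counts as a change), and
#' `"other"` for two- and three-fold degenerate positions (excluded from
#' MKT site classes). Codons containing ambiguous bases return
#' `"excluded"`.
#'
#' @param codon a 3-character string over A/C/G/T (coding strand).
#' @param position 0-based position within the codon (0, 1 or 2).
#' @return One of `"fourfold"`, `"zerofold"`, `"other"`, `"excluded"`.
#' @export
classify_coding_degeneracy <- function(codon, position) {
  codon <- toupper(codon)
  stopifnot(position %in% 0:2)
  bases <- c("A", "C", "G", "T")
  cb <- strsplit(codon, "")[[1L]]
  if (length(cb) != 3L || !all(cb %in% bases)) return("excluded")
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  syn <- 0L
  for (b in setdiff(bases, cb[position + 1L])) {
    alt <- cb
    alt[position + 1L] <- b
    if (code[[paste(alt, collapse = "")]] == aa) syn <- syn + 1L
  }
  if (syn == 3L) "fourfold" else if (syn == 0L) "zerofold" else "other"
}

#' Site-class map of a gene
#'
#' Assigns every position in the gene's extent plus flanks to one mutually
#' exclusive class: `fourfold` / `zerofold` / `other` inside the CDS (by
#' degeneracy on the coding strand), `utr5` / `utr3` for exonic non-CDS,
#' `intron` between exons, `intergenic_flank` for the +/- flank outside the
#' transcript, and `excluded` for flank positions falling inside another
#' gene's transcript. A CDS with an internal stop codon flags the gene and
#' withholds coding classes.
#'
#' @param gene a [gene_model].
#' @param reference_sequence chromosome reference sequence: a character
#'   string or `DNAString` (position 1 = chromosome coordinate 0).
#' @param other_genes optional list of other [gene_model]s whose transcript
#'   extents are excluded from this gene's flanks.
#' @return An object of class `site_class_map`: list with `pos` (0-based),
#'   `class` (character), `gene_id`, and `internal_stop` flag.
#' @export
build_site_class_map <- function(gene, reference_sequence, other_genes = NULL) {
  refseq <- toupper(as.character(reference_sequence))
  flank <- gene$flank_size
  ext_start <- max(0, gene$start - flank)
  ext_end <- gene$end + flank
  if (nchar(refseq) < ext_end)
    stop(sprintf("reference sequence (%d bp) shorter than gene extent + flank (%d bp)",
                 nchar(refseq), ext_end))
  pos <- seq(ext_start, ext_end - 1)
  class <- rep("intergenic_flank", length(pos))
  inside <- pos >= gene$start & pos < gene$end
  class[inside] <- "intron"
  at <- function(p) match(p, pos)
  class[at(segment_positions(gene$utr5))] <- "utr5"
  class[at(segment_positions(gene$utr3))] <- "utr3"
  internal_stop <- FALSE
  cds_pos <- segment_positions(gene$cds)          # genomic order
  if (gene$codable && length(cds_pos)) {
    if (gene$strand == "-") cds_pos <- rev(cds_pos)
    codon_chars <- substring(refseq, cds_pos + 1, cds_pos + 1)
    if (gene$strand == "-")
      codon_chars <- chartr("ACGT", "TGCA", codon_chars)
    ncod <- length(cds_pos) %/% 3L
    codons <- vapply(seq_len(ncod), function(k)
      paste(codon_chars[(3L * k - 2L):(3L * k)], collapse = ""), "")
    aas <- ifelse(codons %in% names(Biostrings::GENETIC_CODE),
                  Biostrings::GENETIC_CODE[codons], "X")
    if (any(aas[-length(aas)] == "*")) internal_stop <- TRUE
    if (!internal_stop) {
      deg <- character(length(cds_pos))
      for (k in seq_len(ncod)) {
        for (off in 0:2)
          deg[3L * (k - 1L) + off + 1L] <-
            classify_coding_degeneracy(codons[k], off)
      }
      class[at(cds_pos)] <- deg
    } else {
      class[at(cds_pos)] <- "excluded"
    }
  } else if (length(cds_pos)) {
    class[at(cds_pos)] <- "excluded"              # non-codable model
  }
  if (!is.null(other_genes)) {
    flank_idx <- which(class == "intergenic_flank")
    for (og in other_genes) {
      if (!identical(og$chrom, gene$chrom) ||
          identical(og$transcript_id, gene$transcript_id)) next
      hit <- pos[flank_idx] >= og$start & pos[flank_idx] < og$end
      class[flank_idx[hit]] <- "excluded"
    }
  }
  structure(list(pos = pos, class = class, gene_id = gene$gene_id,
                 internal_stop = internal_stop),
            class = "site_class_map")
}

## positions of one class in a site-class map
class_positions <- function(class_map, cls) {
  class_map$pos[class_map$class %in% cls]
}

#' Derived allele frequency spectrum
#'
#' Normalized histogram of derived-allele frequencies over polarized
#' segregating sites at the given positions.
#'
#' @param panel a [hap_panel].
#' @param sites 0-based positions to include.
#' @param bins number of equal-width bins on `[0, 1]` (default 10).
#' @param pop optional population label.
#' @return Numeric vector of bin proportions (sums to 1), or all-`NA` when
#'   no polarized segregating site exists.
#' @export
daf_spectrum <- function(panel, sites, bins = 10, pop = NULL) {
  rows <- hap_rows(panel, pop)
  n <- length(rows)
  j <- which(panel$pos %in% sites & panel$ancestral != "unknown" &
               !panel$three_state)
  if (length(j) == 0L) return(rep(NA_real_, bins))
  cnt <- colSums(panel$hap[rows, j, drop = FALSE])
  seg <- cnt > 0 & cnt < n
  if (!any(seg)) return(rep(NA_real_, bins))
  der <- ifelse(panel$ancestral[j][seg] == "alt", n - cnt[seg], cnt[seg])
  p <- der / n
  b <- pmin(floor(p * bins), bins - 1L) + 1L
  tabulate(b, nbins = bins) / length(p)
}

#' Polymorphism and divergence counts for an MKT site-class pair
#'
#' For the test and neutral classes: analyzable sites `m` (accessible and
#' outgroup-aligned positions of the class), segregating sites `P`
#' partitioned at minor allele frequency `maf_cutoff` into `P_low`/`P_high`,
#' divergent sites `D` (fixed differences vs the outgroup; a polymorphic
#' site is never also counted divergent, three-state sites are excluded),
#' per-site diversity `pi` and Jukes-Cantor divergence `K`.
#'
#' @param panel an outgroup-annotated [hap_panel]
#'   ([merge_outgroup_panel]).
#' @param outgroup the [outgroup_track].
#' @param class_map a [build_site_class_map] result.
#' @param test_class site class to test (e.g. `"zerofold"`, `"utr5"`).
#' @param neutral_class assumed-neutral class (default `"fourfold"`).
#' @param pop optional population label.
#' @param mask optional [access_mask]; when given, only accessible
#'   positions are analyzable.
#' @param maf_cutoff MAF partition point (default 0.05).
#' @return An object of class `mkt_counts`: list with `test` and `neutral`
#'   sublists (`m`, `P`, `P_low`, `P_high`, `D`, `pi`, `K`) plus the class
#'   names and `n`.
#' @export
mkt_counts <- function(panel, outgroup, class_map, test_class,
                       neutral_class = "fourfold", pop = NULL, mask = NULL,
                       maf_cutoff = 0.05) {
  rows <- hap_rows(panel, pop)
  n <- length(rows)
  count_class <- function(cls) {
    cpos <- class_positions(class_map, cls)
    if (!is.null(mask))
      cpos <- cpos[is_accessible(mask, panel$chrom, cpos)]
    aligned <- outgroup_aligned_at(outgroup, cpos)
    cpos <- cpos[aligned]
    m <- length(cpos)
    if (m == 0L)
      return(list(m = 0, P = 0, P_low = 0, P_high = 0, D = 0,
                  pi = NA_real_, K = NA_real_))
    j <- which(panel$pos %in% cpos)
    cnt <- if (length(j)) colSums(panel$hap[rows, j, drop = FALSE]) else integer(0)
    seg <- cnt > 0 & cnt < n
    three <- panel$three_state[j]
    maf <- pmin(cnt, n - cnt) / n
    P_low <- sum(seg & !three & maf < maf_cutoff)
    P_high <- sum(seg & !three & maf >= maf_cutoff)
    P <- P_low + P_high
    pi_total <- sum(pi_contrib(cnt[seg & !three], n))
    ## divergence: divergence-only records in the class + fixed differences
    ## at panel records (exclude three-state)
    D <- sum(panel$div_only %in% cpos)
    if (length(j)) {
      fx <- which(!seg & !three)
      if (length(fx)) {
        samp <- ifelse(cnt[fx] == n, panel$alt[j[fx]], panel$ref[j[fx]])
        oc <- panel$outgroup[j[fx]]
        D <- D + sum(!is.na(oc) & oc != samp)
      }
    }
    p_div <- D / m
    K <- if (p_div < 3 / 4) -3 / 4 * log(1 - 4 * p_div / 3) else NA_real_
    list(m = m, P = P, P_low = P_low, P_high = P_high, D = D,
         pi = pi_total / m, K = K)
  }
  structure(list(test = count_class(test_class),
                 neutral = count_class(neutral_class),
                 test_class = test_class, neutral_class = neutral_class,
                 n = n),
            class = "mkt_counts")
}

#' Build an mkt_counts object from raw cell counts
#'
#' Convenience constructor for working directly with a 2x2 (or
#' MAF-partitioned) MKT table.
#'
#' @param P_t,D_t,P_s,D_s polymorphic and divergent site counts for the
#'   test (t) and neutral (s) classes.
#' @param m_t,m_s analyzable site counts.
#' @param P_t_low,P_s_low low-MAF partitions (default 0; the remainder is
#'   high-MAF).
#' @param pi_t,pi_s,K_t,K_s optional per-site diversity/divergence.
#' @return An `mkt_counts` object.
#' @export
mkt_table <- function(P_t, D_t, P_s, D_s, m_t = NA_real_, m_s = NA_real_,
                      P_t_low = 0, P_s_low = 0,
                      pi_t = NA_real_, pi_s = NA_real_,
                      K_t = NA_real_, K_s = NA_real_) {
  structure(list(test = list(m = m_t, P = P_t, P_low = P_t_low,
                             P_high = P_t - P_t_low, D = D_t,
                             pi = pi_t, K = K_t),
                 neutral = list(m = m_s, P = P_s, P_low = P_s_low,
                                P_high = P_s - P_s_low, D = D_s,
                                pi = pi_s, K = K_s),
                 test_class = "test", neutral_class = "neutral",
                 n = NA_integer_),
            class = "mkt_counts")
}

#' Standard McDonald-Kreitman test
#'
#' From the 2x2 polymorphism/divergence table: the neutrality index
#' NI = (P_t/P_s)/(D_t/D_s), the adaptive proportion alpha = 1 - NI (and
#' its pi/K-based variant), and the direction of selection
#' DoS = D_t/(D_t+D_s) - P_t/(P_t+P_s). Statistics with a zero denominator
#' are missing, never infinite.
#'
#' @param counts an `mkt_counts` object.
#' @return A list with `alpha_std`, `alpha_pik`, `NI`, `DoS`.
#' @export
standard_mkt <- function(counts) {
  t <- counts$test; s <- counts$neutral
  NI <- if (s$P > 0 && t$D > 0 && s$D > 0) (t$P / s$P) / (t$D / s$D) else NA_real_
  alpha_std <- if (!is.na(NI)) 1 - NI else NA_real_
  alpha_pik <- if (!is.na(t$pi) && !is.na(s$pi) && !is.na(t$K) &&
                   !is.na(s$K) && s$pi > 0 && t$K > 0)
    1 - (t$pi / s$pi) * (s$K / t$K) else NA_real_
  DoS <- if ((t$D + s$D) > 0 && (t$P + s$P) > 0)
    t$D / (t$D + s$D) - t$P / (t$P + s$P) else NA_real_
  list(alpha_std = alpha_std, alpha_pik = alpha_pik, NI = NI, DoS = DoS)
}

#' Integrative McDonald-Kreitman test
#'
#' Partitions the test-class polymorphism at the MAF cutoff to remove the
#' excess of slightly deleterious segregating variants before estimating
#' the fractions of new mutations that are strongly deleterious (`d`),
#' slightly deleterious (`b`) and neutral (`f`), the corrected adaptive
#' proportion `alpha_cor`, and the split of the neutral fraction into
#' anciently neutral (`f_old`, reported as "f - gamma") and recently
#' neutral (`gamma`). The neutral-class low/high split calibrates how much
#' low-frequency test-class polymorphism is expected without selection:
#' `P_t_neutral = P_t_high * P_s / P_s_high` and the weakly deleterious
#' excess is `P_t_wd = P_t_low - P_t_high * (P_s_low / P_s_high)`, floored
#' at 0. `f_old` uses a divergence-based neutral fraction with the pi/K
#' alpha (`alpha_pik`); using `alpha_cor` there would force gamma to 0
#' algebraically.
#'
#' @param counts an `mkt_counts` object (with MAF partitions and `m`
#'   counts).
#' @param maf_cutoff recorded MAF partition point (default 0.05; the
#'   partition itself is made when counting).
#' @return A list of class `mkt_result`: `alpha_std`, `alpha_pik`, `NI`,
#'   `DoS`, `d`, `b`, `f`, `f_old`, `gamma`, `alpha_cor`, `clamped`.
#' @export
integrative_mkt <- function(counts, maf_cutoff = 0.05) {
  t <- counts$test; s <- counts$neutral
  std <- standard_mkt(counts)
  out <- c(std, list(d = NA_real_, b = NA_real_, f = NA_real_,
                     f_old = NA_real_, gamma = NA_real_,
                     alpha_cor = NA_real_, clamped = FALSE,
                     maf_cutoff = maf_cutoff))
  if (!(s$P_high > 0 && t$D > 0 && s$D > 0 && s$P > 0) ||
      is.na(t$m) || is.na(s$m) || t$m <= 0 || s$m <= 0) {
    class(out) <- "mkt_result"
    return(out)
  }
  clamp01 <- function(x) {
    if (is.na(x)) return(list(v = x, c = FALSE))
    list(v = min(max(x, 0), 1), c = x < 0 || x > 1)
  }
  P_t_neutral <- t$P_high * s$P / s$P_high
  P_t_wd_raw <- t$P_low - t$P_high * (s$P_low / s$P_high)
  clamped <- P_t_wd_raw < 0
  P_t_wd <- max(P_t_wd_raw, 0)
  f <- (s$m / t$m) * (P_t_neutral / s$P)
  b <- (s$m / t$m) * (P_t_wd / s$P)
  cf <- clamp01(f); cb <- clamp01(b)
  f <- cf$v; b <- cb$v
  d_raw <- 1 - f - b
  cd <- clamp01(d_raw)
  clamped <- clamped || cf$c || cb$c || cd$c
  alpha_cor <- 1 - (P_t_neutral / s$P) * (s$D / t$D)
  f_old <- if (!is.na(std$alpha_pik))
    (s$m / t$m) * ((1 - std$alpha_pik) * t$D / s$D) else NA_real_
  gamma <- if (!is.na(f_old)) max(0, f - f_old) else NA_real_
  if (!is.na(f_old) && f_old > f) {     # keep f = f_old + gamma
    clamped <- TRUE
    f_old <- f
  }
  out$d <- cd$v; out$b <- b; out$f <- f
  out$f_old <- f_old; out$gamma <- gamma
  out$alpha_cor <- alpha_cor
  out$clamped <- clamped
  class(out) <- "mkt_result"
  out
}

#' @export
print.mkt_result <- function(x, ...) {
  cat("Integrative MKT\n")
  cat(sprintf("  standard: NI = %s, alpha = %s, alpha(pi/K) = %s, DoS = %s\n",
              fmtna(x$NI), fmtna(x$alpha_std), fmtna(x$alpha_pik), fmtna(x$DoS)))
  cat(sprintf("  fractions: d = %s, b = %s, f = %s (f-gamma = %s, gamma = %s)\n",
              fmtna(x$d), fmtna(x$b), fmtna(x$f), fmtna(x$f_old), fmtna(x$gamma)))
  cat(sprintf("  corrected alpha = %s%s\n", fmtna(x$alpha_cor),
              if (isTRUE(x$clamped)) " [clamped]" else ""))
  invisible(x)
}

fmtna <- function(x) if (is.null(x) || is.na(x)) "NA" else sprintf("%.4f", x)
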