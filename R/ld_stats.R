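#' Pairwise r-squared between two sites
#'
#' r2 = D^2 / (p1 q1 p2 q2) with D = f11 - p1 p2 computed on phased
#' haplotypes (gamete counting). Invariant to allele relabeling at either
#' site. Both sites must segregate in the analyzed haplotypes.
#'
#' @param x,y binary haplotype columns of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(x, y) {
  p1 <- mean(x); p2 <- mean(y)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1))
    stop("monomorphic site passed to pairwise_r2; pre-filter to segregating sites")
  D <- mean(x * y) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

## haplotype columns of the window's segregating sites for one population,
## in genomic order
segregating_columns <- function(panel, window, pop = NULL) {
  rows <- hap_rows(panel, pop)
  j <- sites_in(panel, window$start, window$end)
  if (length(j) == 0L) return(matrix(0L, nrow = length(rows), ncol = 0L))
  H <- panel$hap[rows, j, drop = FALSE]
  cnt <- colSums(H)
  H[, cnt > 0 & cnt < length(rows), drop = FALSE]
}

## full r2 matrix via Pearson correlation (equal to gamete-counting r2 for
## binary columns)
r2_matrix <- function(H) {
  r <- suppressWarnings(stats::cor(H))
  r * r
}

#' Kelly's ZnS
#'
#' Average pairwise r-squared over all pairs of segregating sites in the
#' window. Missing with fewer than 2 segregating sites.
#'
#' @param panel a [hap_panel].
#' @param window one row of a windows data.frame.
#' @param pop optional population label.
#' @return ZnS in `[0, 1]`, or `NA`.
#' @export
kelly_zns <- function(panel, window, pop = NULL) {
  H <- segregating_columns(panel, window, pop)
  S <- ncol(H)
  if (S < 2L) return(NA_real_)
  r2 <- r2_matrix(H)
  mean(r2[upper.tri(r2)])
}

#' Rozas' ZA and ZZ
#'
#' ZA averages r-squared over the S - 1 adjacent pairs of segregating sites
#' (genomic order, never across window boundaries); ZZ = ZA - ZnS, positive
#' when LD is concentrated between neighbors (a recombination signal).
#'
#' @inheritParams kelly_zns
#' @return A list with `za` and `zz`, `NA` when S < 2.
#' @export
rozas_za_zz <- function(panel, window, pop = NULL) {
  H <- segregating_columns(panel, window, pop)
  S <- ncol(H)
  if (S < 2L) return(list(za = NA_real_, zz = NA_real_))
  r2 <- r2_matrix(H)
  za <- mean(r2[cbind(seq_len(S - 1L), seq_len(S - 1L) + 1L)])
  zns <- mean(r2[upper.tri(r2)])
  list(za = za, zz = za - zns)
}

#' Wall's B and Q
#'
#' A pair of adjacent segregating sites is congruent when the two columns
#' jointly show only two distinct two-site haplotypes (the sites induce the
#' same or complementary bipartition of the sample; no recombination needed
#' between them). B = B'/(S-1) with B' the congruent-pair count; Q =
#' (B' + A)/S with A the number of distinct bipartitions among congruent
#' pairs.
#'
#' @inheritParams kelly_zns
#' @return A list with `b` and `q`; `b` is `NA` when S < 2, `q` when S < 1.
#' @export
wall_b_q <- function(panel, window, pop = NULL) {
  H <- segregating_columns(panel, window, pop)
  S <- ncol(H)
  if (S < 1L) return(list(b = NA_real_, q = NA_real_))
  if (S < 2L) return(list(b = NA_real_, q = NA_real_))
  congruent <- logical(S - 1L)
  parts <- character(S - 1L)
  for (k in seq_len(S - 1L)) {
    x <- H[, k]; y <- H[, k + 1L]
    congruent[k] <- length(unique(paste(x, y))) == 2L
    if (congruent[k]) {
      ## canonical bipartition label: flip so the first haplotype carries 0
      if (x[1L] == 1L) x <- 1L - x
      parts[k] <- paste(x, collapse = "")
    }
  }
  Bp <- sum(congruent)
  A <- length(unique(parts[congruent]))
  list(b = Bp / (S - 1L), q = (Bp + A) / S)
}
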