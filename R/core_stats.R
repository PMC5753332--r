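#' Sample-size constants for SFS neutrality tests
#'
#' Deterministic functions of the haplotype sample size n: the harmonic
#' sums a1 and a2 and the variance constants of Tajima's D and of the
#' outgroup (derived-singleton) versions of Fu and Li's D and F.
#'
#' @param n haplotype sample size (>= 2).
#' @return A list of constants: `a1`, `a2`, Tajima's `b1,b2,c1,c2,e1,e2`,
#'   Fu-Li's `cn,uD,vD,uF,vF`.
#' @export
sample_constants <- function(n) {
  if (n < 2) stop("need at least 2 haplotypes")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  cn <- if (n > 2) 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  vD <- 1 + (a1^2 / (a2 + a1^2)) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  an1 <- a1 + 1 / n                     # a_{n+1}
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (a1^2 + a2)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / a1 - vF
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2, cn = cn, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Site frequency spectrum of a window
#'
#' Counts derived-allele occurrence classes among the window's segregating
#' sites for one population. Sites with a known ancestral state enter the
#' unfolded spectrum `xi`; three-state sites and sites without polarization
#' are tallied separately (by their minor-allele count) and remain usable by
#' folded statistics only.
#'
#' @param panel a [hap_panel].
#' @param window one row of a windows data.frame (list with `start`, `end`,
#'   `accessible_bases`).
#' @param pop optional population label (default: all samples).
#' @return An object of class `site_spectrum`: list with `n` (haplotypes),
#'   `xi` (unfolded counts, length n-1), `folded_extra` (minor-allele counts
#'   of unpolarizable segregating sites), `L` (accessible bases),
#'   `derived_counts` and `positions` of the polarized sites.
#' @export
site_spectrum <- function(panel, window, pop = NULL) {
  rows <- hap_rows(panel, pop)
  n <- length(rows)
  j <- sites_in(panel, window$start, window$end)
  L <- window$accessible_bases
  xi <- integer(max(n - 1L, 0L))
  dc <- integer(0); dpos <- numeric(0); folded <- integer(0)
  if (length(j)) {
    alt_count <- colSums(panel$hap[rows, j, drop = FALSE])
    seg <- alt_count > 0 & alt_count < n
    j <- j[seg]; alt_count <- alt_count[seg]
    if (length(j)) {
      anc <- panel$ancestral[j]
      polar <- anc != "unknown" & !panel$three_state[j]
      der <- ifelse(anc == "alt", n - alt_count, alt_count)
      dc <- der[polar]; dpos <- panel$pos[j][polar]
      xi <- tabulate(dc, nbins = n - 1L)
      mc <- pmin(alt_count, n - alt_count)
      folded <- mc[!polar]
    }
  }
  structure(list(n = n, xi = xi, folded_extra = folded, L = L,
                 derived_counts = dc, positions = dpos),
            class = "site_spectrum")
}

## per-site heterozygosity contribution 2 i (n - i) / (n (n - 1))
pi_contrib <- function(i, n) 2 * i * (n - i) / (n * (n - 1))

## total pairwise diversity of a spectrum, all segregating sites
spectrum_pi_total <- function(sp) {
  i <- seq_along(sp$xi)
  sum(sp$xi * pi_contrib(i, sp$n)) + sum(pi_contrib(sp$folded_extra, sp$n))
}

## pairwise diversity over polarized sites only
spectrum_pi_polarized <- function(sp) {
  i <- seq_along(sp$xi)
  sum(sp$xi * pi_contrib(i, sp$n))
}

spectrum_S_total <- function(sp) sum(sp$xi) + length(sp$folded_extra)

#' Windowed diversity and divergence statistics
#'
#' Computes the frequency-based and divergence-based statistics of one
#' window for one population: segregating sites per site (S), nucleotide
#' diversity (Pi), Watterson's theta, haplotype diversity, theta_L and
#' theta_H totals, divergent sites and Jukes-Cantor-corrected divergence K.
#'
#' Divergent sites are positions where all sample alleles agree and differ
#' from the aligned outgroup: divergence-only records plus fixed differences
#' at panel record positions (three-state sites excluded; a polymorphic site
#' is never also counted divergent). K = -(3/4) log(1 - (4/3) Divsites /
#' L_aligned) with L_aligned the accessible positions covered by the
#' alignment; K is missing when the observed proportion reaches saturation
#' (>= 3/4).
#'
#' @param panel a [hap_panel] (outgroup-annotated via [merge_outgroup_panel]
#'   for divergence fields).
#' @param window one row of a windows data.frame.
#' @param outgroup optional [outgroup_track] (needed for `divsites`/`K`).
#' @param mask optional [access_mask] restricting `L_aligned`; when absent,
#'   all aligned positions inside the window count.
#' @param pop optional population label.
#' @return A list of class `diversity_stats`: `S`, `S_per_site`, `pi_total`,
#'   `pi_per_site`, `theta_w_per_site`, `hap_diversity`, `theta_L`,
#'   `theta_H`, `divsites`, `K_jc`, `L`, `L_aligned`, `n`.
#' @export
diversity_stats <- function(panel, window, outgroup = NULL, mask = NULL,
                            pop = NULL) {
  rows <- hap_rows(panel, pop)
  n <- length(rows)
  L <- window$accessible_bases
  j <- sites_in(panel, window$start, window$end)
  H <- panel$hap[rows, j, drop = FALSE]
  alt_count <- if (length(j)) colSums(H) else integer(0)
  seg <- alt_count > 0 & alt_count < n
  S <- sum(seg)
  mc <- alt_count[seg]
  pi_total <- sum(pi_contrib(mc, n))
  cons <- sample_constants(n)
  sp <- site_spectrum(panel, window, pop)
  theta_L <- if (sum(sp$xi) > 0) sum(seq_along(sp$xi) * sp$xi) / (n - 1) else
    if (S == 0) 0 else NA_real_
  theta_H <- if (sum(sp$xi) > 0)
    sum(2 * seq_along(sp$xi)^2 * sp$xi) / (n * (n - 1)) else
      if (S == 0) 0 else NA_real_
  hap_div <- if (n >= 2 && ncol(H) > 0) {
    f <- table(apply(H, 1L, paste, collapse = "")) / n
    (n / (n - 1)) * (1 - sum(f^2))
  } else if (n >= 2) 0 else NA_real_
  divsites <- NA_real_; K_jc <- NA_real_; L_aligned <- NA_real_
  if (!is.null(outgroup)) {
    div <- 0
    div <- div + sum(panel$div_only >= window$start & panel$div_only < window$end)
    if (length(j)) {
      fixed <- which(!seg)
      jf <- j[fixed]
      if (length(jf)) {
        samp_allele <- ifelse(alt_count[fixed] == n, panel$alt[jf], panel$ref[jf])
        oc <- panel$outgroup[jf]
        ok <- !is.na(oc) & !panel$three_state[jf]
        div <- div + sum(ok & oc != samp_allele)
      }
    }
    all_pos <- outgroup$offset + seq_along(outgroup$ref) - 1
    inw <- all_pos >= window$start & all_pos < window$end
    aligned <- inw & !is.na(outgroup$call)
    if (!is.null(mask))
      aligned <- aligned & is_accessible(mask, panel$chrom, all_pos)
    L_aligned <- sum(aligned)
    divsites <- div
    if (L_aligned > 0) {
      p <- divsites / L_aligned
      K_jc <- if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
    }
  }
  structure(list(n = n, L = L, S = S,
                 S_per_site = if (L > 0) S / L else NA_real_,
                 pi_total = pi_total,
                 pi_per_site = if (L > 0) pi_total / L else NA_real_,
                 theta_w_per_site = if (L > 0) S / (cons$a1 * L) else NA_real_,
                 hap_diversity = hap_div,
                 theta_L = theta_L, theta_H = theta_H,
                 divsites = divsites, K_jc = K_jc, L_aligned = L_aligned),
            class = "diversity_stats")
}

#' Tajima's D
#'
#' Contrasts the number of segregating sites with the average pairwise
#' difference; negative under an excess of rare variants. Uses all
#' segregating sites (folded information suffices). Missing when S = 0.
#'
#' @param spectrum a [site_spectrum].
#' @param constants optional [sample_constants] for the spectrum's n.
#' @return The D statistic, or `NA` when undefined.
#' @export
tajimas_d <- function(spectrum, constants = sample_constants(spectrum$n)) {
  S <- spectrum_S_total(spectrum)
  if (S < 1) return(NA_real_)
  pi_total <- spectrum_pi_total(spectrum)
  v <- constants$e1 * S + constants$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / constants$a1) / sqrt(v)
}

#' Fu and Li's D and F (outgroup versions)
#'
#' Contrast derived singletons (mutations on external branches) with the
#' total number of segregating sites (D) or with the mean pairwise
#' difference (F). Only polarized sites are used; missing when no polarized
#' segregating site exists.
#'
#' @param spectrum a [site_spectrum].
#' @param constants optional [sample_constants].
#' @return A list with elements `D` and `F`.
#' @export
fu_li_tests <- function(spectrum, constants = sample_constants(spectrum$n)) {
  S <- sum(spectrum$xi)
  if (S < 1) return(list(D = NA_real_, F = NA_real_))
  xi1 <- spectrum$xi[1L]
  vD <- constants$uD * S + constants$vD * S^2
  vF <- constants$uF * S + constants$vF * S^2
  D <- if (vD > 0) (S - constants$a1 * xi1) / sqrt(vD) else NA_real_
  pi_pol <- spectrum_pi_polarized(spectrum)
  F <- if (vF > 0) (pi_pol - xi1) / sqrt(vF) else NA_real_
  list(D = D, F = F)
}

#' Fay and Wu's H
#'
#' Contrasts pairwise diversity with the high-frequency-weighted theta_H;
#' strongly negative after a recent sweep has driven derived alleles to high
#' frequency. Defaults to the unnormalized theta_pi - theta_H form; the
#' normalized variant standardizes by the variance of (theta_L-weighted)
#' high-frequency excess. Missing when no polarized segregating site exists.
#'
#' @param spectrum a [site_spectrum].
#' @param normalized use the variance-normalized form (default FALSE).
#' @param constants optional [sample_constants].
#' @return The H statistic, or `NA`.
#' @export
fay_wu_h <- function(spectrum, normalized = FALSE,
                     constants = sample_constants(spectrum$n)) {
  S <- sum(spectrum$xi)
  if (S < 1) return(NA_real_)
  n <- spectrum$n
  i <- seq_along(spectrum$xi)
  theta_H <- sum(2 * i^2 * spectrum$xi) / (n * (n - 1))
  H <- spectrum_pi_polarized(spectrum) - theta_H
  if (!normalized) return(H)
  ## normalized form: H / sqrt(var(theta_pi - theta_L)), with theta and
  ## theta^2 estimated from S (pi - theta_H = 2 (pi - theta_L))
  a1 <- constants$a1; a2 <- constants$a2
  theta <- S / a1
  theta2 <- S * (S - 1) / (a1^2 + a2)
  bn1 <- a2 + 1 / n^2                   # sum_{i=1}^{n} 1/i^2
  v <- (n - 2) / (6 * (n - 1)) * theta +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * theta2
  if (v <= 0) return(NA_real_)
  H / (2 * sqrt(v))                     # H = 2 (pi - theta_L)
}

#' Zeng's E
#'
#' Contrasts theta_L (mean derived-allele count scaled) with Watterson's
#' theta; sensitive to changes in high-frequency derived variants. Missing
#' when no polarized segregating site exists.
#'
#' @param spectrum a [site_spectrum].
#' @param constants optional [sample_constants].
#' @return The E statistic, or `NA`.
#' @export
zeng_e <- function(spectrum, constants = sample_constants(spectrum$n)) {
  S <- sum(spectrum$xi)
  if (S < 1) return(NA_real_)
  n <- spectrum$n
  a1 <- constants$a1; a2 <- constants$a2
  theta_L <- sum(seq_along(spectrum$xi) * spectrum$xi) / (n - 1)
  theta_W <- S / a1
  theta <- S / a1
  theta2 <- S * (S - 1) / (a1^2 + a2)
  v <- theta * (n / (2 * (n - 1)) - 1 / a1) +
    theta2 * (a2 / a1^2 + 2 * (n / (n - 1))^2 * a2 -
                2 * (n * a2 - n + 1) / ((n - 1) * a1) -
                (3 * n + 1) / (n - 1))
  if (v <= 0) return(NA_real_)
  (theta_L - theta_W) / sqrt(v)
}
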