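## pair homozygosity of a grouping: sum C(n_g, 2) / C(n, 2)
group_homozygosity <- function(ids, n) {
  sum(choose(tabulate(ids), 2L)) / choose(n, 2L)
}

## extend a haplotype grouping over successive columns, returning EHH at
## each step; stops early once EHH hits 0
ehh_extend <- function(H, cols, ids = rep(1L, nrow(H))) {
  n <- nrow(H)
  ehh <- rep(NA_real_, length(cols))
  for (k in seq_along(cols)) {
    key <- paste(ids, H[, cols[k]])
    ids <- match(key, unique(key))
    ehh[k] <- group_homozygosity(ids, n)
    if (ehh[k] == 0) {
      ehh[seq_along(cols) > k] <- 0
      break
    }
  }
  list(ehh = ehh, ids = ids)
}

#' Extended haplotype homozygosity curve around a core allele
#'
#' EHH at distance x is the probability that two randomly chosen haplotypes
#' carrying the core allele are identical at every site between the core and
#' x. The curve starts at 1 at the core and is non-increasing outward.
#'
#' @param panel a [hap_panel] (phased, polarized at the core).
#' @param core_site 0-based position of the core SNP.
#' @param allele `"ancestral"` or `"derived"`.
#' @param direction `"left"` or `"right"` from the core.
#' @param pop optional population label.
#' @return A data.frame with columns `pos` and `ehh`; first row is the core
#'   (`ehh = 1`). `NULL` when fewer than 2 haplotypes carry the allele.
#' @export
ehh_curve <- function(panel, core_site, allele = c("derived", "ancestral"),
                      direction = c("right", "left"), pop = NULL) {
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  ci <- match(core_site, panel$pos)
  if (is.na(ci)) stop("core_site is not a panel position: ", core_site)
  anc <- panel$ancestral[ci]
  if (anc == "unknown")
    stop("core site is unpolarized; EHH by allele needs an ancestral state")
  derived_code <- if (anc == "ref") 1L else 0L
  target <- if (allele == "derived") derived_code else 1L - derived_code
  rows <- hap_rows(panel, pop)
  carriers <- rows[panel$hap[rows, ci] == target]
  if (length(carriers) < 2L) return(NULL)
  cols <- if (direction == "right") {
    seq_len(length(panel$pos))[-seq_len(ci)]
  } else {
    rev(seq_len(ci - 1L))
  }
  H <- panel$hap[carriers, , drop = FALSE]
  ehh <- if (length(cols)) ehh_extend(H, cols)$ehh else numeric(0)
  data.frame(pos = c(panel$pos[ci], panel$pos[cols]), ehh = c(1, ehh))
}

#' Integrate an EHH curve over physical distance
#'
#' Trapezoidal integral of EHH against distance from the core, accumulated
#' while EHH stays above `cutoff` (the crossing segment down to the first
#' sub-cutoff point is included). Integration is truncated -- and the site
#' flagged -- when two consecutive informative SNPs are more than `max_gap`
#' apart, or when the curve reaches its end without crossing the cutoff.
#'
#' @param curve data.frame from [ehh_curve] (`pos`, `ehh`).
#' @param cutoff EHH level at which integration stops (default 0.05).
#' @param max_gap maximum tolerated gap between consecutive SNPs in bp
#'   (default 20000).
#' @return A list with `ihh` (the integral) and `truncated` (logical).
#' @export
integrated_ehh <- function(curve, cutoff = 0.05, max_gap = 20000) {
  if (is.null(curve) || nrow(curve) == 0L)
    return(list(ihh = 0, truncated = TRUE))
  d <- abs(curve$pos - curve$pos[1L])
  e <- curve$ehh
  acc <- 0
  if (nrow(curve) >= 2L) {
    for (k in 2:nrow(curve)) {
      if (!(e[k - 1L] > cutoff)) return(list(ihh = acc, truncated = FALSE))
      gap <- d[k] - d[k - 1L]
      if (gap > max_gap) return(list(ihh = acc, truncated = TRUE))
      acc <- acc + (e[k - 1L] + e[k]) / 2 * gap
      if (e[k] <= cutoff) return(list(ihh = acc, truncated = FALSE))
    }
  }
  ## ran off the curve with EHH still above the cutoff
  list(ihh = acc, truncated = !(e[length(e)] <= cutoff))
}

## two-sided iHH for one allele at one core
ihh_both <- function(panel, core_site, allele, pop, cutoff, max_gap) {
  l <- integrated_ehh(ehh_curve(panel, core_site, allele, "left", pop),
                      cutoff, max_gap)
  r <- integrated_ehh(ehh_curve(panel, core_site, allele, "right", pop),
                      cutoff, max_gap)
  list(ihh = l$ihh + r$ihh, truncated = l$truncated || r$truncated)
}

## merge frequency bins until each holds at least min_size scores
merge_bins <- function(bin, min_size) {
  repeat {
    lev <- sort(unique(bin))
    if (length(lev) <= 1L) break
    cnt <- table(factor(bin, levels = lev))
    if (all(cnt >= min_size)) break
    i <- which.min(cnt)
    j <- if (i == 1L) 2L else if (i == length(lev)) i - 1L else
      if (cnt[i - 1L] <= cnt[i + 1L]) i - 1L else i + 1L
    bin[bin == lev[i]] <- lev[j]
  }
  bin
}

standardize_in_bins <- function(score, bin) {
  z <- rep(NA_real_, length(score))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    s <- stats::sd(score[idx])
    if (length(idx) >= 2L && s > 0)
      z[idx] <- (score[idx] - mean(score[idx])) / s
  }
  z
}

#' iHS scan
#'
#' Per polarized SNP with minor allele frequency above `maf_min`, computes
#' the unstandardized score ln(iHH_ancestral / iHH_derived) and standardizes
#' it to zero mean and unit variance within derived-allele-frequency bins.
#' Sites failing the MAF filter, lacking polarization, with an undefined
#' log-ratio, or whose integration was truncated (gap rule or chromosome
#' edge) carry a `qc_flag` and are excluded from standardization.
#'
#' @param panel a [hap_panel].
#' @param pop optional population label.
#' @param region optional `c(start, end)` restricting core sites.
#' @param maf_min minor-allele-frequency filter; sites with MAF <= this are
#'   skipped (default 0.05).
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param max_gap maximum SNP gap in bp before truncation (default 20000).
#' @param bin_width derived-allele-frequency bin width for standardization
#'   (default 0.02); bins with fewer than `min_bin_size` scores are merged
#'   with their neighbors.
#' @param min_bin_size minimum scores per standardization bin (default 20).
#' @return A data.frame of class `hap_scan_scores`: `position`, `freq`
#'   (derived-allele frequency), `unstd`, `std`, `qc_flag` in
#'   `{"passed", "truncated", "skipped"}`.
#' @export
ihs_scan <- function(panel, pop = NULL, region = NULL, maf_min = 0.05,
                     cutoff = 0.05, max_gap = 20000, bin_width = 0.02,
                     min_bin_size = 20) {
  rows <- hap_rows(panel, pop)
  n <- length(rows)
  idx <- seq_along(panel$pos)
  if (!is.null(region))
    idx <- idx[panel$pos >= region[1L] & panel$pos < region[2L]]
  pos <- freq <- unstd <- numeric(0)
  flag <- character(0)
  for (ci in idx) {
    if (panel$ancestral[ci] == "unknown" || panel$three_state[ci]) next
    cnt <- sum(panel$hap[rows, ci])
    maf <- min(cnt, n - cnt) / n
    der <- if (panel$ancestral[ci] == "ref") cnt else n - cnt
    p_d <- der / n
    if (maf <= maf_min) next
    this_flag <- "passed"
    a <- ihh_both(panel, panel$pos[ci], "ancestral", pop, cutoff, max_gap)
    d <- ihh_both(panel, panel$pos[ci], "derived", pop, cutoff, max_gap)
    u <- NA_real_
    if (is.null(a) || is.null(d) || a$ihh == 0 || d$ihh == 0) {
      this_flag <- "skipped"
    } else {
      u <- log(a$ihh / d$ihh)
      if (a$truncated || d$truncated) this_flag <- "truncated"
    }
    pos <- c(pos, panel$pos[ci]); freq <- c(freq, p_d)
    unstd <- c(unstd, u); flag <- c(flag, this_flag)
  }
  std <- rep(NA_real_, length(pos))
  ok <- flag == "passed"
  if (sum(ok) >= 2L) {
    bin <- merge_bins(floor(freq[ok] / bin_width), min_bin_size)
    std[ok] <- standardize_in_bins(unstd[ok], bin)
  }
  flag[ok & is.na(std)] <- "skipped"
  structure(data.frame(position = pos, freq = freq, unstd = unstd,
                       std = std, qc_flag = flag, stringsAsFactors = FALSE),
            class = c("hap_scan_scores", "data.frame"))
}

## population-level EHH curve (all haplotypes, core column included)
pop_ehh_curve <- function(H, ci, direction) {
  cols <- if (direction == "right") seq(ci, ncol(H)) else rev(seq_len(ci))
  ehh_extend(H, cols)$ehh
}

## integrate one population's EHH over the segments the combined curve
## licenses (same stop rule as integrated_ehh, driven by the combined curve)
xp_integrate <- function(d, e_pop, e_comb, cutoff, max_gap) {
  acc <- 0
  if (length(d) >= 2L) {
    for (k in 2:length(d)) {
      if (!(e_comb[k - 1L] > cutoff)) return(list(ihh = acc, truncated = FALSE))
      gap <- d[k] - d[k - 1L]
      if (gap > max_gap) return(list(ihh = acc, truncated = TRUE))
      acc <- acc + (e_pop[k - 1L] + e_pop[k]) / 2 * gap
      if (e_comb[k] <= cutoff) return(list(ihh = acc, truncated = FALSE))
    }
  }
  list(ihh = acc, truncated = !(e_comb[length(e_comb)] <= cutoff))
}

#' XP-EHH scan between two populations
#'
#' Per SNP passing the (combined-sample) MAF filter, integrates each
#' population's haplotype homozygosity around the core until the
#' combined-population EHH drops below `cutoff`, and scores
#' ln(iHH_A / iHH_B), standardized over all passed sites (single bin).
#' Positive scores indicate longer haplotypes (a more recent or stronger
#' sweep) in population A.
#'
#' @param panel_a,panel_b [hap_panel]s over the same sites (e.g. two
#'   population subsets of one cohort panel).
#' @inheritParams ihs_scan
#' @return A `hap_scan_scores` data.frame as in [ihs_scan].
#' @export
xpehh_scan <- function(panel_a, panel_b, region = NULL, maf_min = 0.05,
                       cutoff = 0.05, max_gap = 20000) {
  if (!identical(panel_a$pos, panel_b$pos))
    stop("panels must share the same sites")
  HA <- panel_a$hap; HB <- panel_b$hap
  H <- rbind(HA, HB)
  nA <- nrow(HA); nB <- nrow(HB); n <- nA + nB
  idx <- seq_along(panel_a$pos)
  if (!is.null(region))
    idx <- idx[panel_a$pos >= region[1L] & panel_a$pos < region[2L]]
  pos <- freq <- unstd <- numeric(0)
  flag <- character(0)
  for (ci in idx) {
    cnt <- sum(H[, ci])
    maf <- min(cnt, n - cnt) / n
    if (maf <= maf_min) next
    this_flag <- "passed"
    tot <- list(A = 0, B = 0); trunc <- FALSE
    for (direction in c("left", "right")) {
      cols <- if (direction == "right") seq(ci, ncol(H)) else rev(seq_len(ci))
      eA <- ehh_extend(HA, cols)$ehh
      eB <- ehh_extend(HB, cols)$ehh
      eC <- ehh_extend(H, cols)$ehh
      d <- abs(panel_a$pos[cols] - panel_a$pos[ci])
      rA <- xp_integrate(d, eA, eC, cutoff, max_gap)
      rB <- xp_integrate(d, eB, eC, cutoff, max_gap)
      tot$A <- tot$A + rA$ihh; tot$B <- tot$B + rB$ihh
      trunc <- trunc || rA$truncated || rB$truncated
    }
    u <- NA_real_
    if (tot$A == 0 || tot$B == 0) {
      this_flag <- "skipped"
    } else {
      u <- log(tot$A / tot$B)
      if (trunc) this_flag <- "truncated"
    }
    pos <- c(pos, panel_a$pos[ci]); freq <- c(freq, cnt / n)
    unstd <- c(unstd, u); flag <- c(flag, this_flag)
  }
  std <- rep(NA_real_, length(pos))
  ok <- flag == "passed"
  if (sum(ok) >= 2L) {
    s <- stats::sd(unstd[ok])
    if (s > 0) std[ok] <- (unstd[ok] - mean(unstd[ok])) / s
  }
  flag[ok & is.na(std)] <- "skipped"
  structure(data.frame(position = pos, freq = freq, unstd = unstd,
                       std = std, qc_flag = flag, stringsAsFactors = FALSE),
            class = c("hap_scan_scores", "data.frame"))
}

#' Summarize per-SNP scan scores into windows
#'
#' Per window, the mean of the absolute standardized score over the passed
#' SNPs it contains; missing when a window holds none.
#'
#' @param scores a `hap_scan_scores` data.frame ([ihs_scan], [xpehh_scan]).
#' @param windows a windows data.frame.
#' @return The windows data.frame with `mean_abs_score` and `n_snps` added.
#' @export
summarize_window_scores <- function(scores, windows) {
  ok <- scores$qc_flag == "passed" & !is.na(scores$std)
  p <- scores$position[ok]
  z <- abs(scores$std[ok])
  out <- windows
  out$mean_abs_score <- rep(NA_real_, nrow(windows))
  out$n_snps <- rep(0L, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    inw <- p >= windows$start[i] & p < windows$end[i]
    out$n_snps[i] <- sum(inw)
    if (any(inw)) out$mean_abs_score[i] <- mean(z[inw])
  }
  out
}
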