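test_that("EHH curves follow pair-counting homozygosity", {
  ## all carriers identical: EHH stays 1
  H <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 1), c(0, 1, 0))
  p <- make_panel(H, pos = c(100, 200, 300))
  cv <- ehh_curve(p, 100, "derived", "right")
  expect_equal(cv$ehh[1], 1)
  ## carriers of derived at 100 are rows 1,2,3; they split 2/1 at site 200
  expect_equal(cv$ehh[2], choose(2, 2) / choose(3, 2))
  ## two carriers differing at the adjacent site: drops to 0
  H2 <- rbind(c(1, 1), c(1, 0), c(0, 0), c(0, 0))
  p2 <- make_panel(H2, pos = c(10, 20))
  expect_equal(ehh_curve(p2, 10, "derived", "right")$ehh, c(1, 0))
  ## 4 carriers splitting 2/2: EHH = 2 * C(2,2) / C(4,2)
  H3 <- rbind(c(1, 1), c(1, 1), c(1, 0), c(1, 0), c(0, 0), c(0, 0))
  p3 <- make_panel(H3, pos = c(10, 20))
  expect_equal(ehh_curve(p3, 10, "derived", "right")$ehh[2], 2 / 6)
  ## fewer than 2 carriers: undefined
  H4 <- rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 1))
  expect_null(ehh_curve(make_panel(H4, pos = c(10, 20)), 10, "derived", "right"))
})

test_that("EHH curves are non-increasing and bounded", {
  p <- random_panel(12, 15, seed = 77)
  polar <- which(colSums(p$hap) >= 2 & colSums(p$hap) <= nrow(p$hap) - 2)
  for (ci in polar[1:min(5, length(polar))]) {
    cv <- ehh_curve(p, p$pos[ci], "derived", "right")
    if (is.null(cv)) next
    expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
    expect_true(all(diff(cv$ehh) <= 1e-12))
  }
})

test_that("EHH integration uses trapezoids, the gap rule and the cutoff", {
  curve <- data.frame(pos = c(0, 10000), ehh = c(1, 0))
  r <- integrated_ehh(curve)
  expect_equal(r$ihh, 5000)                        # rectangle + triangle
  expect_false(r$truncated)
  ## gap beyond 20 kb truncates and flags
  curve2 <- data.frame(pos = c(0, 25000), ehh = c(1, 0.5))
  r2 <- integrated_ehh(curve2)
  expect_equal(r2$ihh, 0)
  expect_true(r2$truncated)
  ## degenerate cutoff
  expect_equal(integrated_ehh(curve, cutoff = 1.0)$ihh, 0)
  ## curve ending above the cutoff is flagged truncated
  curve3 <- data.frame(pos = c(0, 1000), ehh = c(1, 0.6))
  expect_true(integrated_ehh(curve3)$truncated)
})

test_that("iHS is zero under symmetric decay and antisymmetric under polarity flip", {
  ## symmetric panel: ancestral and derived carriers decay identically
  H <- rbind(c(0, 1, 0, 1), c(0, 1, 1, 0), c(1, 0, 0, 1), c(1, 0, 1, 0))
  p <- make_panel(H, pos = c(0, 500, 1000, 1500))
  a <- popgenwin:::ihh_both(p, 1000, "ancestral", NULL, 0.05, 20000)
  d <- popgenwin:::ihh_both(p, 1000, "derived", NULL, 0.05, 20000)
  expect_equal(a$ihh, d$ihh)                       # ln ratio would be 0
  ## flipping ancestral/derived labels at the core negates the raw score
  p2 <- random_panel(10, 12, seed = 55)
  core <- p2$pos[6]
  a2 <- popgenwin:::ihh_both(p2, core, "ancestral", NULL, 0.05, 20000)
  d2 <- popgenwin:::ihh_both(p2, core, "derived", NULL, 0.05, 20000)
  p2f <- p2; p2f$ancestral[6] <- "alt"             # relabel polarity at core
  a2f <- popgenwin:::ihh_both(p2f, core, "ancestral", NULL, 0.05, 20000)
  d2f <- popgenwin:::ihh_both(p2f, core, "derived", NULL, 0.05, 20000)
  expect_equal(a2$ihh, d2f$ihh, tolerance = 1e-12)
  expect_equal(d2$ihh, a2f$ihh, tolerance = 1e-12)
})

test_that("iHS standardization yields mean 0 and unit variance per bin", {
  sim <- simulate_panel(fixture_spec(genome_length = 60000,
                                     accessible_frac = 1, n_samples = 12,
                                     theta = 0.003, gene_count = 0, seed = 14))
  sc <- ihs_scan(sim$panel, bin_width = 0.25, min_bin_size = 5)
  ok <- sc$qc_flag == "passed"
  expect_gt(sum(ok), 10)
  bins <- popgenwin:::merge_bins(floor(sc$freq[ok] / 0.25), 5)
  for (b in unique(bins)) {
    z <- sc$std[ok][bins == b]
    if (length(z) >= 2) {
      expect_equal(mean(z), 0, tolerance = 1e-8)
      expect_equal(sd(z), 1, tolerance = 1e-8)
    }
  }
})

test_that("sweeps produce negative iHS at the core; skipped sites obey the MAF filter", {
  sim <- simulate_panel(fixture_spec(genome_length = 60000,
                                     accessible_frac = 1, n_samples = 15,
                                     theta = 0.002, gene_count = 0, seed = 18))
  set.seed(18)
  swept <- inject_sweep(sim$panel, 30000, 25000, 0.6)
  core <- attr(swept, "core_pos")
  sc <- ihs_scan(swept)
  u <- sc$unstd[sc$position == core]
  expect_length(u, 1)
  expect_lt(u, 0)
  ## a MAF 0.04 site is absent from the scan output
  maf <- {
    cnt <- colSums(sim$panel$hap)
    pmin(cnt, nrow(sim$panel$hap) - cnt) / nrow(sim$panel$hap)
  }
  low <- sim$panel$pos[maf <= 0.05 & maf > 0]
  expect_false(any(low %in% ihs_scan(sim$panel)$position))
})

test_that("XP-EHH is zero between identical panels and positive for a sweep in A", {
  p <- random_panel(12, 14, seed = 91)
  sc <- xpehh_scan(p, p)
  expect_true(all(abs(sc$unstd[!is.na(sc$unstd)]) < 1e-12))
  sim <- simulate_panel(fixture_spec(genome_length = 60000,
                                     accessible_frac = 1, n_samples = 20,
                                     n_pops = 2, theta = 0.002,
                                     gene_count = 0, seed = 92))
  set.seed(92)
  pa <- subset_panel_pop(sim$panel, "POP1")
  pb <- subset_panel_pop(sim$panel, "POP2")
  swept_a <- inject_sweep(pa, 30000, 25000, 0.7)
  core <- attr(swept_a, "core_pos")
  sc2 <- xpehh_scan(swept_a, pb)
  u <- sc2$unstd[sc2$position == core]
  expect_length(u, 1)
  expect_gt(u, 0)
})

test_that("window summaries average absolute standardized scores", {
  scores <- structure(data.frame(position = c(100, 200, 300, 5000),
                                 freq = 0.5,
                                 unstd = c(-2, 1.5, 0.5, -1.7),
                                 std = c(-2, 1.5, 0.5, -1.7),
                                 qc_flag = "passed"),
                      class = c("hap_scan_scores", "data.frame"))
  w <- data.frame(chrom = "chr1", start = c(0, 1000, 4000),
                  end = c(1000, 2000, 6000))
  s <- summarize_window_scores(scores, w)
  expect_equal(s$mean_abs_score, c(4 / 3, NA, 1.7))
  expect_equal(s$n_snps, c(3L, 0L, 1L))
  ## invariant to sign flips
  scores$std <- -scores$std
  expect_equal(summarize_window_scores(scores, w)$mean_abs_score,
               s$mean_abs_score)
})
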