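test_that("site spectra count derived alleles with correct polarization", {
  hap <- rbind(c(1), c(1), c(1), c(0))
  p <- make_panel(hap, pos = 10)
  sp <- site_spectrum(p, list(start = 0, end = 100, accessible_bases = 100))
  expect_equal(sp$xi, c(0, 0, 1))                 # xi_3 = 1
  p2 <- make_panel(hap, pos = 10, ancestral = "alt")
  sp2 <- site_spectrum(p2, list(start = 0, end = 100, accessible_bases = 100))
  expect_equal(sp2$xi, c(1, 0, 0))                # flipped coding
  mono <- make_panel(matrix(0, 4, 1), pos = 10)
  sp3 <- site_spectrum(mono, list(start = 0, end = 100, accessible_bases = 100))
  expect_equal(sum(sp3$xi), 0)
})

test_that("diversity statistics match hand-computed examples", {
  ## n = 2, L = 10, one difference
  p <- make_panel(rbind(1, 0), pos = 5)
  d <- diversity_stats(p, list(start = 0, end = 10, accessible_bases = 10))
  expect_equal(d$pi_per_site, 0.1)
  ## n = 4, one site with 2 derived copies, L = 1: all 6 pairs enumerated
  p2 <- make_panel(rbind(1, 1, 0, 0), pos = 0)
  d2 <- diversity_stats(p2, list(start = 0, end = 1, accessible_bases = 1))
  expect_equal(d2$pi_per_site, 4 / 6)
  expect_equal(d2$hap_diversity, (4 / 3) * (1 - (2 * 0.5^2)))
  ## all haplotypes distinct
  p3 <- make_panel(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  d3 <- diversity_stats(p3, whole_window(p3))
  expect_equal(d3$hap_diversity, 1.0)
  ## identical haplotypes
  p4 <- make_panel(matrix(1, 4, 2))
  expect_equal(diversity_stats(p4, whole_window(p4))$hap_diversity, 0)
})

test_that("Jukes-Cantor correction and saturation guard", {
  expect_equal(-3 / 4 * log(1 - 4 * 0.05 / 3), 0.05174465,
               tolerance = 1e-6)
  ## divergence through the full path: 1 divergent site over 20 aligned
  hap <- rbind(c(1), c(1))
  p <- make_panel(hap, pos = 3)
  tr <- outgroup_track("chr1", 0, ref = rep("A", 20),
                       call = c(rep("A", 10), rep("C", 1), rep("A", 9)))
  p <- merge_outgroup_panel(p, tr)
  d <- diversity_stats(p, list(start = 0, end = 20, accessible_bases = 20), tr)
  ## fixed derived at pos 3 (outgroup A = ref, samples all alt) + 1 div-only
  expect_equal(d$divsites, 2)
  expect_equal(d$K_jc, -3 / 4 * log(1 - 4 * (2 / 20) / 3))
})

test_that("Tajima's D matches an independent recomputation and sign ordering", {
  expect_true(is.na(tajimas_d(site_spectrum(
    make_panel(matrix(0, 4, 1)), list(start = 0, end = 10, accessible_bases = 10)))))
  ## n = 4 panel with derived counts {1, 1, 2}
  hap <- rbind(c(1, 0, 1), c(0, 1, 1), c(0, 0, 0), c(0, 0, 0))
  p <- make_panel(hap)
  sp <- site_spectrum(p, whole_window(p))
  ## oracle: recompute pi, S and the variance constants from first principles
  n <- 4; S <- 3
  pi <- oracle_pi_total(hap)
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_oracle <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(sp), D_oracle, tolerance = 1e-12)
  ## singleton-heavy spectra are more negative than intermediate-heavy ones
  sp_singleton <- structure(list(n = 8, xi = c(5, 0, 0, 0, 0, 0, 0),
                                 folded_extra = integer(0), L = 100),
                            class = "site_spectrum")
  sp_mid <- structure(list(n = 8, xi = c(0, 0, 0, 5, 0, 0, 0),
                           folded_extra = integer(0), L = 100),
                      class = "site_spectrum")
  expect_lt(tajimas_d(sp_singleton), tajimas_d(sp_mid))
})

test_that("Fu and Li's tests have the expected signs and missing rule", {
  sp_all_single <- structure(list(n = 4, xi = c(3, 0, 0),
                                  folded_extra = integer(0), L = 100),
                             class = "site_spectrum")
  fl <- fu_li_tests(sp_all_single)
  expect_lt(fl$D, 0)                              # numerator S - a1*S < 0
  sp_no_single <- structure(list(n = 4, xi = c(0, 2, 1),
                                 folded_extra = integer(0), L = 100),
                            class = "site_spectrum")
  expect_gt(fu_li_tests(sp_no_single)$D, 0)       # numerator S - 0 > 0
  empty <- structure(list(n = 4, xi = c(0, 0, 0), folded_extra = integer(0),
                          L = 100), class = "site_spectrum")
  expect_true(is.na(fu_li_tests(empty)$D))
})

test_that("Fay and Wu's H matches hand enumeration", {
  sp3 <- structure(list(n = 4, xi = c(0, 0, 1), folded_extra = integer(0),
                        L = 1), class = "site_spectrum")
  expect_equal(fay_wu_h(sp3), 0.5 - 1.5)          # pi = 0.5, theta_H = 1.5
  sp1 <- structure(list(n = 4, xi = c(1, 0, 0), folded_extra = integer(0),
                        L = 1), class = "site_spectrum")
  expect_equal(fay_wu_h(sp1), 0.5 - 2 / 12)
  empty <- structure(list(n = 4, xi = c(0, 0, 0), folded_extra = integer(0),
                          L = 1), class = "site_spectrum")
  expect_true(is.na(fay_wu_h(empty)))
})

test_that("Zeng's E numerator and the pi + theta_H = 2 theta_L identity hold", {
  sp3 <- structure(list(n = 4, xi = c(0, 0, 1), folded_extra = integer(0),
                        L = 1), class = "site_spectrum")
  a1 <- 11 / 6
  e <- zeng_e(sp3)
  expect_gt(e, 0)                                 # theta_L = 1 > theta_W = 6/11
  sp1 <- structure(list(n = 4, xi = c(2, 0, 0), folded_extra = integer(0),
                        L = 1), class = "site_spectrum")
  expect_lt(zeng_e(sp1), 0)                       # theta_L = 2/3 < theta_W
  ## algebraic identity on random polarized spectra
  set.seed(9)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    xi <- rpois(n - 1, 1.2)
    pi_t <- sum(xi * 2 * seq_len(n - 1) * (n - seq_len(n - 1)) / (n * (n - 1)))
    th_H <- sum(2 * seq_len(n - 1)^2 * xi) / (n * (n - 1))
    th_L <- sum(seq_len(n - 1) * xi) / (n - 1)
    expect_equal(pi_t + th_H, 2 * th_L, tolerance = 1e-12)
  }
})

test_that("per-site statistics are invariant to window translation", {
  hap <- matrix(rbinom(6 * 8, 1, 0.4), nrow = 6)
  p1 <- make_panel(hap, pos = seq(10, 80, 10))
  p2 <- make_panel(hap, pos = seq(10, 80, 10) + 5000)
  w1 <- list(start = 0, end = 100, accessible_bases = 100)
  w2 <- list(start = 5000, end = 5100, accessible_bases = 100)
  d1 <- diversity_stats(p1, w1); d2 <- diversity_stats(p2, w2)
  expect_equal(d1$pi_per_site, d2$pi_per_site)
  expect_equal(d1$theta_w_per_site, d2$theta_w_per_site)
  expect_equal(tajimas_d(site_spectrum(p1, w1)),
               tajimas_d(site_spectrum(p2, w2)))
})

test_that("population subsetting recomputes segregation per population", {
  ## site fixed in POP1, segregating in POP2
  hap <- rbind(c(1), c(1), c(1), c(1), c(1), c(0), c(0), c(0))
  ns <- 4
  samples <- sprintf("S%02d", 1:ns)
  pops <- stats::setNames(c("POP1", "POP1", "POP2", "POP2"), samples)
  p <- hap_panel("chr1", 10, hap, "A", "G", "ref", samples, pops)
  w <- list(start = 0, end = 100, accessible_bases = 100)
  expect_equal(diversity_stats(p, w, pop = "POP1")$S, 0)
  expect_equal(diversity_stats(p, w, pop = "POP2")$S, 1)
})
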