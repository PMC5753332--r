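test_that("degeneracy classification matches hand-checked codons", {
  expect_equal(classify_coding_degeneracy("GGG", 2), "fourfold")  # all Gly
  expect_equal(classify_coding_degeneracy("ATG", 0), "zerofold")  # Met unique
  expect_equal(classify_coding_degeneracy("TGG", 2), "zerofold")  # TGA/TGC/TGT all change
  expect_equal(classify_coding_degeneracy("GAN", 1), "excluded")
  expect_equal(classify_coding_degeneracy("TTA", 0), "other")     # Leu twofold-ish
})

test_that("degeneracy agrees with the genetic-code oracle over all 64 codons x 3 positions", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (codon in codons) for (posn in 0:2)
    expect_identical(classify_coding_degeneracy(codon, posn),
                     oracle_degeneracy(codon, posn))
})

test_that("site class maps partition the gene extent by strand-aware rules", {
  ## gene: flank 500 | utr5 90 | CDS 300 | intron 150 | CDS 300 | utr3 120 | flank
  sim <- simulate_panel(fixture_spec(genome_length = 40000, gene_count = 2,
                                     accessible_frac = 1, seed = 33))
  for (g in sim$genes) {
    cmap <- build_site_class_map(g, sim$ref_seq)
    tab <- table(cmap$class)
    ## genomic layout is 90 bp before the CDS and 120 bp after; which is the
    ## 5' UTR depends on the strand
    if (g$strand == "+") {
      expect_equal(unname(tab["utr5"]), 90)
      expect_equal(unname(tab["utr3"]), 120)
    } else {
      expect_equal(unname(tab["utr5"]), 120)
      expect_equal(unname(tab["utr3"]), 90)
    }
    expect_equal(unname(tab["intron"]), 150)
    expect_equal(unname(tab["intergenic_flank"]), 1000)
    expect_false(cmap$internal_stop)
    cds_classes <- sum(tab[c("fourfold", "zerofold", "other")])
    expect_equal(unname(cds_classes), 600)
    ## classes are mutually exclusive and cover the extent
    expect_equal(length(cmap$pos), length(cmap$class))
    expect_equal(length(cmap$pos), g$end - g$start + 1000)
  }
  ## degeneracy is computed on the reverse complement for minus-strand genes:
  ## the two fixture genes share structure but differ in strand, and both
  ## yield valid degenerate classes
  minus <- sim$genes[[2]]
  expect_equal(minus$strand, "-")
  cm_minus <- build_site_class_map(minus, sim$ref_seq)
  expect_gt(sum(cm_minus$class == "fourfold"), 0)
})

test_that("internal stop codons withhold coding classes", {
  g <- gene_model("g", "t", "chr1", "+", exons = cbind(0, 30),
                  cds = cbind(0, 30))
  ## stop at codon 2; pad so the flank fits inside the reference
  ref <- paste0(paste(c("ATG", "TGA", rep("GGG", 8)), collapse = ""),
                strrep("G", 600))
  cmap <- build_site_class_map(g, ref)
  expect_true(cmap$internal_stop)
  expect_equal(sum(cmap$class %in% c("fourfold", "zerofold", "other")), 0)
})

test_that("flanks overlapping a neighboring transcript are excluded", {
  g1 <- gene_model("g1", "t1", "chr1", "+", exons = cbind(1000, 1300),
                   cds = cbind(1000, 1300))
  g2 <- gene_model("g2", "t2", "chr1", "+", exons = cbind(1400, 1700),
                   cds = cbind(1400, 1700))
  ref <- paste(rep("GGGG", 700), collapse = "")
  cmap <- build_site_class_map(g1, ref, other_genes = list(g1, g2))
  right_flank <- cmap$pos >= 1300
  expect_equal(sum(cmap$class[right_flank] == "excluded"), 300)
  expect_equal(sum(cmap$class[right_flank] == "intergenic_flank"), 200)
})

test_that("DAF spectra bin derived frequencies and normalize", {
  hap <- matrix(0, 20, 1); hap[1:7, 1] <- 1       # frequency 0.35
  p <- make_panel(hap, pos = 10)
  d <- daf_spectrum(p, sites = 10, bins = 10)
  expect_equal(d[4], 1)
  expect_equal(sum(d), 1)
  p2 <- random_panel(10, 8, seed = 61)
  d2 <- daf_spectrum(p2, sites = p2$pos, bins = 5)
  expect_equal(sum(d2), 1)
})

test_that("MKT counts partition P at the MAF cutoff and keep P and D exclusive", {
  ## 40 haplotypes; site A at MAF 0.025 (low), site B at MAF 0.25 (high),
  ## site C fixed derived vs outgroup, site D polymorphic and differing
  hap <- matrix(0, 40, 4)
  hap[1, 1] <- 1
  hap[1:10, 2] <- 1
  hap[, 3] <- 1
  hap[1:20, 4] <- 1
  p <- make_panel(hap, pos = c(10, 20, 30, 40),
                  ref = c("A", "A", "A", "A"), alt = c("G", "G", "G", "G"))
  ref_track <- rep("A", 60)
  call <- ref_track; call[41] <- "T"               # pos 40: outgroup T vs {A,G}: three-state
  tr <- outgroup_track("chr1", 0, ref = ref_track, call = call)
  p <- merge_outgroup_panel(p, tr)
  cmap <- structure(list(pos = 0:59, class = rep("fourfold", 60),
                         gene_id = "g", internal_stop = FALSE),
                    class = "site_class_map")
  cnt <- mkt_counts(p, tr, cmap, "fourfold")$test
  expect_equal(cnt$P_low, 1)
  expect_equal(cnt$P_high, 1)                      # three-state site excluded
  expect_equal(cnt$D, 1)                           # only the fixed-derived site
  expect_equal(cnt$m, 60)
})

test_that("standard MKT reproduces the hand-computed 2x2 table", {
  counts <- mkt_table(P_t = 2, D_t = 7, P_s = 42, D_s = 17)
  r <- standard_mkt(counts)
  expect_equal(r$NI, (2 / 42) / (7 / 17), tolerance = 1e-12)
  expect_equal(r$NI, 0.11565, tolerance = 1e-4)
  expect_equal(r$alpha_std, 0.88435, tolerance = 1e-4)
  expect_equal(r$DoS, 7 / 24 - 2 / 44, tolerance = 1e-12)
  expect_equal(r$DoS, 0.24621, tolerance = 1e-4)
  ## neutral expectation collapses to zero
  r0 <- standard_mkt(mkt_table(P_t = 10, D_t = 5, P_s = 20, D_s = 10))
  expect_equal(r0$alpha_std, 0)
  expect_equal(r0$DoS, 0)
  ## zero denominators give missing, never infinities
  expect_true(is.na(standard_mkt(mkt_table(P_t = 1, D_t = 1, P_s = 0,
                                           D_s = 1))$NI))
})

test_that("integrative MKT reproduces the worked example and its collapses", {
  counts <- mkt_table(P_t = 80, D_t = 40, P_s = 100, D_s = 60,
                      m_t = 1000, m_s = 1000, P_t_low = 50, P_s_low = 30)
  r <- integrative_mkt(counts)
  expect_equal(r$f, 30 * 100 / 70 / 100, tolerance = 1e-12)
  expect_equal(r$b, (50 - 30 * 30 / 70) / 100, tolerance = 1e-12)
  expect_equal(r$d, 1 - r$f - r$b, tolerance = 1e-12)
  expect_equal(r$f, 0.4286, tolerance = 1e-3)
  expect_equal(r$b, 0.3714, tolerance = 1e-3)
  expect_equal(r$d, 0.2000, tolerance = 1e-3)
  expect_equal(r$alpha_cor, 0.3571, tolerance = 1e-3)
  expect_equal(r$alpha_std, -0.2, tolerance = 1e-10)
  expect_false(r$clamped)
  expect_equal(r$d + r$b + r$f, 1, tolerance = 1e-12)
  ## no low-frequency excess: correction collapses to the standard test
  c2 <- mkt_table(P_t = 40, D_t = 40, P_s = 100, D_s = 60,
                  m_t = 1000, m_s = 1000, P_t_low = 12, P_s_low = 30)
  r2 <- integrative_mkt(c2)
  expect_equal(r2$b, 0, tolerance = 1e-12)
  expect_equal(r2$alpha_cor, r2$alpha_std, tolerance = 1e-12)
  ## removing a deleterious excess cannot lower alpha
  expect_gt(r$alpha_cor, r$alpha_std)
})

test_that("DoS and alpha share their sign when both defined", {
  set.seed(71)
  for (k in 1:30) {
    tab <- mkt_table(P_t = sample(1:30, 1), D_t = sample(1:30, 1),
                     P_s = sample(1:30, 1), D_s = sample(1:30, 1))
    r <- standard_mkt(tab)
    if (!is.na(r$NI) && abs(r$NI - 1) > 1e-9)
      expect_equal(sign(r$DoS), sign(r$alpha_std))
  }
})

test_that("longest codable transcript is selected deterministically", {
  short <- gene_model("g1", "tS", "chr1", "+", cbind(0, 120), cbind(0, 120))
  long <- gene_model("g1", "tL", "chr1", "+", cbind(0, 300), cbind(0, 300))
  broken <- gene_model("g1", "tB", "chr1", "+", cbind(0, 1000), cbind(0, 1000))
  expect_false(broken$codable)                    # 1000 not divisible by 3
  pick <- longest_transcript_per_gene(list(short, broken, long))
  expect_equal(pick[["g1"]]$transcript_id, "tL")
})
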