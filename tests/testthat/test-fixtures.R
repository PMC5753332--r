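test_that("simulation is deterministic under its seed", {
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_panel(fixture_spec(genome_length = 20000, n_samples = 8,
                                    theta = 0.002, seed = 5), dir = d1)
  s2 <- simulate_panel(fixture_spec(genome_length = 20000, n_samples = 8,
                                    theta = 0.002, seed = 5), dir = d2)
  for (f in names(s1$files))
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]))
  s3 <- simulate_panel(fixture_spec(genome_length = 20000, n_samples = 8,
                                    theta = 0.002, seed = 6))
  expect_false(identical(s1$panel$pos, s3$panel$pos))
})

test_that("emitted files re-read into the simulated objects", {
  sim <- simulate_panel(fixture_spec(genome_length = 30000, n_samples = 6,
                                     n_pops = 2, theta = 0.002, seed = 8),
                        dir = tempfile())
  p <- read_vcf_panel(sim$files[["vcf"]], sim$files[["panel"]])
  expect_equal(p$pos, sim$panel$pos)
  expect_equal(unname(p$hap), unname(sim$panel$hap))
  expect_equal(p$ancestral, sim$panel$ancestral)
  expect_equal(unname(p$pops), unname(sim$panel$pops))
  m <- read_mask_bed(sim$files[["bed"]])
  expect_equal(unname(m[[1]]), unname(sim$mask[[1]]))
  tr <- pairwise_mfa_to_outgroup(sim$files[["mfa"]])
  expect_equal(tr$ref, sim$outgroup$ref)
  expect_equal(tr$call, sim$outgroup$call)
  genes <- read_gene_models(sim$files[["gff"]])
  expect_equal(length(genes), length(sim$genes))
  expect_equal(genes[[1]]$cds, sim$genes[[1]]$cds, ignore_attr = TRUE)
  map <- read_genetic_map(sim$files[["map"]])
  expect_equal(map$pos, sim$map$pos)
  expect_equal(map$cM, sim$map$cM)
})

test_that("an inaccessible genome yields a valid empty panel", {
  sim <- simulate_panel(fixture_spec(genome_length = 10000,
                                     accessible_frac = 0, n_samples = 4,
                                     gene_count = 0, seed = 3),
                        dir = tempfile())
  expect_equal(length(sim$panel$pos), 0)
  expect_equal(nrow(sim$mask[[1]]), 0)
  p <- read_vcf_panel(sim$files[["vcf"]], sim$files[["panel"]])
  expect_equal(length(p$pos), 0)
})

test_that("Watterson's estimator is centered on the simulated theta", {
  reps <- 60
  est <- numeric(reps)
  for (k in seq_len(reps)) {
    sim <- simulate_panel(fixture_spec(genome_length = 20000,
                                       accessible_frac = 1, n_samples = 10,
                                       theta = 0.002, gene_count = 0,
                                       seed = 7000 + k))
    w <- list(start = 0, end = 20000, accessible_bases = 20000)
    est[k] <- diversity_stats(sim$panel, w)$theta_w_per_site
  }
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.002), 3 * se)
})

test_that("sweep injection forces EHH of the derived core allele to 1 over its span", {
  sim <- simulate_panel(fixture_spec(genome_length = 50000,
                                     accessible_frac = 1, n_samples = 12,
                                     theta = 0.002, gene_count = 0, seed = 12))
  set.seed(12)
  swept <- inject_sweep(sim$panel, 25000, 20000, 0.5)
  core <- attr(swept, "core_pos")
  cv <- ehh_curve(swept, core, "derived", "right")
  span <- cv$pos <= core + 10000
  expect_true(all(cv$ehh[span] == 1))
  ## zero sweep length leaves the panel unchanged
  expect_identical(inject_sweep(sim$panel, 25000, 0, 0.5), sim$panel)
  expect_error(inject_sweep(sim$panel, 25000, 1000, 1.2), "carrier_frac")
})

test_that("deleterious injection raises only the test class's low-MAF counts", {
  sim <- simulate_panel(fixture_spec(genome_length = 40000,
                                     accessible_frac = 1, n_samples = 20,
                                     theta = 0.008, divergence = 0.03,
                                     gene_count = 2, cds_bp = 1500, seed = 44))
  cmap <- build_site_class_map(sim$genes[[1]], sim$ref_seq)
  before <- mkt_counts(sim$panel, sim$outgroup, cmap, "zerofold")
  set.seed(45)
  pan <- inject_deleterious_class(sim$panel, cmap, 0.25, sim$outgroup)
  after <- mkt_counts(pan, sim$outgroup, cmap, "zerofold")
  expect_gt(after$test$P_low, before$test$P_low)
  expect_equal(after$neutral$P, before$neutral$P)      # neutral class untouched
  expect_equal(after$neutral$P_low, before$neutral$P_low)
  expect_equal(after$test$D, before$test$D)            # no divergence added
  ## fraction 0 is a no-op
  expect_identical(inject_deleterious_class(sim$panel, cmap, 0, sim$outgroup),
                   sim$panel)
})
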