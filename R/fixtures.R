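#' Specification for a synthetic input set
#'
#' Describes a toy "genome" emulating the pipeline's input ensemble: an
#' accessibility mask with accessible/inaccessible runs, a phased biallelic
#' panel whose segregating sites follow the neutral frequency expectation
#' (derived-count classes with probability proportional to 1/i, sites
#' independent), an outgroup sequence at a controlled divergence, a handful
#' of protein-coding gene models, and a linear genetic map.
#'
#' @param genome_length genome length in bp.
#' @param accessible_frac fraction of the genome accessible.
#' @param run_scale mean accessible run length in bp (inaccessible runs are
#'   scaled to hit `accessible_frac`).
#' @param n_samples number of diploid samples (2x haplotypes).
#' @param n_pops number of populations; samples assigned round-robin.
#' @param theta per-site diversity target (Watterson scale).
#' @param divergence per-site outgroup divergence rate.
#' @param gene_count number of gene models to place.
#' @param cds_bp total CDS length per gene (rounded to a multiple of 6; the
#'   CDS is split across two exons).
#' @param cM_per_Mb constant recombination rate of the linear map.
#' @param chrom chromosome name.
#' @param seed mandatory RNG seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(genome_length = 100000, accessible_frac = 0.9,
                         run_scale = 5000, n_samples = 20, n_pops = 1,
                         theta = 0.001, divergence = 0.01, gene_count = 2,
                         cds_bp = 600, cM_per_Mb = 1, chrom = "chr1", seed) {
  if (missing(seed)) stop("a seed is mandatory for fixture generation")
  stopifnot(accessible_frac >= 0, accessible_frac <= 1,
            divergence >= 0, divergence <= 1, theta >= 0)
  structure(list(genome_length = genome_length,
                 accessible_frac = accessible_frac, run_scale = run_scale,
                 n_samples = n_samples, n_pops = n_pops, theta = theta,
                 divergence = divergence, gene_count = gene_count,
                 cds_bp = 6 * round(cds_bp / 6),
                 cM_per_Mb = cM_per_Mb, chrom = chrom, seed = seed),
            class = "fixture_spec")
}

## alternating accessible/inaccessible run lengths covering the genome
simulate_mask_runs <- function(len, frac, run_scale) {
  if (frac >= 1) return(matrix(c(0, len), ncol = 2,
                               dimnames = list(NULL, c("start", "end"))))
  if (frac <= 0) return(matrix(numeric(0), ncol = 2,
                               dimnames = list(NULL, c("start", "end"))))
  gap_scale <- run_scale * (1 - frac) / frac
  runs <- list(); at <- 0; accessible <- stats::runif(1) < frac
  while (at < len) {
    w <- ceiling(stats::rexp(1, 1 / if (accessible) run_scale else gap_scale))
    w <- min(w, len - at)
    if (accessible) runs[[length(runs) + 1L]] <- c(at, at + w)
    at <- at + w
    accessible <- !accessible
  }
  if (length(runs) == 0L) runs <- list(c(0, min(run_scale, len)))
  do.call(rbind, runs)
}

## evenly spaced two-exon gene models (utr5 | CDS .. intron .. CDS | utr3)
simulate_genes <- function(spec) {
  if (spec$gene_count < 1) return(list())
  cds1 <- spec$cds_bp / 2; cds2 <- spec$cds_bp / 2
  utr5 <- 90; intr <- 150; utr3 <- 120
  glen <- utr5 + cds1 + intr + cds2 + utr3
  pitch <- spec$genome_length / spec$gene_count
  if (pitch < glen + 2000)
    stop("genome too short for the requested gene count")
  lapply(seq_len(spec$gene_count), function(i) {
    s <- round((i - 0.5) * pitch - glen / 2)
    e1 <- c(s, s + utr5 + cds1)
    e2 <- c(e1[2L] + intr, e1[2L] + intr + cds2 + utr3)
    cds <- rbind(c(s + utr5, e1[2L]), c(e2[1L], e2[1L] + cds2))
    gene_model(gene_id = sprintf("gene%d", i),
               transcript_id = sprintf("tx%d", i),
               chrom = spec$chrom,
               strand = if (i %% 2 == 1) "+" else "-",
               exons = rbind(e1, e2), cds = cds)
  })
}

#' Simulate a complete synthetic input set
#'
#' Generates reference and outgroup sequences, an accessibility mask, a
#' phased haplotype panel with neutral-expectation site frequencies
#' (P(derived count = i) proportional to 1/i, independent sites placed
#' uniformly on accessible positions, S drawn Poisson with mean
#' theta * a1 * accessible bases so Watterson's estimator is centered on
#' theta), gene models and a linear genetic map -- all deterministic under
#' the spec's seed. With `dir` given, the set is also written as
#' VCF / BED / two-sequence MFA / GFF3 / panel TSV / map TSV, re-readable
#' by the package's readers.
#'
#' @param spec a [fixture_spec].
#' @param dir optional output directory for the file renditions.
#' @return A list of class `sim_panel`: `panel` ([hap_panel], outgroup
#'   annotated), `outgroup` ([outgroup_track]), `mask` ([access_mask]),
#'   `genes` (list of [gene_model]), `map` ([genetic_map]), `ref_seq`
#'   (character), `spec`, and `files` (named paths when written).
#' @export
simulate_panel <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  L <- spec$genome_length
  bases <- c("A", "C", "G", "T")
  ref_vec <- sample(bases, L, replace = TRUE)
  genes <- simulate_genes(spec)
  ## write stop-free coding sequence into each CDS so degeneracy classes
  ## exist and no internal stop flags fire
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (g in genes) {
    cds_pos <- segment_positions(g$cds)
    ncod <- length(cds_pos) %/% 3L
    coding <- unlist(strsplit(sample(sense, ncod, replace = TRUE), ""))
    if (g$strand == "-")
      coding <- rev(chartr("ACGT", "TGCA", coding))
    ref_vec[cds_pos + 1L] <- coding
  }
  mask <- access_mask(stats::setNames(
    list(simulate_mask_runs(L, spec$accessible_frac, spec$run_scale)),
    spec$chrom))
  acc_pos <- accessible_positions(mask, spec$chrom, 0, L)
  nh <- 2L * spec$n_samples
  cons <- sample_constants(max(nh, 2L))
  expS <- spec$theta * cons$a1 * length(acc_pos)
  S <- stats::rpois(1, expS)
  if (S > length(acc_pos))
    stop("theta too high for the accessible genome length")
  pos <- sort(sample(acc_pos, S))
  i_class <- seq_len(nh - 1L)
  der_count <- sample(i_class, S, replace = TRUE, prob = 1 / i_class)
  hap <- matrix(0L, nrow = nh, ncol = S)
  for (j in seq_len(S))
    hap[sample.int(nh, der_count[j]), j] <- 1L
  ref_al <- ref_vec[pos + 1L]
  alt_al <- vapply(ref_al, function(b) sample(setdiff(bases, b), 1L), "")
  ## outgroup: reference mutated at the divergence rate
  out_vec <- ref_vec
  nmut <- stats::rbinom(1, L, spec$divergence)
  mut_pos <- sample.int(L, nmut)
  out_vec[mut_pos] <- vapply(ref_vec[mut_pos],
                             function(b) sample(setdiff(bases, b), 1L), "")
  samples <- sprintf("S%02d", seq_len(spec$n_samples))
  pops <- stats::setNames(sprintf("POP%d", ((seq_len(spec$n_samples) - 1L) %%
                                              spec$n_pops) + 1L), samples)
  panel <- hap_panel(chrom = spec$chrom, pos = pos, hap = hap,
                     ref = ref_al, alt = alt_al,
                     ancestral = rep("ref", S), samples = samples,
                     pops = pops)
  track <- outgroup_track(spec$chrom, 0, ref = ref_vec, call = out_vec)
  panel <- merge_outgroup_panel(panel, track)
  map <- genetic_map(c(0, L), c(0, spec$cM_per_Mb * L / 1e6))
  sim <- structure(list(panel = panel, outgroup = track, mask = mask,
                        genes = genes, map = map,
                        ref_seq = paste(ref_vec, collapse = ""),
                        spec = spec, files = NULL),
                   class = "sim_panel")
  if (!is.null(dir)) sim$files <- write_fixture_files(sim, dir)
  sim
}

#' Write a simulated input set to disk
#'
#' Emits the simulated panel as a phased VCF with `AA` annotations, the mask
#' as BED, the reference/outgroup pair as a two-sequence aligned MFA, gene
#' models as GFF3, the sample-to-population table as TSV and the genetic map
#' as TSV.
#'
#' @param sim a [simulate_panel] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths.
#' @export
write_fixture_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  files <- c(vcf = p("panel.vcf"), bed = p("mask.bed"), mfa = p("outgroup.mfa"),
             gff = p("genes.gff3"), panel = p("samples.panel"),
             map = p("map.tsv"))
  panel <- sim$panel
  n <- length(panel$samples)
  con <- file(files[["vcf"]], "wt")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", sim$spec$chrom,
                       sim$spec$genome_length),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")), con)
  if (length(panel$pos)) {
    gts <- vapply(seq_along(panel$pos), function(j) {
      a1 <- panel$hap[seq(1L, 2L * n, 2L), j]
      a2 <- panel$hap[seq(2L, 2L * n, 2L), j]
      paste(paste0(a1, "|", a2), collapse = "\t")
    }, "")
    aa <- ifelse(panel$ancestral == "alt", panel$alt, panel$ref)
    writeLines(paste(panel$chrom, panel$pos + 1,
                     sprintf("snp%d", seq_along(panel$pos)),
                     panel$ref, panel$alt, ".", "PASS",
                     paste0("AA=", aa), "GT", gts, sep = "\t"), con)
  }
  close(con)
  iv <- sim$mask[[sim$spec$chrom]]
  bed <- if (is.null(iv) || nrow(iv) == 0L) character(0) else
    paste(sim$spec$chrom, format(iv[, 1L], scientific = FALSE, trim = TRUE),
          format(iv[, 2L], scientific = FALSE, trim = TRUE), sep = "\t")
  writeLines(bed, files[["bed"]])
  writeLines(c(sprintf(">%s reference", sim$spec$chrom), sim$ref_seq,
               ">outgroup aligned",
               paste(ifelse(is.na(sim$outgroup$call), "N", sim$outgroup$call),
                     collapse = "")),
             files[["mfa"]])
  write_genes_gff3(sim$genes, files[["gff"]])
  writeLines(paste(panel$samples, panel$pops, sep = "\t"), files[["panel"]])
  writeLines(c("position\tcM",
               paste(format(sim$map$pos, scientific = FALSE, trim = TRUE),
                     sim$map$cM, sep = "\t")), files[["map"]])
  files
}

write_genes_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines,
               paste(g$chrom, "sim", "gene", g$start + 1, g$end, ".",
                     g$strand, ".", sprintf("ID=%s", g$gene_id), sep = "\t"),
               paste(g$chrom, "sim", "mRNA", g$start + 1, g$end, ".",
                     g$strand, ".",
                     sprintf("ID=%s;Parent=%s", g$transcript_id, g$gene_id),
                     sep = "\t"))
    for (i in seq_len(nrow(g$exons)))
      lines <- c(lines, paste(g$chrom, "sim", "exon", g$exons[i, 1L] + 1,
                              g$exons[i, 2L], ".", g$strand, ".",
                              sprintf("Parent=%s", g$transcript_id), sep = "\t"))
    for (i in seq_len(nrow(g$cds)))
      lines <- c(lines, paste(g$chrom, "sim", "CDS", g$cds[i, 1L] + 1,
                              g$cds[i, 2L], ".", g$strand, "0",
                              sprintf("Parent=%s", g$transcript_id), sep = "\t"))
  }
  writeLines(lines, path)
}

#' Inject a selective-sweep haplotype pattern
#'
#' Makes a fraction of haplotypes identical over a region around a core
#' site, carrying the derived allele there -- the footprint a recent hard
#' sweep leaves and the signal iHS / XP-EHH detect. Non-carriers are
#' untouched. A zero sweep length returns the panel unchanged.
#'
#' @param panel a [hap_panel].
#' @param core_pos approximate core position; the nearest polarized site is
#'   used.
#' @param sweep_length length of the homogenized region in bp.
#' @param carrier_frac fraction of haplotypes carrying the sweep, in (0, 1).
#' @return The modified [hap_panel]; the chosen core position is attached
#'   as attribute `"core_pos"`.
#' @export
inject_sweep <- function(panel, core_pos, sweep_length, carrier_frac) {
  if (carrier_frac <= 0 || carrier_frac >= 1)
    stop("carrier_frac must be in (0, 1)")
  if (sweep_length <= 0) return(panel)
  polar <- which(panel$ancestral != "unknown" & !panel$three_state)
  if (length(polar) == 0L) stop("no polarized site available for a sweep core")
  ci <- polar[which.min(abs(panel$pos[polar] - core_pos))]
  core <- panel$pos[ci]
  nh <- nrow(panel$hap)
  nc <- max(2L, round(carrier_frac * nh))
  carriers <- sample.int(nh, nc)
  derived_code <- if (panel$ancestral[ci] == "ref") 1L else 0L
  span <- which(panel$pos >= core - sweep_length / 2 &
                  panel$pos <= core + sweep_length / 2)
  template <- panel$hap[carriers[1L], span]
  for (r in carriers) panel$hap[r, span] <- template
  panel$hap[carriers, ci] <- derived_code
  panel$hap[-carriers, ci] <- 1L - derived_code
  attr(panel, "core_pos") <- core
  panel
}

#' Inject low-frequency variants into one site class
#'
#' Adds segregating singleton sites (MAF below the cutoff) at unoccupied
#' positions of the target class, raising the slightly-deleterious excess
#' that the integrative MKT's `b` estimates. The number of added sites is
#' chosen so that the expected recovered `b` equals `fraction`:
#' `round(fraction * P_s * m_t / m_s)` with `P_s`, `m_t`, `m_s` computed
#' from the current panel and class map. The neutral class is untouched.
#'
#' @param panel an outgroup-annotated [hap_panel].
#' @param class_map a [build_site_class_map] result.
#' @param fraction target `b` fraction in `[0, 1)`.
#' @param outgroup the [outgroup_track] (new sites are placed where the
#'   outgroup matches the reference, so divergence counts are unchanged).
#' @param test_class class receiving the excess (default `"zerofold"`).
#' @param neutral_class calibrating neutral class (default `"fourfold"`).
#' @param mask optional [access_mask] consistent with downstream counting.
#' @return The modified [hap_panel].
#' @export
inject_deleterious_class <- function(panel, class_map, fraction, outgroup,
                                     test_class = "zerofold",
                                     neutral_class = "fourfold",
                                     mask = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(panel)
  nh <- nrow(panel$hap)
  if (1 / nh >= 0.05)
    stop("too few haplotypes for singleton MAF to fall below the 5% cutoff")
  site_pool <- function(cls) {
    cpos <- class_positions(class_map, cls)
    if (!is.null(mask)) cpos <- cpos[is_accessible(mask, panel$chrom, cpos)]
    cpos[outgroup_aligned_at(outgroup, cpos)]
  }
  tpos <- site_pool(test_class)
  spos <- site_pool(neutral_class)
  m_t <- length(tpos); m_s <- length(spos)
  if (m_t == 0L || m_s == 0L) stop("empty site class")
  jseg <- which(panel$pos %in% spos)
  cnt <- if (length(jseg)) colSums(panel$hap[, jseg, drop = FALSE]) else integer(0)
  P_s <- sum(cnt > 0 & cnt < nh)
  if (P_s == 0L) stop("neutral class has no segregating sites to calibrate against")
  n_add <- round(fraction * P_s * m_t / m_s)
  if (n_add == 0L) return(panel)
  free <- setdiff(tpos, panel$pos)
  oc <- outgroup_call_at(outgroup, free)
  ref_at <- outgroup$ref[free - outgroup$offset + 1L]
  free <- free[!is.na(oc) & oc == ref_at]
  if (n_add > length(free))
    stop("requested fraction exceeds the achievable site density")
  new_pos <- sort(sample(free, n_add))
  bases <- c("A", "C", "G", "T")
  new_ref <- outgroup$ref[new_pos - outgroup$offset + 1L]
  new_alt <- vapply(new_ref, function(b) sample(setdiff(bases, b), 1L), "")
  new_hap <- matrix(0L, nrow = nh, ncol = n_add)
  new_hap[cbind(sample.int(nh, n_add, replace = TRUE), seq_len(n_add))] <- 1L
  ord <- order(c(panel$pos, new_pos))
  out <- panel
  out$pos <- c(panel$pos, new_pos)[ord]
  out$hap <- cbind(panel$hap, new_hap)[, ord, drop = FALSE]
  out$ref <- c(panel$ref, new_ref)[ord]
  out$alt <- c(panel$alt, new_alt)[ord]
  out$ancestral <- c(panel$ancestral, rep("ref", n_add))[ord]
  out$outgroup <- c(panel$outgroup, new_ref)[ord]
  out$three_state <- c(panel$three_state, rep(FALSE, n_add))[ord]
  out
}
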