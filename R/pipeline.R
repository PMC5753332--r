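#' Windows-based statistic vocabulary
#'
#' Track names of the frequency, divergence, linkage-disequilibrium and
#' SFS-test statistics computed per window per population.
#' @return Character vector of statistic names.
#' @export
windows_statistics <- function() {
  c("S", "Pi", "theta", "hap_diversity_within", "Divsites", "K",
    "Kelly_ZnS", "Rozas_ZA", "Rozas_ZZ", "Wall_B", "Wall_Q",
    "Tajima_D", "FuLi_D", "FuLi_F", "FayWu_H", "Zeng_E")
}

#' Assemble a run configuration
#'
#' Collects the input paths and run-level constants of a full analysis:
#' window sizes (10 kb fully accessible, 100 kb fixed), the scan MAF filter
#' and MKT MAF partition (both 0.05), the +/- 500 bp gene flank, the
#' populations to analyze and the output directory.
#'
#' @param vcf,mask,gff,outgroup,map,panel input file paths (map optional;
#'   gff/outgroup needed for gene analyses).
#' @param pops populations to analyze (default: all in the panel table).
#' @param pop_pairs list of 2-vectors for XP-EHH (default: all pairs).
#' @param out_dir output directory for track files.
#' @param window_sizes accessible and fixed window sizes in bp.
#' @param chrom_sizes optional named vector or chrom.sizes path for the
#'   fixed windows (default: inferred from the mask extent).
#' @param maf_scan MAF filter for haplotype scans (sites kept when MAF
#'   exceeds it).
#' @param maf_mkt MAF partition point of the integrative MKT.
#' @param flank_size intergenic flank in bp.
#' @param statistics statistic toggles (default [windows_statistics]).
#' @param exclude_samples sample ids dropped at read time.
#' @param include_sex_chromosomes scan chrX/chrY too (default FALSE).
#' @param seed RNG seed recorded with the run (the analyses themselves are
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, mask, gff = NULL, outgroup = NULL, map = NULL,
                       panel, pops = NULL, pop_pairs = NULL, out_dir = NULL,
                       window_sizes = c(10000, 100000), chrom_sizes = NULL,
                       maf_scan = 0.05, maf_mkt = 0.05, flank_size = 500,
                       statistics = windows_statistics(),
                       exclude_samples = character(),
                       include_sex_chromosomes = FALSE, seed = 1) {
  for (f in c(vcf, mask, gff, outgroup, map, panel))
    if (is.character(f) && !file.exists(f)) stop("missing input file: ", f)
  stopifnot(all(window_sizes > 0))
  structure(list(vcf = vcf, mask = mask, gff = gff, outgroup = outgroup,
                 map = map, panel = panel, pops = pops,
                 pop_pairs = pop_pairs, out_dir = out_dir,
                 window_sizes = window_sizes, chrom_sizes = chrom_sizes,
                 maf_scan = maf_scan, maf_mkt = maf_mkt,
                 flank_size = flank_size, statistics = statistics,
                 exclude_samples = exclude_samples,
                 include_sex_chromosomes = include_sex_chromosomes,
                 seed = seed),
            class = "run_config")
}

load_run_inputs <- function(config) {
  panel <- read_vcf_panel(config$vcf, config$panel,
                          exclude_samples = config$exclude_samples)
  mask <- read_mask_bed(config$mask)
  outgroup <- if (!is.null(config$outgroup))
    pairwise_mfa_to_outgroup(config$outgroup, chrom = panel$chrom) else NULL
  if (!is.null(outgroup)) panel <- merge_outgroup_panel(panel, outgroup)
  pops <- config$pops
  if (is.null(pops)) pops <- sort(unique(panel$pops))
  missing_pops <- setdiff(pops, panel$pops)
  if (length(missing_pops))
    stop("populations absent from panel: ", paste(missing_pops, collapse = ", "))
  map <- if (!is.null(config$map)) read_genetic_map(config$map) else NULL
  genes <- if (!is.null(config$gff))
    read_gene_models(config$gff, flank_size = config$flank_size) else NULL
  list(panel = panel, mask = mask, outgroup = outgroup, map = map,
       genes = genes, pops = pops)
}

window_sets <- function(config, inputs) {
  mask <- inputs$mask
  acc <- place_accessible_windows(mask, size = config$window_sizes[1L])
  sizes <- config$chrom_sizes
  if (is.character(sizes)) sizes <- read_chrom_sizes(sizes)
  if (is.null(sizes))
    sizes <- vapply(mask, function(iv)
      if (nrow(iv)) max(iv[, 2L]) else 0, 0)
  sizes <- sizes[sizes > 0]
  fixed <- if (length(config$window_sizes) > 1L && length(sizes))
    place_fixed_windows(sizes, size = config$window_sizes[2L], mask) else NULL
  rbind(acc, fixed)
}

## all Table-2-style statistics of one window for one population
compute_window_stats <- function(panel, window, outgroup, mask, pop,
                                 statistics) {
  sp <- site_spectrum(panel, window, pop)
  dv <- diversity_stats(panel, window, outgroup, mask, pop)
  fl <- fu_li_tests(sp)
  zazz <- rozas_za_zz(panel, window, pop)
  bq <- wall_b_q(panel, window, pop)
  vals <- c(S = dv$S_per_site, Pi = dv$pi_per_site,
            theta = dv$theta_w_per_site,
            hap_diversity_within = dv$hap_diversity,
            Divsites = dv$divsites, K = dv$K_jc,
            Kelly_ZnS = kelly_zns(panel, window, pop),
            Rozas_ZA = zazz$za, Rozas_ZZ = zazz$zz,
            Wall_B = bq$b, Wall_Q = bq$q,
            Tajima_D = tajimas_d(sp), FuLi_D = fl$D, FuLi_F = fl$F,
            FayWu_H = fay_wu_h(sp), Zeng_E = zeng_e(sp))
  if (window$accessible_bases <= 0) vals[] <- NA_real_
  vals[statistics]
}

#' Run the windows-based analysis
#'
#' Places both window schemes under the mask, computes every enabled
#' statistic per window per population, and (when `out_dir` is set) writes
#' one bedGraph per statistic x population x scheme, plus recombination
#' tracks when a genetic map is configured. Fully deterministic: rerunning
#' an identical configuration reproduces the output bytes.
#'
#' @param config a [run_config].
#' @return A data.frame of window statistic rows (with a `scheme` column).
#' @export
run_windows_analysis <- function(config) {
  inputs <- load_run_inputs(config)
  windows <- window_sets(config, inputs)
  rows <- list()
  for (pop in inputs$pops) {
    for (i in seq_len(nrow(windows))) {
      w <- windows[i, ]
      vals <- compute_window_stats(inputs$panel, w, inputs$outgroup,
                                   inputs$mask, pop, config$statistics)
      rows[[length(rows) + 1L]] <-
        cbind(window_stats_row(w$chrom, w$start, w$end, pop,
                               names(vals), unname(vals)),
              scheme = w$scheme)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(inputs$map)) {
    rec <- window_recomb_rate(inputs$map, windows)
    out <- rbind(out, cbind(window_stats_row(windows$chrom, windows$start,
                                             windows$end, "all",
                                             "recomb_sexavg", rec),
                            scheme = windows$scheme))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (stat in unique(out$statistic)) {
      for (pop in unique(out$population[out$statistic == stat])) {
        for (sch in unique(out$scheme)) {
          sel <- out$statistic == stat & out$population == pop &
            out$scheme == sch
          if (!any(sel)) next
          write_track(out[sel, ], "bedGraph",
                      file.path(config$out_dir,
                                sprintf("%s_%s_%s.bedGraph", stat, pop, sch)))
        }
      }
    }
  }
  out
}

#' Run the genes-based MKT analysis
#'
#' Collapses multi-transcript genes to their longest codable transcript,
#' builds a site-class map per gene (degeneracy classes from the outgroup
#' alignment's reference sequence), and per gene x population x test class
#' reports the standard and integrative MKT against 4-fold sites, plus
#' whole-gene descriptive diversity and divergence. Uncodable genes yield
#' descriptive rows with MKT fields missing.
#'
#' @param config a [run_config] (gff and outgroup inputs required).
#' @return A data.frame with one row per gene x population x test class;
#'   written as `genes_mkt.tsv` under `out_dir` when set.
#' @export
run_genes_analysis <- function(config) {
  if (is.null(config$gff) || is.null(config$outgroup))
    stop("gene analysis needs gff and outgroup inputs")
  inputs <- load_run_inputs(config)
  genes <- longest_transcript_per_gene(inputs$genes)
  ref_seq <- paste(inputs$outgroup$ref, collapse = "")
  test_classes <- c("zerofold", "utr5", "utr3", "intron", "intergenic_flank")
  rows <- list()
  for (g in genes) {
    cmap <- build_site_class_map(g, ref_seq, other_genes = inputs$genes)
    ext_start <- min(cmap$pos); ext_end <- max(cmap$pos) + 1
    for (pop in inputs$pops) {
      gw <- list(start = ext_start, end = ext_end,
                 accessible_bases = accessible_bases(inputs$mask, g$chrom,
                                                     ext_start, ext_end))
      dv <- diversity_stats(inputs$panel, gw, inputs$outgroup, inputs$mask,
                            pop)
      for (cls in test_classes) {
        cnt <- mkt_counts(inputs$panel, inputs$outgroup, cmap, cls,
                          pop = pop, mask = inputs$mask,
                          maf_cutoff = config$maf_mkt)
        r <- integrative_mkt(cnt, maf_cutoff = config$maf_mkt)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, population = pop, class = cls,
          m = cnt$test$m, P_low = cnt$test$P_low, P_high = cnt$test$P_high,
          D = cnt$test$D, pi = cnt$test$pi, K = cnt$test$K,
          m_neutral = cnt$neutral$m, P_neutral = cnt$neutral$P,
          D_neutral = cnt$neutral$D,
          gene_pi = dv$pi_per_site, gene_K = dv$K_jc,
          alpha_std = r$alpha_std, alpha_pik = r$alpha_pik, NI = r$NI,
          DoS = r$DoS, d = r$d, b = r$b, f = r$f, f_old = r$f_old,
          gamma = r$gamma, alpha_cor = r$alpha_cor,
          flags = paste(c(if (isTRUE(r$clamped)) "clamped",
                          if (cmap$internal_stop) "internal_stop",
                          if (!g$codable) "non_codable"), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(format(out, digits = 10, trim = TRUE),
                       file.path(config$out_dir, "genes_mkt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run the haplotype-based selection scans
#'
#' iHS per population and XP-EHH per population pair (autosomes only by
#' default), summarized per accessible window as the mean absolute
#' standardized score. Per-site scores are written as TSV and window
#' summaries as bedGraph under `out_dir`.
#'
#' @param config a [run_config].
#' @return A list with `scores` (named list of per-site score frames) and
#'   `summaries` (named list of window summary frames).
#' @export
run_hap_scan <- function(config) {
  inputs <- load_run_inputs(config)
  panel <- inputs$panel
  sexchr <- c("X", "Y", "chrX", "chrY")
  if (panel$chrom %in% sexchr && !config$include_sex_chromosomes) {
    message("skipping sex chromosome ", panel$chrom,
            " (set include_sex_chromosomes = TRUE to override)")
    return(list(scores = list(), summaries = list()))
  }
  windows <- place_accessible_windows(inputs$mask,
                                      size = config$window_sizes[1L])
  scores <- list(); summaries <- list()
  for (pop in inputs$pops) {
    sc <- ihs_scan(panel, pop = pop, maf_min = config$maf_scan)
    nm <- paste0("iHS_", pop)
    scores[[nm]] <- sc
    summaries[[nm]] <- summarize_window_scores(sc, windows)
  }
  pairs <- config$pop_pairs
  if (is.null(pairs) && length(inputs$pops) >= 2L)
    pairs <- utils::combn(inputs$pops, 2L, simplify = FALSE)
  for (pr in pairs) {
    pa <- subset_panel_pop(panel, pr[1L])
    pb <- subset_panel_pop(panel, pr[2L])
    sc <- xpehh_scan(pa, pb, maf_min = config$maf_scan)
    nm <- sprintf("XP_EHH_%s_%s", pr[1L], pr[2L])
    scores[[nm]] <- sc
    summaries[[nm]] <- summarize_window_scores(sc, windows)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(scores)) {
      utils::write.table(format(scores[[nm]], digits = 10, trim = TRUE),
                         file.path(config$out_dir, paste0(nm, "_sites.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s <- summaries[[nm]]
      if (nrow(s) == 0L) next
      stat <- if (grepl("^iHS", nm)) "iHS" else "XP_EHH"
      popnm <- sub("^(iHS_|XP_EHH_)", "", nm)
      write_track(window_stats_row(s$chrom, s$start, s$end, popnm, stat,
                                   s$mean_abs_score),
                  "bedGraph", file.path(config$out_dir, paste0(nm, ".bedGraph")))
    }
  }
  list(scores = scores, summaries = summaries)
}

#' Restrict a panel to one population's haplotypes
#'
#' Keeps the full site list; allele states, polarization and outgroup
#' annotation are untouched (population-specific segregation is recomputed
#' by the statistics).
#'
#' @param panel a [hap_panel].
#' @param pop population label.
#' @return A [hap_panel] holding only that population's samples.
#' @export
subset_panel_pop <- function(panel, pop) {
  keep <- which(panel$pops == pop)
  if (length(keep) == 0L) stop("population not present in panel: ", pop)
  out <- panel
  out$hap <- panel$hap[sort(c(2L * keep - 1L, 2L * keep)), , drop = FALSE]
  out$samples <- panel$samples[keep]
  out$pops <- panel$pops[keep]
  out
}
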