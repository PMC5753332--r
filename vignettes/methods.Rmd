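---
title: "Methods: statistics, windowing and design choices in popgenwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics, windowing and design choices in popgenwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenwin)
```

`popgenwin` computes window- and gene-based population genetics statistics
from phased variant panels. This vignette documents the statistical models,
the conventions and numerical choices behind each module, and what the
synthetic-data generator does and does not emulate.

## Input model and coordinates

All internal coordinates are 0-based, half-open, matching BED/bedGraph, the
dominant interchange formats here; VCF and GFF3 (1-based) are converted at
the read boundary and back at the write boundary. The polymorphism
container is a phased biallelic haplotype matrix: multi-allelic records,
indels and structural variants are dropped at VCF read time, and unphased
genotypes are a hard error because every haplotype-based statistic (EHH,
iHS, XP-EHH, haplotype diversity, LD) is defined on phased chromosomes.
Sample exclusion (e.g. reportedly inbred individuals) is a generic
`exclude_samples` list rather than a baked-in cohort-specific roster: the
filter is part of the method, the roster is data.

Ancestral states are resolved in two tiers: the VCF `AA` annotation when
present, else the aligned outgroup base at the site (only when it matches
one of the two sample alleles). Sites with neither remain usable by folded
statistics only (Tajima's D, π, θ_W, LD) and are excluded from the unfolded
tests. Sites where the outgroup matches *neither* allele ("three-state"
sites) violate the biallelic infinite-sites treatment and are excluded from
both polymorphism polarization and divergence counts.

The outgroup track is built from a two-sequence alignment: columns with a
reference gap consume no reference coordinate, columns with an outgroup gap
or `N` are unaligned, and soft-masked lowercase bases are valid calls —
masking is the accessibility mask's job, not the alignment's.

## Windowing under the accessibility mask

Two schemes are used, mirroring the two standard trade-offs:

* **Fully accessible 10 kb windows**: each accessible mask interval is
  tiled from its own start; remainders shorter than the window are
  discarded and no window ever spans two intervals, so no window overlaps a
  single non-accessible base. Anchoring at each interval's start (rather
  than at global multiples of 10 kb) is the only tiling consistent with
  both non-overlap and full accessibility while maximizing placed windows.
* **Fixed 100 kb windows**: tiled from coordinate 0 along the whole
  chromosome; the last partial window is retained with its true extent
  (discarding it would silently drop chromosome ends). Each window records
  its mask-accessible base count, which is the per-site denominator
  everywhere downstream — masked-out positions never inflate a denominator,
  and a fully masked window reports every statistic as missing.

Per-window recombination rates are (cM at end − cM at start)/Mb with cM
linearly interpolated between map points; positions outside the map clamp
to the terminal values, so windows beyond the map get rate 0.

## Frequency-based statistics and neutrality tests

For a window with n haplotypes, L accessible bases and derived-allele
counts i at segregating sites:

* π(total) = Σ 2i(n−i)/(n(n−1)); θ_W = S/a₁ with a₁ = Σ_{k<n} 1/k;
  θ_L = Σ i ξ_i/(n−1); θ_H = Σ 2i²ξ_i/(n(n−1)). The identity
  π + θ_H = 2θ_L holds on any polarized spectrum and is asserted in the
  tests.
* Tajima's D uses all segregating sites (folded information suffices);
  Fu & Li's D and F (outgroup versions, contrasting derived singletons ξ₁
  with S and with π), Fay & Wu's H and Zeng's E use polarized sites only.
* Variance constants are functions of n alone, transcribed from the tests'
  original formulations (including the corrected u_F term). H defaults to
  the unnormalized θ_π − θ_H form, matching the common windowed usage; a
  `normalized` flag switches to the variance-standardized version.
* Undefined statistics (S = 0, zero variance, empty window) propagate as
  missing values, never as 0 — a window with no data is not a window with
  no signal.

Statistics are computed per population with no pooling; segregation is
re-evaluated after subsetting, so a site fixed within a population does not
count as segregating there.

## Linkage disequilibrium

r² is computed on phased haplotypes by gamete counting
(D = f₁₁ − p₁p₂, r² = D²/(p₁q₁p₂q₂); equal to the squared Pearson
correlation of the two binary columns, which is how the matrix form is
evaluated). Kelly's ZnS averages all C(S,2) pairs; Rozas' ZA the S−1
adjacent pairs (genomic order, never across window boundaries);
ZZ = ZA − ZnS. Wall's B counts adjacent pairs whose two columns show only
two distinct two-site haplotypes (same or complementary bipartition);
Q = (B′ + A)/S adds the number of distinct bipartitions among congruent
pairs, following the original definition. Note that congruence is stricter
than mere compatibility with one genealogy: nested mutations on one tree
produce three two-site haplotypes and are not congruent.

## Haplotype scans

EHH of a core allele at distance x is the probability that two random
carrier haplotypes are identical over [core, x]; it starts at 1 and is
non-increasing. iHH integrates EHH trapezoidally over physical distance on
both sides until EHH falls below the cutoff (default 0.05, the cited scan
software's convention); the crossing segment is included. Integration over
cM is available when a genetic map is supplied, but physical distance is
the reproducible default. Two QC rules flag a core site as `truncated`:
a gap above 20 kb between consecutive informative SNPs, and a curve that
reaches the chromosome or window edge still above the cutoff. Truncated
and skipped sites are excluded from standardization but retained in the
output with their flag, favouring auditability over silent loss.

iHS = ln(iHH_ancestral/iHH_derived), standardized to zero mean and unit
variance within derived-allele-frequency bins (width 0.02; bins with fewer
than 20 scores are merged with their smaller neighbor — small fixed bins
with a merge rule are stable at small scale). Standardization is pooled
across the whole input, stated in the output rather than assumed. XP-EHH
integrates each population's EHH until the *combined*-population EHH drops
below the cutoff and scores ln(iHH_A/iHH_B), standardized in a single bin.
SNPs are filtered at MAF > 0.05 before scanning, and sex chromosomes are
skipped by default (an override flag exists). Window summaries report the
mean of |standardized score| over the passed SNPs each window contains.

## Gene-based MKT

Site classes are mutually exclusive per transcript: 4-fold and 0-fold
degenerate CDS positions (degeneracy evaluated on the coding strand against
the standard genetic code; 2- and 3-fold positions fall into `other` and
are excluded from MKT), 5′/3′ UTRs (exon minus CDS, oriented by strand),
introns, and ±500 bp intergenic flanks with positions inside another
transcript excluded. Genes with CDS length not divisible by 3 or with an
internal stop are retained for non-coding classes but withhold coding
classes. Multi-transcript genes collapse to the longest codable transcript
— deterministic and common practice where the choice is otherwise
unconstrained.

Counting: m_c is the number of accessible, outgroup-aligned positions of
class c; P_c the population-specific segregating sites, partitioned at
MAF < 0.05; D_c the fixed differences against the outgroup (a polymorphic
site is never also divergent; three-state sites are excluded); π_c and K_c
(Jukes–Cantor, −¾ ln(1 − 4p/3), undefined past saturation p ≥ ¾) are
per-site over m_c.

Standard MKT: NI = (P_t/P_s)/(D_t/D_s), α = 1 − NI, plus the π/K-based
α = 1 − (π_t/π_s)(K_s/K_t) and DoS = D_t/(D_t+D_s) − P_t/(P_t+P_s). Any
zero denominator yields a missing value, never ±∞.

Integrative MKT: the neutral class's low/high MAF split calibrates the
low-frequency polymorphism expected without selection,
P_t(neutral) = P_t(high)·P_s/P_s(high), and the weakly deleterious excess
P_t(wd) = P_t(low) − P_t(high)·P_s(low)/P_s(high), floored at 0 (sampling
noise can drive it negative; flooring is flagged). Then
f = (m_s/m_t)·P_t(neutral)/P_s, b = (m_s/m_t)·P_t(wd)/P_s, d = 1 − f − b,
and α_cor = 1 − (P_t(neutral)/P_s)·(D_s/D_t). The split of f into an
anciently neutral part (f − γ) and a recently neutral γ needs a
divergence-based neutral fraction; using α_cor there would make γ vanish
algebraically, so the π/K-based α is used: f_old = (m_s/m_t)·(1 −
α_{π/K})·D_t/D_s and γ = max(0, f − f_old). This operationalization of γ is
a reconstruction from the framework the correction derives from, not a
uniquely determined formula, and is the module's most consequential
interpretation; it is isolated in one place (`integrative_mkt`) and the
remaining quantities do not depend on it. Fractions are clamped to [0, 1]
with a truthful `clamped` flag; d + b + f = 1 exactly when no clamping
occurred.

## The synthetic-data generator

`simulate_panel` emulates the full input ensemble at toy scale:
an accessibility mask with exponential accessible/inaccessible run lengths,
segregating sites placed uniformly on accessible positions with derived
counts drawn from the neutral expectation P(i) ∝ 1/i (independent sites),
S ~ Poisson(θ·a₁·L) so Watterson's estimator is centered on θ, an outgroup
sequence mutated at a fixed per-site rate, two-exon gene models whose CDS
is overwritten with stop-free sense codons so degeneracy classes exist, and
a linear genetic map. Everything is deterministic under the spec's
mandatory seed, and every emitted file re-reads through the package's own
readers (a tested round-trip).

What it does **not** emulate: linkage (sites are independent, so LD- and
EHH-dependent behaviour is validated with explicitly constructed haplotype
patterns, `inject_sweep`, and hand-built cases rather than with the neutral
sampler), demography, recombination graphs, sequencing error and missing
genotypes. Passing calibration on these fixtures therefore validates the
estimators' arithmetic and their neutral centering — under the
independent-sites model every test numerator has conditional expectation 0
given S, so the neutral means are exactly 0 in expectation — but says
nothing about robustness to demographic confounding on real cohorts.

`inject_sweep` homogenizes a chosen fraction of haplotypes over a region
around a core derived allele (the hard-sweep footprint iHS detects);
`inject_deleterious_class` adds singleton sites to a target class, with the
count chosen as round(b·P_s·m_t/m_s) so the integrative MKT's expected
recovered b equals the requested fraction.

## Problem sizes and tolerances

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in minutes on one CPU while keeping Monte-Carlo error
well inside the asserted bands: 200 random panels (n ≤ 8, ≤ 20 sites) for
exact oracle equivalence at 1e-12; 500 neutral replicates (n = 20,
θ = 0.001, 10 kb) for the SFS-test centering (asserted within 3 standard
errors of 0); ~1800 pooled scores for the iHS tail fraction (|z| > 2 ≈
0.046, asserted ±0.02); 100 replicates each for deleterious-fraction
recovery (b = 0.3 ± 0.05 on the mean) and sweep sign recovery (≥ 95%
negative at the core). The genome-scale 10 kb window inventory against the
published pilot-mask counts requires the external mask file and is reported
as unavailable when the file is absent.

Numerical conventions worth noting: bedGraph values are written with
`%.17g` so a write/read round-trip is bit-exact (the determinism guarantee
is byte-level); missing values are omitted from bedGraph, written as `.` in
TSV; EHH integration at cutoff 1.0 is exactly 0 (no segment starts above
the cutoff); and merged standardization bins inherit the pooled mean/sd of
their member scores.
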