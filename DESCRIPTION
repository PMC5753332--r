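Package: popgenwin
Title: Window- and Gene-Based Population Genomics Statistics from Phased Variant Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A statistics engine for population genomics surveys of phased
    variant panels. From a phased VCF, an accessibility mask (BED), gene
    models (GFF3), a pairwise reference-vs-outgroup alignment (multi-FASTA)
    and sex-specific genetic maps, it computes windowed nucleotide diversity,
    divergence, linkage disequilibrium summaries (Kelly's ZnS, Rozas' ZA/ZZ,
    Wall's B and Q), site-frequency-spectrum neutrality tests (Tajima's D,
    Fu and Li's D and F, Fay and Wu's H, Zeng's E), haplotype-based selection
    scans (EHH, iHS, XP-EHH) with per-window mean absolute score summaries,
    and gene-based standard and integrative McDonald-Kreitman tests with a
    minor-allele-frequency correction for slightly deleterious polymorphism.
    Windows are placed under the accessibility mask either as fully accessible
    10 kb tiles or as fixed 100 kb tiles with per-site masking, and results
    export as bedGraph, GFF3 or TSV browser tracks. A seeded synthetic-data
    generator emulates all input formats at toy scale for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
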