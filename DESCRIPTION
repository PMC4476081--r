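Package: fstscan
Title: Selection-Signature Scans from Two-Population SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of divergent selection between two populations
    genotyped on a medium-density SNP array. Computes per-SNP fixation indices
    (Fst) from pooled allele frequencies, smooths them chromosome-by-chromosome
    with a locally weighted (LOWESS) regression whose span corresponds to a
    fixed SNP window, and flags outlier and borderline peaks with a 3-SD
    control chart. A complementary regional linkage-disequilibrium scan
    compares windowed genotype-correlation spectra between the populations
    (varLD-style eigenvalue statistic). Includes PLINK PED/MAP and VCF input,
    the standard data-editing pipeline (autosome restriction, monomorphic,
    missingness and MAF filters, modal-allele imputation), gene-overlap
    annotation of significant regions from a local GFF3/BED file, and a
    seedable two-population genotype simulator with planted selective sweeps
    and LD-divergent regions for power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
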