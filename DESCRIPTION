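Package: strandfold
Title: Strand-Resolved Chromatin Replication Analytics
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for quantifying replication-coupled chromatin
    assembly experiments. Implements the strand-partition computation used in
    sister-chromatid-after-replication (SCAR) sequencing (binning, CPM
    normalization, uniform smoothing, input correction, coverage filtering,
    partition and replication-fork-directionality scores, initiation-zone
    meta-profiles, spike-in normalization), a self-contained read pipeline for
    plasmid-based nucleosome assembly and quantitation (NAQ) MNase-seq
    libraries (dual-index demultiplexing, adapter trimming, unique-best
    mapping to small circular references, nucleosomal fragment-length
    selection, percent-nicked and loading-control-normalized coverage),
    gel-densitometry utilities (minimum-profile background subtraction,
    log-Rf molecular-weight ladder calibration, band-front detection, maximum
    replication-rate regression, EMSA percent-bound, full-length product
    fractions), equilibrium binding-curve fitting (one-site with Hill slope,
    fluorescence polarization), and mass-photometry calibration, Gaussian
    mixture peak fitting and stoichiometry assignment. A synthetic-data
    generator with known ground truth accompanies every stage so the whole
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    minpack.lm,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
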