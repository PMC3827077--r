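Package: scnaclone
Title: Somatic Copy-Number Aberration Calling with Tumor Purity and
    Subclonality Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies, characterizes and quantifies somatic copy-number
    aberrations (SCNAs) from paired tumor-normal sequencing data.  Taking
    per-SNP read depths and lesser-allele frequencies (LAF) as input, the
    pipeline smooths the LAF signal, detects candidate change points by
    circular binary segmentation with pseudo-point padding, prunes them by
    stepwise selection with BIC on a cumulative piecewise-constant
    regression, estimates per-segment somatic ratios by a Geary-Hinkley
    transformed maximum likelihood estimator, assigns integer copy states
    and estimates the normal-cell admixture rate with a Bayesian finite
    mixture sampled by Markov chain Monte Carlo, and tests each aberrant
    segment for consistency with a clonal one-copy change to quantify the
    fraction of tumor cells carrying it.  A built-in cancer-genome
    simulator generates paired read-depth/LAF data with known ground truth
    for power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
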