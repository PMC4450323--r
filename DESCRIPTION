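Package: ProgressionKit
Title: Longitudinal Genetic and Epigenetic Analysis of Leukemia Progression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of paired pre-treatment tumor samples from chronic
    lymphocytic leukemia (CLL) patients followed from diagnosis to
    treatment. Calls somatic variants from germline/tumor/tumor allele
    counts with a permutation chi-square test, tests per-variant allele
    frequency drift between time points with Fisher's exact test under
    Benjamini-Hochberg FDR control, classifies each leukemia as evolving,
    expanding or static, and groups somatic copy-number segments into
    per-patient alteration units. For methylation arrays it estimates
    five-cell-type composition by constrained least squares deconvolution,
    adjusts beta values by linear regression, discovers
    progression-associated CpGs with paired Wilcoxon signed-rank tests,
    and annotates them via 200 bp window overlap with ChIP-seq peaks
    (hypergeometric enrichment), probe-bias-corrected gene-set resampling
    tests, and naive/memory B-cell concordance analyses. A synthetic
    cohort generator with full ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, SomaticMutation, CopyNumberVariation,
    Software
RoxygenNote: 7.3.3
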