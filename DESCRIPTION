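Package: steatoreg
Title: Integrative Regulatory and Methylation Analysis of Hepatocyte Epigenomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrating open-chromatin, transcriptome and DNA
    methylation data from a two-condition hepatocyte study design. Implements
    biophysical (TRAP-style) transcription-factor binding-affinity scoring over
    differential open-chromatin peaks, aggregation into per-condition TF-gene
    scores, regularized logistic regression to predict transcriptional
    regulators of differentially expressed gene clusters, a cluster-wise TF
    effect score, and a DNA-methylation arm covering chromatogram-based
    methylation indices, differential-methylation filtering of bisulfite count
    data, and aging-versus-diet concordance classification. A synthetic-data
    module generates all inputs with the statistical structure the analysis
    assumes, so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
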