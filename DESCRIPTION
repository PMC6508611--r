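Package: TxProfiler
Title: Transcriptome-Based Scoring of Drug Efficacy and Inter-Treatment
    Similarity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how well pharmacological treatments restore
    diseased transcriptomes toward the healthy state. Implements
    dual-baseline differential expression (one-way ANOVA with Dunnett
    many-to-one comparisons against both a healthy and a disease
    control), a restored/not-restored/altered gene trichotomy per
    treatment, mean-absolute-log2FC profile distances, two-dimensional
    per-pathway treatment coordinates with log10 efficiency scores,
    Ward/silhouette clustering of differential-expression profiles,
    hypergeometric gene-set over-representation, exclusive (UpSet-style)
    multi-set intersections, and repeated random-forest classification of
    samples at gene and pathway level. A synthetic-study generator with
    planted ground truth supports end-to-end validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, mvtnorm, cluster,
    randomForest, yaml, jsonlite
Suggests: testthat (>= 3.0.0), multcomp, optparse
biocViews: Transcriptomics, DifferentialExpression, Classification,
    GeneSetEnrichment, Clustering, Pharmacogenomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
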