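Package: methpred
Title: Context-Specific Prediction of Plant Cytosine Methylation from
    Sequence, Annotations and Neighboring Methylation Levels
Version: 0.1.0
Authors@R:
    person("Open", "Methylomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the binary methylation status of cytosines
    in the CG, CHG and CHH sequence contexts of plant genomes. Implements a
    convolutional neural network that classifies a cytosine from the one-hot
    encoded DNA window around it, optionally augmented with per-base gene and
    repeat annotation channels; a multilayer perceptron that classifies a
    cytosine from the methylation levels of its nearest covered neighbors; a
    combined network using both input modalities; and a bagged-tree baseline.
    Includes parsers for Bismark-style cytosine reports, GFF3/BED/RepeatMasker
    annotations, balanced training-set construction with an 80/10/10 split,
    gene-body methylation metaprofiles, cross-context and cross-species
    evaluation grids, Grad-CAM importance scoring with motif-candidate FASTA
    export, and a fully reproducible synthetic methylome simulator used by the
    test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    withr,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
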