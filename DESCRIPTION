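Package: polyacode
Title: Sequence-Based Modeling of 3' Cleavage and Alternative Polyadenylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for modeling 3'-end cleavage and
    polyadenylation from DNA sequence. Implements a dilated residual
    convolutional network that maps a 205-nt polyadenylation signal to a
    base-resolution 206-way cleavage distribution, together with the
    downstream machinery commonly layered on such a model: variant effect
    scoring by isoform log odds ratios, pairwise and masked-softmax multi-PAS
    isoform regression, condition-specific residual models, mask-based
    (Gumbel-relaxed) variant interpretation, population-scale saturation
    screening of PAS catalogs, and quantification of 3'-end MPRA reads with
    UMI collapsing. A synthetic-data module generates every input the
    toolkit consumes under a known ground-truth cleavage law, so each
    component can be trained and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
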