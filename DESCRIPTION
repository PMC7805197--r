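Package: dpgsea
Title: Drug-Perturbation Gene Set Enrichment Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Directional, significance-ranked enrichment of a disease
    differential-expression profile against drug-derived gene signatures
    ("proto-matrices"). For each drug the package computes a weighted
    running-sum enrichment score (ES), a target compatibility score (TCS)
    locating where in the ranked list enrichment peaks, permutation-normalized
    scores (NES, NTCS), empirical p-values, GSEA-style pooled-null false
    discovery rates, and leading-edge driver genes. Includes a proto-matrix
    builder for per-drug differential-expression tables, a synthetic screen
    generator for power and error-rate studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
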