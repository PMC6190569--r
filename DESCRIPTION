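Package: rvpedsim
Title: Simulate Pedigrees Ascertained for Multiple Disease-Affected Relatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pedigrees ascertained on the basis of multiple
    disease-affected relatives, as in family-based studies of rare disease
    variants. Life events (disease onset, death, reproduction) are modelled as
    competing non-homogeneous Poisson processes conditioned on age, disease
    status and rare-variant carrier status; a causal variant is introduced by
    at most one founder and transmitted by Mendel's laws. Ascertainment is
    modelled explicitly: proband selection within an ascertainment span,
    recall-based trimming of relatives with connector retention, and a
    discard-and-retry loop. The package also provides the pedigree statistics
    used to analyse such samples: recursive kinship coefficients, mean
    pairwise identity-by-descent among affecteds, generation assignment for
    apparent-anticipation analysis, per-family summary tables, and the
    proportion of ascertained families segregating a causal variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
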