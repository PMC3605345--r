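Package: chromoscan
Title: Structural Discovery and Classification of Chromoviral LTR Retrotransposons
Version: 0.1.0
Authors@R: person("chromoscan", "developers", role = c("aut", "cre"),
    email = "chromoscan@example.org")
Description: Structure-based detection of full-length chromoviral
    (Ty3-gypsy) LTR retrotransposons in genomic contigs: de novo LTR-pair
    discovery with target-site-duplication validation, annotation of primer
    binding sites, polypurine tracts, gag-pol open reading frames and
    protein domain cassettes, chromodomain group and clade classification
    (CRM, Tekay, Reina, Galadriel), family clustering by LTR identity,
    neighbor-joining dendrograms with bootstrap supports, and insertion-age
    estimation from LTR divergence via the molecular clock t = K/(2r).
    Includes a synthetic-genome generator with full ground truth for
    validating every stage, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
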