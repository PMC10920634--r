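Package: paleocacao
Title: Archaeogenomic Detection and Ancestry Assignment of Cacao Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting Theobroma cacao and Herrania ancient DNA in
    ceramic-residue sequencing libraries and assigning its ancestry to modern
    reference genetic groups. Implements a synthetic damaged-aDNA generator
    (terminal cytosine deamination, depurination-biased fragmentation,
    admixed genotypes drawn from group allele frequencies), a read-processing
    chain (adapter/quality trimming, pair merging, exact deduplication,
    windowed entropy filtering), best-hit taxonomic assignment with a
    distinct-sequence presence threshold, post-mortem damage authentication
    profiles, damage-aware SNP allele extraction, supervised admixture
    estimation by EM, Nei (1978) genetic distances, neighbor-joining trees
    with locus bootstrap, and methylxanthine positivity calling with
    aDNA/chemistry concordance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
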