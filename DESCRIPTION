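Package: indelatlas
Title: Extraction and Phylogenetic Classification of Protein Indels
    from Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consensus-guided extraction of insertion/deletion (indel)
    regions from gapped protein multiple sequence alignments,
    classification of indel regions as simple (binary presence/absence)
    or complex (multi-state), phylogenetic typing of simple indels as
    singleton, clade-defining, homoplastic or ambiguous against a rooted
    reference phylogeny, polarization of singleton indels into
    insertions and deletions, and estimation of insertion:deletion
    ratios.  Also provides an ortholog-cluster screening stage (BLAST
    hit-table filtering, fragment removal, in-paralog pruning, taxon
    coverage categories), a simulator that plants indel events on the
    branches of a phylogeny with a ground-truth event log, and a
    pipeline driver that runs screening, extraction and phylogenetic
    interpretation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
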