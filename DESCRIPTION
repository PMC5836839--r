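Package: miRfootprint
Title: Structural Footprints of miRNA Biogenesis in pre-miRNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how microRNA maturation is imprinted in the secondary
    structure of pre-miRNA hairpins: signed duplex overhang lengths at the
    basal (Drosha or splice-site) and apical (Dicer) processing sites, their
    joint distribution and a two-parameter independence null model for
    cleavage-site coherence, signed distances from miRNA ends to the nearest
    single-stranded region (the loop-counting rule), positional
    unpaired-nucleotide-frequency profiles and their correlation with
    substitution rates, region-wise SNP densities, and branchpoint
    localisation within mirtron hairpins. A synthetic hairpin generator with
    designed overhangs, SNP rates and branchpoint offsets makes every stage
    verifiable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
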