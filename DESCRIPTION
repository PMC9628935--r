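Package: markerMLST
Title: Housekeeping-Gene Marker Discovery and Species-Specific PCR for
    Bacillus Strain Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting housekeeping-gene markers that discriminate
    Bacillus subtilis from closely related species. Computes per-locus
    multilocus sequence typing (MLST) statistics (allele counts, polymorphic
    sites, typing efficiency, Hunter-Gaston discriminatory power, and
    Nei-Gojobori dN/dS with Jukes-Cantor correction), percent-identity and
    neighbor-joining analyses over single loci and concatenated MLST schemes,
    and species-specific primer design with in-silico PCR specificity
    screening. Includes a codon-aware multi-species strain-panel simulator
    with planted species-diagnostic primer windows, so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Phylogenetics,
    MultipleComparison, Software
RoxygenNote: 7.3.3
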