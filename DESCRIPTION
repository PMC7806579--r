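Package: adductgraph
Title: Graph-Based Adduct Annotation of High-Resolution ESI-MS1 Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of centroided positive-mode high-resolution
    electrospray MS1 spectra. Peaks are linked by known and combined
    adduct, neutral-loss and multimer mass differences into a weighted
    directed graph, related peaks are clustered, and protonated-molecule
    ([M+H]+) candidates are ranked by explained total ion current with
    connectivity tie-breaking. Reports cluster global connectivity (CGC),
    cluster intensity coverage (CIC) and cluster count coverage (CCC)
    confidence indexes. Includes exact monoisotopic mass arithmetic for
    elemental formulas and singly charged ion species, Mascot generic
    format (mgf) reading and writing, pseudo-spectrum conversion of
    chromatographic feature tables, spectrum filters (thresholding,
    deisotoping, monoisotopic validation) and a seeded ground-truthed
    synthetic-spectrum generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
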