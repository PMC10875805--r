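Package: kinamotif
Title: Kinase Substrate Preference Motifs and Phosphosite Kinase Ranking
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds position-specific probability and Shannon-information
    matrices for protein kinases from curated phosphosite data, derives
    chi-square-filtered sequence logos and anti-logos of favored and
    disfavored residues, and ranks kinases for any centralized 13-mer
    phosphopeptide by the dot product of a Boolean query encoding with each
    kinase's information-content matrix. Includes a synthetic peptide-set
    generator (basophilic, proline-directed, acidophilic and tyrosine-kinase
    presets) for end-to-end benchmarking, a JSON profile store, CSV export
    of ranked predictions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
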