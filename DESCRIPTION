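Package: molnetr
Title: Molecular Networking and Discovery-Potential Statistics for Untargeted LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical molecular networking for untargeted tandem mass
    spectrometry of microbial extracts: MGF input/output, GNPS-style
    spectral preprocessing (precursor-window removal, windowed top-k peak
    filtering, blank-derived exclusion lists), a modified-cosine similarity
    kernel with exact maximum-weight peak matching, consensus clustering of
    near-identical MS/MS scans, network construction with mutual top-K edge
    filtering and molecular-family size capping, exact and analog spectral
    library annotation with fragment-level mass-shift localization, and
    discovery-potential statistics (rarefaction/accumulation curves over
    strains, media-overlap counts, annotation rates, pathway-by-media
    matrices). Includes a seeded synthetic-study generator emulating a
    strains-by-media culture design with ground-truth molecules, structural
    families, ion-form redundancy and media background, so the whole
    pipeline is testable end-to-end without raw data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
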