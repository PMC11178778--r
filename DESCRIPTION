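Package: tkfusions
Title: Selection of Oncogenic Tyrosine-Kinase Fusions from Genome-Wide Translocation Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for studying how oncogenic tyrosine-kinase
    fusions are selected from pools of random chromosomal rearrangements.
    Implements junction calling from high-throughput genome-wide
    translocation sequencing (HTGTS) alignment tables with the standard
    filter cascade (primer anchoring, alignment validity, PCR de-duplication,
    ligation-artifact removal), breakpoint hotspot detection by island
    clustering against a Poisson background with local-enrichment refinement
    and Bonferroni correction, an entropy-based strand-bias score,
    productive-fusion annotation from orientation, exon phase, partner
    transcription and protein stability, and COSMIC-style fusion-landscape
    summaries (partner frequency, partner sharing, exon usage). Includes a
    synthetic-data generator producing toy genomes, pre- and post-selection
    junction libraries with planted hotspots and artifacts, and fusion
    tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
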