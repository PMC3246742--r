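Package: genoglyph
Title: Whole-Genome Linear Ideogram Rendering from GFF3
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders features on all chromosomes of a genome at once as a
    raster ideogram. Reads GFF3 describing backbones (chromosomes, linkage
    groups, pseudomolecules) and features in any linear unit system (base
    pairs, centimorgans, cytological units), lays them out as parallel
    vertical bars under a shared unit-to-pixel scale, and draws centromere
    overlays, position dots, range bars, border bands, marker ticks and
    feature-density histograms. Output is a genome PNG, a legend PNG and a
    tab-separated pixel-coordinate file suitable for building HTML image
    maps. Includes converters that lift tabular BLAST hits onto genomic
    coordinates via a peptide location GFF and collapse adjacent HSPs with
    a gap-threshold sliding window, plus a seeded synthetic-genome
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    png,
    stats,
    utils
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
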