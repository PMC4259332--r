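Package: oritrack
Title: Replication Profiling of Origin-Depleted Yeast Chromosomes on Synthetic Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models deletion editing of budding yeast replication origins and
    the tiling-array experiments used to characterize an origin-depleted
    chromosome. Generates probe-level Orc2 ChIP and BrdU-IP log2-ratio tracks
    from an explicit origin-firing and hydroxyurea-constrained fork-progression
    model, conditions tracks with Tukey biweight centring and a Hodges-Lehmann
    pseudomedian sliding window, normalizes BrdU tracks against known
    unreplicated regions, forms wild-type minus mutant difference tracks, and
    calls and classifies initiation and binding peaks as canonical, residual
    (non-canonical, near a deleted origin), or novel. Includes a seeded
    end-to-end pipeline and a planted-truth recovery benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
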