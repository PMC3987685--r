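Package: clockmine
Title: Circadian Gene Cluster Discovery and Clock Transcription-Factor
    Set Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering circadian-regulated gene clusters
    in short replicated liver time courses and inferring their
    transcriptional regulators. Differentially expressed probesets are
    selected by one-way ANOVA with Storey positive-FDR q-values, grouped
    by consensus clustering with trivial-cluster removal, and tested for
    24 h rhythmicity with Fisher's exact g-test after replicate
    redistribution over consecutive cycles. Promoters are remodelled into
    ordered binding-site lists by information-weighted position weight
    matrix scanning, filtered by phylogenetic footprinting across
    orthologous promoters, and mined for clock transcription-factor
    combinations scored by hypergeometric enrichment against a GC-matched
    background. A ground-truthed synthetic-data generator emulates the
    full input bundle so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    withr,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
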