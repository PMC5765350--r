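Package: motifconcord
Title: Concordance of KRAB Zinc Finger Binding Motifs and Peaks Across ChIP Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to compare transcription-factor ChIP experiments for the
    same protein across datasets: AUROC-based motif evaluation of position
    weight matrices against dinucleotide-shuffled peak sequences, motif
    similarity by correlation of predicted affinities over a common random
    sequence background, summit-window peak overlap statistics, endogenous
    retroelement (ERE) class enrichment profiles with a matched-versus-
    unmatched correlation null, and a rule-based procedure that selects one
    reference motif per protein with confidence metrics. Includes a seeded
    synthetic-data generator (genome, ERE annotation, planted motifs, paired
    noisy peak sets) so the whole pipeline runs end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
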