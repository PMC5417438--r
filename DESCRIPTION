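Package: distotu
Title: Distribution-Based OTU Calling for Amplicon Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Groups dereplicated 16S rRNA amplicon sequences into
    operational taxonomic units (OTUs) using their distribution across
    samples in addition to sequence similarity. Candidate sequences are
    processed in order of decreasing abundance and merged into an
    existing OTU only if they pass an abundance criterion, a genetic
    criterion based on a length-normalised Levenshtein edit distance,
    and a distribution criterion based on a Poisson likelihood-ratio
    test of proportional counts across samples. Includes a Monte-Carlo
    simulated chi-squared test of independence (the legacy distribution
    criterion) with exact enumeration for small tables, evaluation
    utilities (confusion counts, sensitivity/specificity, F1,
    correlation with confidence intervals, threshold sweeps), and a
    synthetic mock-community generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
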