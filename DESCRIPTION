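Package: kmerprof
Title: Alignment-Free Quality Control and Comparison of Sequencing Data via k-mer Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds k-mer frequency profiles from DNA sequencing reads or
    reference sequences using a 2-bit base encoding with constant-time
    reverse complementation, transforms them (shrink, balance, shuffle,
    pairwise dynamic smoothing, scaling) to make libraries of different
    sizes comparable, and quantifies dissimilarity between datasets with a
    multiset distance and a strand-coverage balance statistic. Enables
    reference-free quality control and complexity assessment of NGS data,
    including simulated metagenome mixtures and composition-preserving
    permutation controls for choosing the word length k.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rhdf5,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
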