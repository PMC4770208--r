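Package: pbfilter
Title: Poisson Binomial Quality Filtering of Amplicon Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality filtering of high-throughput amplicon reads based on the
    exact Poisson binomial distribution of the per-read error count. Each
    read's Phred quality scores define independent per-base error
    probabilities; their sum follows a Poisson binomial distribution which is
    computed by iterated Bernoulli convolution, lazily, up to a
    confidence-bounded quantile j_xi (the read's predicted maximum number of
    errors). Reads whose predicted maximum errors exceed a tolerance derived
    from the trimmed read length are discarded. The package also provides the
    surrounding pipeline: paired-end contig assembly with consensus quality
    scores, fixed-length truncation, dereplication of identical sequences
    with least-error representatives (a taxonomic-bias remedy), FASTQ and
    FASTA+qual input/output, and a calibrated read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
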