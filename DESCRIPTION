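Package: apalong
Title: Alternative Polyadenylation Analysis from Long-Read 3' End Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies alternative polyadenylation (APA) from
    long-read 3' end positions. Provides internal-priming artifact filtering
    based on genomic A-content, iterative 24-nt clustering of cleavage sites
    into polyadenylation site clusters (PACs) with weighted density-peak
    sub-cluster refinement, genomic-region annotation and known/novel matching
    against a reference poly(A) site table, percentage-of-site-usage (PSU)
    statistics with Wald tests for differential usage (DPUI), relative
    end-offset (RED) calls of 3' UTR lengthening and shortening, four-pattern
    classification of 3' UTR dynamics across a three-stage design, and
    poly(A)-signal sequence-context quality control. A fully deterministic
    synthetic-data generator with ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
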