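Package: hifrep
Title: De Novo Repeat Identification from Short Reads by Assembly of
    High-Frequency Reads
Version: 1.0.0
Authors@R:
    person("Morgan", "Reyes", email = "morgan.reyes@example.org",
           role = c("aut", "cre"))
Description: Builds a de novo repeat library from next-generation sequencing
    short reads without a reference genome. The k-mer frequency spectrum of
    the reads is used to locate the main coverage peak and estimate average
    read coverage; k-mers above a coverage-scaled threshold form a
    high-frequency set; whole reads whose terminal k-mers and at least a
    fixed fraction of all k-mers belong to that set are retained as
    high-frequency reads and assembled (built-in unitig de Bruijn assembler,
    or a pluggable external assembler) into repeat contigs, which are then
    filtered by coverage and length. Includes a synthetic planted-repeat
    genome and read simulator with ground-truth labels, evaluation
    statistics (N50/N90, read-level recall, base-level repeat recovery) and
    a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
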