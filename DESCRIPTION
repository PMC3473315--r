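Package: selenoscan
Title: Selenoprotein Gene Discovery by In-Frame TGA Exon Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies selenoprotein genes in genome assemblies by building
    open reading frames that read through in-frame TGA (selenocysteine)
    codons. Candidate exons bounded by start/stop/splice signals are scored
    with position weight matrices plus a three-periodic Markov
    coding/non-coding log-likelihood ratio, and for every exon carrying an
    in-frame TGA the maximal-coding-potential gene model through that exon
    is assembled by dynamic programming over splice-compatible exon chains.
    Candidates are confirmed by Sec/Cys homology pairing against a protein
    database, SECIS stem-loop detection in the 3' flank, and optional EST
    read-through support, then summarised into family count tables and
    tandem gene clusters. A synthetic-genome generator with planted
    selenoprotein genes, homolog databases, ESTs and ground truth supports
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
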