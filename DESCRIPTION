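Package: drugsimnet
Title: Disease-Contextual Drug Functional Similarity Networks for Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a disease-contextual weighted drug-drug functional
    similarity network from drug target sets, functional gene sets (such as
    GO Molecular Function terms), and a case/control expression dataset, then
    prioritizes candidate drugs by random-walk-with-restart eigenvector
    centrality with a gene-level bootstrap null and Benjamini-Hochberg FDR
    control. Includes readers for the standard input formats, a synthetic
    benchmark generator with a planted disease signal, and an evaluation
    toolkit (AUROC, top-k overlap, rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, pROC, fgsea, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
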