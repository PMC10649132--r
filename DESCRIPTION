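Package: lncpipe
Title: Long Non-Coding RNA Discovery, Differential Expression and Target
    Inference from Assembled Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying long non-coding RNAs
    (lncRNAs) among assembled transcripts, calling differentially
    expressed genes and lncRNAs between two treatment groups with a
    negative-binomial Wald test, and inferring cis- and trans-regulated
    target genes by expression correlation. Transcripts are compared
    against a reference annotation with gffcompare-style class codes,
    passed through structural and coding-potential filters (longest-ORF
    scan, Fickett TESTCODE and hexamer usage features feeding a
    cross-validated random-forest classifier), and triaged by homology.
    A synthetic-data module generates genomes, annotations, transcript
    sequences and negative-binomial count matrices with planted ground
    truth so the whole cascade is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    S4Vectors,
    data.table,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
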