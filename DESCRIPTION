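Package: lncsieve
Title: Coding-Potential Classification of Long Non-Coding RNA Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Distinguishes long non-coding RNA (lncRNA) transcripts from
    protein-coding transcripts using a hybrid 89-dimensional feature vector:
    a discrete-Fourier-transform period-3 signal-to-noise ratio, longest open
    reading frame features, k-mer composition (k = 1..3), transcript length
    and GC content. Features are ranked by a Golub-style feature score
    criterion, representative training samples are chosen per class with a
    self-organizing map and ceiling-proportional allocation, and a 300-tree
    random forest with a short-ORF shortcut rule produces a per-transcript
    non-coding score. Includes a synthetic transcript generator, evaluation
    metrics (Sn, Sp, ACC, MCC, AUC), permutation feature importance, and an
    end-to-end train/predict/evaluate pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
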