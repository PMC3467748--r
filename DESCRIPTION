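Package: pudi
Title: Positive-Unlabeled Learning for Disease Gene Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies disease genes from a set of confirmed disease genes
    (positives) and a large set of unknown genes (unlabeled) without assuming
    the unknowns are negatives. Genes are characterized by protein-domain
    membership, Gene Ontology semantic similarity (Wang S-value method over
    is_a/part_of DAGs), and protein-protein interaction network topology;
    discriminative features are selected by an affinity-frequency score; the
    unlabeled set is partitioned into reliable-negative, likely-positive,
    likely-negative and weak-negative subsets via centroid-distance filtering
    and random-walk label propagation on a top-Q gene similarity network; a
    multi-level weighted soft-margin SVM with per-subset misclassification
    penalties is then trained to classify unknown genes. Includes a synthetic
    study generator with planted positives and a contaminated unlabeled set,
    plus a cross-validation evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    kernlab,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
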