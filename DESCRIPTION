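Package: sacon
Title: Residue Solvent Accessibility and Contact Number Prediction with
    Stacked Sparse Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue structural labels for proteins --
    fifteen-state contact (coordination) number from C-beta/C-alpha
    coordinates and three-state relative solvent accessibility from DSSP
    accessible surface areas -- and predicts both label tracks from
    sequence-derived features alone.  Features combine evolutionary
    profiles (PSI-BLAST PSSM and HHblits HMM emissions, logistic-scaled),
    predicted structural tracks (secondary structure, disorder, backbone
    angles) and position-independent amino-acid properties into windowed
    per-residue vectors.  The classifier is a stacked sparse autoencoder:
    sigmoid layers greedily pretrained by stochastic gradient descent
    under a Kullback-Leibler sparsity penalty with dropout, then
    fine-tuned end-to-end with a softmax head by limited-memory BFGS.
    Includes readers for the standard input formats, evaluation metrics
    (Q3/Q15, per-class precision/recall/F1, Pearson correlation, MAE,
    within-k contact accuracy), synthetic fixture generators for fully
    offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
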