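Package: voicersa
Title: Time-Resolved Representational Similarity Analysis of Voice EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for time-resolved representational
    similarity analysis (RSA) linking EEG responses to voices with
    subjective ratings of person characteristics. Builds neural
    representational dissimilarity matrices (RDMs) by cross-validated
    pairwise linear-SVM decoding with multivariate noise normalization,
    behavioral RDMs from mean-rating distances, acoustic RDMs from
    long-term average spectra and a PCA of perceptually salient acoustic
    measures, relates them through nested partial Spearman rank
    correlation models, and performs permutation-based cluster-size
    inference at the group level. Includes a synthetic-data generator
    that embeds a known representational geometry into simulated EEG,
    ratings and acoustics so that the full pipeline is testable end to
    end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
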