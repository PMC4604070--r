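Package: toxdup
Title: Detection of Toxin Gene Duplications from Homology and Proteome Evidence
Version: 0.1.0
Authors@R: person("Toxdup", "Maintainers", email = "toxdup@example.org",
    role = c("aut", "cre"))
Description: Toolkit for detecting candidate venom-toxin genes and their
    duplications in a predicted proteome. Builds position-specific profile
    hidden Markov models from multiple alignments, scores them against each
    other by local pairwise HMM-HMM alignment with extreme-value (Gumbel)
    E-value calibration, and iteratively merges sequences into duplication
    groups with a relationship tree. A five-stage filter turns homology-search
    hit tables against toxin databases into candidate toxins; peptide-level
    evidence from tryptic digests decides which candidates are detected in a
    venom proteome; Tajima's D is computed per duplication group. Seeded
    synthetic-data generators with planted ground truth replace genome and
    mass-spectrometry inputs for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
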