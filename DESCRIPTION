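Package: keyreg
Title: Key Regulator Discovery from Multi-Omics Differential Expression
Version: 0.1.0
Authors@R:
    person("Yan", "Novak", email = "ynovak@example.org", role = c("aut", "cre"))
Description: Identifies candidate upstream regulators of a marker gene from
    paired transcriptome and proteome differential-expression experiments.
    Implements two-colour microarray differential-expression calling (Welch
    test with Benjamini-Hochberg correction and a fold-change gate), emPAI
    label-free protein quantification with geometric-mean normalization,
    promoter scanning with positional weight matrices calibrated by a
    minSUM-style threshold, master-regulator search on directed regulatory
    networks with a permutation null, and a rank-integration scheme that
    combines transcription-factor and master-regulator evidence across cell
    lines into a single ordered key-regulator table. A synthetic-data
    generator with a planted regulator makes the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
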