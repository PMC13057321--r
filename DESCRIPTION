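Package: repshape
Title: TCR Beta Repertoire Analysis and V(D)J Recombination Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of T-cell receptor beta-chain (TCRbeta) clonotype
    repertoires: functionality partition, CDR3 length and insertion
    statistics, convergence, diversity indices, Kidera-factor and
    binding-strength profiling of CDR regions, F2 repertoire overlap with
    multidimensional scaling, V-segment usage and depletion analysis,
    matching against annotated TCR databases, and nonparametric group
    comparison (Kruskal-Wallis, Dunn post hoc, FDR correction). Includes
    an explicit V(D)J recombination simulator with tunable terminal
    deoxynucleotidyl transferase (TdT) insertion activity and exact
    in-model generation probabilities, so fetal-like and adult-like
    cohorts can be synthesised and every analysis stage verified end to
    end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml, Biostrings
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
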