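#' The packaged Kidera factor table
#'
#' Ten orthogonal physicochemical factors per standard amino acid,
#' derived by Kidera and colleagues (1985, J. Protein Chem. 4, 23-55)
#' from 188 physical properties. kf4 is the hydrophobicity-related
#' factor; kf8 relates to occurrence in alpha regions. Values are on the
#' standard published (dimensionless, roughly unit-variance) scale.
#'
#' @return 20 x 10 numeric matrix, rownames the one-letter amino-acid
#'   codes, colnames `kf1`..`kf10`.
#' @export
kidera_factors <- function() {
  path <- system.file("extdata", "kidera_factors.tsv",
                      package = "repshape", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 20L, ncol(tab) == 11L)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$aa
  stopifnot(setequal(rownames(m), AA_STANDARD),
            all(abs(colMeans(m)) < 0.2))  # published-table property
  m
}

#' Packaged synthetic germline segment library
#'
#' A self-contained SYNTHETIC TRB segment library (10 V genes over 8
#' families, 2 D, 3 J) for simulation and testing. Sequences are
#' invented but structurally faithful: every V 3' region starts at a
#' conserved Cys codon, every J carries a conserved Phe anchor, and all
#' germline pieces are length-multiples of three so that zero-insertion,
#' zero-deletion rearrangements are in frame. CDR2 amino acids are chosen
#' to give families a defined binding-strength gradient (TRBV4 and TRBV7
#' strong, the rest weak) so usage/depletion analyses are exercisable.
#' It is not an IMGT snapshot and carries no biological gene annotation.
#'
#' @param toy If `TRUE`, return the reduced 3 V / 2 D / 3 J version.
#' @return A `segment_library`.
#' @export
synthetic_segment_library <- function(toy = FALSE) {
  f <- if (toy) "segments_toy.tsv" else "segments_synthetic.tsv"
  read_segment_library(system.file("extdata", f, package = "repshape",
                                   mustWork = TRUE))
}
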