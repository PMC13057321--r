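# Codon-wise CDR3 translation. Out-of-frame sequences are translated
# codon-by-codon with '_' appended for a trailing partial codon so that
# non-functional clonotypes keep an amino-acid representation.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Translate CDR3 nucleotide sequences codon by codon
#'
#' Standard-code translation with `*` for stop codons and `_` appended when
#' the sequence length is not a multiple of three (trailing partial codon).
#'
#' @param nt Character vector of uppercase A/C/G/T sequences.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_cdr3(c("TGTGCCAGC", "TGTGC"))
#' @export
translate_cdr3 <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  if (any(grepl("[^ACGT]", nt))) {
    stop("CDR3 nucleotide sequence contains characters outside ACGT",
         call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    n <- nchar(s)
    nc <- n %/% 3L
    aa <- if (nc > 0L) {
      starts <- 3L * seq_len(nc) - 2L
      paste(unname(code[substring(s, starts, starts + 2L)]), collapse = "")
    } else ""
    if (n %% 3L != 0L) aa <- paste0(aa, "_")
    aa
  }, character(1), USE.NAMES = FALSE)
}

#' Classify clonotype functionality from its CDR3
#'
#' A rearrangement is `out_of_frame` when the CDR3 nucleotide length is not
#' a multiple of three, `stop_codon` when the in-frame translation contains
#' `*`, and `functional` otherwise.
#'
#' @param cdr3_nt Character vector of CDR3 nucleotide sequences.
#' @param cdr3_aa Optional matching amino-acid sequences; translated from
#'   `cdr3_nt` when missing.
#' @return Character vector with levels `functional`, `out_of_frame`,
#'   `stop_codon`.
#' @export
classify_functionality <- function(cdr3_nt, cdr3_aa = NULL) {
  if (is.null(cdr3_aa)) cdr3_aa <- translate_cdr3(cdr3_nt)
  out <- rep("functional", length(cdr3_nt))
  out[grepl("\\*", cdr3_aa)] <- "stop_codon"
  out[nchar(cdr3_nt) %% 3L != 0L] <- "out_of_frame"
  out
}
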