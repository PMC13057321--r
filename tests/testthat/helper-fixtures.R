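# Shared fixtures: tiny segment libraries, generative models, and
# hand-built repertoires used across the suite.

# degenerate 1 V / 1 D / 1 J library whose only zero-deletion,
# zero-insertion product is TGTGCC + GGG + TTT
lib_forced <- function() {
  segment_library(
    v = data.frame(name = "TRBV1", cdr1_aa = NA_character_,
                   cdr2_aa = NA_character_, nt_3prime = "TGTGCC",
                   stringsAsFactors = FALSE),
    d = data.frame(name = "TRBD1", nt = "GGG", stringsAsFactors = FALSE),
    j = data.frame(name = "TRBJ1-1", nt = "TTTTTC", anchor_offset = 0L,
                   stringsAsFactors = FALSE))
}

# small 2 V / 1 D / 2 J library for exhaustive-enumeration oracles
lib_small <- function() {
  segment_library(
    v = data.frame(name = c("TRBV1", "TRBV2"),
                   cdr1_aa = NA_character_, cdr2_aa = NA_character_,
                   nt_3prime = c("TGTGCCAGC", "TGCACCGTT"),
                   stringsAsFactors = FALSE),
    d = data.frame(name = "TRBD1", nt = "GGGAC",
                   stringsAsFactors = FALSE),
    j = data.frame(name = c("TRBJ1", "TRBJ2"),
                   nt = c("AAGCTTTCGG", "GAATTTTGG"),
                   anchor_offset = c(5L, 3L), stringsAsFactors = FALSE))
}

quick_repertoire <- function(nt, counts, v = "TRBV4-1", j = "TRBJ1-1",
                             vd = NA_real_, dj = NA_real_, aa = NULL, ...) {
  df <- data.frame(cdr3_nt = nt, v_gene = v, j_gene = j,
                   umi_count = counts, vd_insert_len = vd,
                   dj_insert_len = dj, stringsAsFactors = FALSE)
  if (!is.null(aa)) df$cdr3_aa <- aa
  repertoire(df, ...)
}
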