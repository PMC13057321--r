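#' Construct a repertoire object
#'
#' A `repertoire` is a sample's clonotype table plus metadata. Clonotypes
#' are keyed by (V gene, CDR3 nucleotide sequence, J gene) at gene level;
#' rows sharing a key are aggregated by summing their UMI counts. V/D/J
#' names are normalized to gene level (allele suffix stripped) on
#' construction, missing amino-acid sequences are translated from the
#' nucleotide sequence, and functionality is derived.
#'
#' @param clonotypes data.frame with columns `cdr3_nt`, `v_gene`, `j_gene`,
#'   `umi_count` and optionally `cdr3_aa`, `d_gene`, `vd_insert_len`,
#'   `dj_insert_len`.
#' @param sample_id Sample identifier.
#' @param subset Cell subset label, e.g. `"naive_CD8"`.
#' @param age_group Age-group label, e.g. `"preterm"`, `"adult"`.
#' @return An object of class `repertoire`: a list with `sample_id`,
#'   `subset`, `age_group` and the aggregated `clonotypes` data.frame.
#' @examples
#' rep <- repertoire(data.frame(
#'   cdr3_nt = c("TGTGCCAGCTTT", "TGTGCCAGCTTT", "TGTGCCGGGTTC"),
#'   v_gene = "TRBV4-1", j_gene = "TRBJ1-1", umi_count = c(4, 6, 1)))
#' total_umis(rep)
#' @export
repertoire <- function(clonotypes, sample_id = "sample",
                       subset = NA_character_, age_group = NA_character_) {
  cl <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  needed <- c("cdr3_nt", "v_gene", "j_gene", "umi_count")
  miss <- setdiff(needed, names(cl))
  if (length(miss)) {
    stop("missing column: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(cl) == 0L) stop("repertoire has no clonotypes", call. = FALSE)
  cl$cdr3_nt <- toupper(cl$cdr3_nt)
  if (any(!nzchar(cl$cdr3_nt))) stop("empty cdr3_nt", call. = FALSE)
  if (any(grepl("[^ACGT]", cl$cdr3_nt))) {
    stop("cdr3_nt contains characters outside ACGT", call. = FALSE)
  }
  cl$umi_count <- as.numeric(cl$umi_count)
  if (any(is.na(cl$umi_count)) || any(cl$umi_count < 1)) {
    bad <- which(is.na(cl$umi_count) | cl$umi_count < 1)
    stop("non-positive umi_count at row ", bad[1], call. = FALSE)
  }
  cl$v_gene <- normalize_gene_name(cl$v_gene, "gene")
  cl$j_gene <- normalize_gene_name(cl$j_gene, "gene")
  if (is.null(cl$d_gene)) cl$d_gene <- NA_character_
  if (is.null(cl$cdr3_aa) || all(is.na(cl$cdr3_aa))) {
    cl$cdr3_aa <- translate_cdr3(cl$cdr3_nt)
  }
  if (is.null(cl$vd_insert_len)) cl$vd_insert_len <- NA_real_
  if (is.null(cl$dj_insert_len)) cl$dj_insert_len <- NA_real_

  key <- paste(cl$v_gene, cl$cdr3_nt, cl$j_gene, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    counts <- tapply(cl$umi_count, key, sum)
    agg <- cl[first, , drop = FALSE]
    agg$umi_count <- as.numeric(counts[key[first]])
    cl <- agg
  }
  # canonical order: key-sorted, so construction is order-independent
  cl <- cl[order(cl$v_gene, cl$cdr3_nt, cl$j_gene), , drop = FALSE]
  rownames(cl) <- NULL
  cl$functional <- classify_functionality(cl$cdr3_nt, cl$cdr3_aa)
  keep <- c("cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene", "umi_count",
            "vd_insert_len", "dj_insert_len", "functional")
  structure(
    list(sample_id = sample_id, subset = subset, age_group = age_group,
         clonotypes = cl[, keep]),
    class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cl <- x$clonotypes
  cat("TCRbeta repertoire '", x$sample_id, "'", sep = "")
  if (!is.na(x$subset)) cat(" [", x$subset, "]", sep = "")
  if (!is.na(x$age_group)) cat(" (", x$age_group, ")", sep = "")
  cat("\n  clonotypes: ", nrow(cl),
      "   UMIs: ", format(total_umis(x)),
      "   functional: ", sum(cl$functional == "functional"), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.repertoire <- function(x, ...) x$clonotypes

#' Total UMI count of a repertoire
#' @param r A [repertoire].
#' @return Numeric scalar, the sum of clonotype UMI counts.
#' @export
total_umis <- function(r) sum(r$clonotypes$umi_count)

#' Clonotype frequencies
#'
#' UMI-count frequencies normalized within the repertoire (they sum to 1).
#' @param r A [repertoire].
#' @return Numeric vector aligned with the clonotype table rows.
#' @export
clonotype_frequencies <- function(r) {
  r$clonotypes$umi_count / total_umis(r)
}

#' Restrict a repertoire to a functionality partition
#'
#' @param r A [repertoire].
#' @param partition `"functional"`, `"nonfunctional"` or `"all"`.
#' @return A [repertoire] containing only the selected clonotypes.
#' @export
filter_functional <- function(r,
    partition = c("functional", "nonfunctional", "all")) {
  partition <- match.arg(partition)
  if (partition == "all") return(r)
  keep <- if (partition == "functional") {
    r$clonotypes$functional == "functional"
  } else {
    r$clonotypes$functional != "functional"
  }
  if (!any(keep)) {
    stop("empty partition: no ", partition, " clonotypes in sample '",
         r$sample_id, "'", call. = FALSE)
  }
  r$clonotypes <- r$clonotypes[keep, , drop = FALSE]
  rownames(r$clonotypes) <- NULL
  r
}
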