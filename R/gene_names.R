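#' Normalize a TRB gene segment name
#'
#' Collapses allele-level calls (e.g. `"TRBV12-3*01"`) to gene level
#' (`"TRBV12-3"`) or family level (`"TRBV12"`). Family level additionally
#' strips the gene-number suffix (`-N`) and any `/DV` cross-locus tag.
#' The function is idempotent at each level.
#'
#' @param raw Character vector of segment names beginning with a locus
#'   prefix (`TRBV`, `TRBD` or `TRBJ`).
#' @param level `"gene"` (drop allele suffix) or `"family"` (additionally
#'   drop the gene number).
#' @return Character vector of normalized names.
#' @examples
#' normalize_gene_name("TRBV12-3*01", "gene")    # "TRBV12-3"
#' normalize_gene_name("TRBV12-3*01", "family")  # "TRBV12"
#' @export
normalize_gene_name <- function(raw, level = c("gene", "family")) {
  level <- match.arg(level)
  if (any(!nzchar(raw)) || any(is.na(raw))) {
    stop("empty segment name", call. = FALSE)
  }
  bad <- !grepl("^TRB[VDJ]", raw)
  if (any(bad)) {
    stop("segment name without TRBV/TRBD/TRBJ prefix: ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  out <- sub("\\*[0-9]+$", "", raw)
  if (level == "family") {
    out <- sub("/DV[0-9]+$", "", out)
    out <- sub("-[0-9]+$", "", out)
  }
  out
}

#' @rdname normalize_gene_name
#' @export
gene_family <- function(raw) normalize_gene_name(raw, "family")
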