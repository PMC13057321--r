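# Readers/writers for clonotype tables (simple and MiXCR-like TSV
# dialects), germline segment libraries, and VDJdb-style annotation
# tables. All tables are tab-separated with a header row, UTF-8.

.col_maps <- list(
  simple = list(
    cdr3_nt = c("cdr3_nt"), cdr3_aa = c("cdr3_aa"),
    v_gene = c("v_gene"), d_gene = c("d_gene"), j_gene = c("j_gene"),
    count = c("count"), vd_insert = c("vd_insert"),
    dj_insert = c("dj_insert"), refpoints = character(0)),
  mixcr_like = list(
    cdr3_nt = c("nSeqCDR3", "nseqcdr3", "cdr3nt"),
    cdr3_aa = c("aaSeqCDR3", "aaseqcdr3", "cdr3aa"),
    v_gene = c("bestVHit", "allVHitsWithScore", "v"),
    d_gene = c("bestDHit", "allDHitsWithScore", "d"),
    j_gene = c("bestJHit", "allJHitsWithScore", "j"),
    count = c("cloneCount", "clonecount", "readCount"),
    vd_insert = character(0), dj_insert = character(0),
    refpoints = c("refPoints", "refpoints"))
)

.find_col <- function(header, aliases) {
  hit <- match(tolower(aliases), tolower(header))
  hit <- hit[!is.na(hit)]
  if (length(hit)) header[hit[1]] else NA_character_
}

# first hit of a MiXCR-style multi-hit field: "TRBV12-3*00(1200),..."
.first_hit <- function(x) {
  x <- sub(",.*$", "", x)
  sub("\\(.*\\)$", "", x)
}

#' Read a clonotype table
#'
#' Parses a tab-separated clonotype table into a [repertoire]. Two header
#' dialects are understood: `"simple"` (columns `cdr3_nt`, `cdr3_aa`,
#' `v_gene`, `d_gene`, `j_gene`, `count`, `vd_insert`, `dj_insert`) and
#' `"mixcr_like"` (`cloneCount`, `nSeqCDR3`, `aaSeqCDR3`, `bestVHit`/
#' `bestDHit`/`bestJHit` or `all*HitsWithScore`, `refPoints`). Rows sharing
#' a (V gene, CDR3nt, J gene) key are aggregated by summing counts.
#'
#' Insertion lengths are taken from explicit `vd_insert`/`dj_insert`
#' columns when present, or derived from a `refPoints` field of the form
#' `vEnd:dBegin:dEnd:jBegin` (0-based CDR3 coordinates; empty D fields
#' denote a D-less junction, whose whole insert run is recorded as
#' `vd_insert_len`). With neither source the lengths are left `NA` —
#' insert-based features are then undefined rather than silently zero.
#'
#' @param path Path to the TSV file.
#' @param dialect `"simple"` or `"mixcr_like"`.
#' @param sample_id Sample identifier; defaults to the file name, or the
#'   `sample_id` column if the file carries one.
#' @param subset,age_group Optional metadata labels.
#' @return A [repertoire].
#' @export
read_clonotype_table <- function(path, dialect = c("simple", "mixcr_like"),
                                 sample_id = NULL, subset = NA_character_,
                                 age_group = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  map <- .col_maps[[dialect]]
  cols <- lapply(map, .find_col, header = names(tab))
  for (mand in c("cdr3_nt", "v_gene", "j_gene", "count")) {
    if (is.na(cols[[mand]])) {
      stop("missing column: ", mand, call. = FALSE)
    }
  }
  cnt <- suppressWarnings(as.numeric(tab[[cols$count]]))
  if (any(is.na(cnt) | cnt < 1)) {
    stop("non-positive or unparseable count at line ",
         which(is.na(cnt) | cnt < 1)[1] + 1L, call. = FALSE)
  }
  cl <- data.frame(cdr3_nt = toupper(tab[[cols$cdr3_nt]]),
                   umi_count = cnt, stringsAsFactors = FALSE)
  cl$v_gene <- .first_hit(tab[[cols$v_gene]])
  cl$j_gene <- .first_hit(tab[[cols$j_gene]])
  cl$d_gene <- if (!is.na(cols$d_gene)) .first_hit(tab[[cols$d_gene]])
               else NA_character_
  cl$d_gene[!nzchar(cl$d_gene) | is.na(cl$d_gene)] <- NA_character_
  cl$cdr3_aa <- if (!is.na(cols$cdr3_aa)) tab[[cols$cdr3_aa]]
                else NA_character_

  if (!is.na(cols$vd_insert) && !is.na(cols$dj_insert)) {
    cl$vd_insert_len <- suppressWarnings(as.numeric(tab[[cols$vd_insert]]))
    cl$dj_insert_len <- suppressWarnings(as.numeric(tab[[cols$dj_insert]]))
  } else if (length(map$refpoints) && !is.na(cols$refpoints)) {
    rp <- .parse_refpoints(tab[[cols$refpoints]])
    cl$vd_insert_len <- rp$vd
    cl$dj_insert_len <- rp$dj
  } else {
    cl$vd_insert_len <- NA_real_
    cl$dj_insert_len <- NA_real_
  }
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(tab)) tab$sample_id[1]
                 else sub("\\.[^.]*$", "", basename(path))
  }
  repertoire(cl, sample_id = sample_id, subset = subset,
             age_group = age_group)
}

# "vEnd:dBegin:dEnd:jBegin" per row; empty D fields = D-less junction
.parse_refpoints <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vd <- dj <- rep(NA_real_, length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 4L) next
    num <- suppressWarnings(as.numeric(p[1:4]))
    if (is.na(num[1]) || is.na(num[4])) next
    if (is.na(num[2]) || is.na(num[3])) {
      vd[i] <- num[4] - num[1]
      dj[i] <- 0
    } else {
      vd[i] <- num[2] - num[1]
      dj[i] <- num[4] - num[3]
    }
  }
  if (any(!is.na(vd) & vd < 0) || any(!is.na(dj) & dj < 0)) {
    stop("negative insertion length derived from reference points",
         call. = FALSE)
  }
  list(vd = vd, dj = dj)
}

#' Write a repertoire as a simple-dialect clonotype TSV
#'
#' @param r A [repertoire].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(r, path) {
  cl <- r$clonotypes
  out <- data.frame(sample_id = r$sample_id, cdr3_nt = cl$cdr3_nt,
                    cdr3_aa = cl$cdr3_aa, v_gene = cl$v_gene,
                    d_gene = ifelse(is.na(cl$d_gene), "", cl$d_gene),
                    j_gene = cl$j_gene, count = cl$umi_count,
                    vd_insert = cl$vd_insert_len,
                    dj_insert = cl$dj_insert_len,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a germline segment library
#'
#' Expects a TSV with columns `class` (V/D/J), `name`, `family`,
#' `cdr1_aa`, `cdr2_aa`, `sequence` and `anchor_offset`. For V entries
#' `sequence` is the 3' nucleotides from the conserved Cys codon onward
#' (it must begin with TGT/TGC); for J entries `anchor_offset` is the
#' 0-based offset of the conserved Phe codon within `sequence`. V entries
#' without CDR1/CDR2 amino acids are kept but flagged unusable for
#' germline strength scoring (`cdr_usable = FALSE`).
#'
#' @param path Path to the TSV file.
#' @return A `segment_library` object (lists `v`, `d`, `j`).
#' @export
read_segment_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("class", "name", "sequence")) {
    if (!col %in% names(tab)) {
      stop("missing column: ", col, call. = FALSE)
    }
  }
  tab$sequence <- toupper(tab$sequence)
  v <- tab[tab$class == "V", , drop = FALSE]
  d <- tab[tab$class == "D", , drop = FALSE]
  j <- tab[tab$class == "J", , drop = FALSE]
  segment_library(
    v = data.frame(name = v$name,
                   cdr1_aa = if ("cdr1_aa" %in% names(v)) v$cdr1_aa
                             else NA_character_,
                   cdr2_aa = if ("cdr2_aa" %in% names(v)) v$cdr2_aa
                             else NA_character_,
                   nt_3prime = v$sequence, stringsAsFactors = FALSE),
    d = data.frame(name = d$name, nt = d$sequence,
                   stringsAsFactors = FALSE),
    j = data.frame(name = j$name, nt = j$sequence,
                   anchor_offset = as.integer(j$anchor_offset),
                   stringsAsFactors = FALSE))
}

#' Construct and validate a segment library
#'
#' @param v data.frame with `name`, `cdr1_aa`, `cdr2_aa`, `nt_3prime`
#'   (nucleotides from the conserved Cys codon to the segment 3' end).
#' @param d data.frame with `name`, `nt`.
#' @param j data.frame with `name`, `nt`, `anchor_offset` (0-based offset
#'   of the conserved Phe codon within `nt`).
#' @return A validated `segment_library`.
#' @export
segment_library <- function(v, d, j) {
  if (nrow(v) == 0L || nrow(j) == 0L) {
    stop("segment library needs at least one V and one J entry",
         call. = FALSE)
  }
  nm <- c(v$name, d$name, j$name)
  if (anyDuplicated(nm)) {
    stop("duplicate segment name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  anchor <- substr(v$nt_3prime, 1, 3)
  bad <- !(anchor %in% c("TGT", "TGC"))
  if (any(bad)) {
    stop("V segment ", v$name[bad][1],
         ": 3' sequence does not begin with a Cys codon", call. = FALSE)
  }
  if (any(is.na(j$anchor_offset)) ||
      any(j$anchor_offset < 0L | j$anchor_offset + 3L > nchar(j$nt))) {
    bad <- which(is.na(j$anchor_offset) | j$anchor_offset < 0L |
                 j$anchor_offset + 3L > nchar(j$nt))
    stop("J segment ", j$name[bad][1],
         ": anchor offset outside sequence bounds", call. = FALSE)
  }
  pcod <- substring(j$nt, j$anchor_offset + 1L, j$anchor_offset + 3L)
  bad <- !(pcod %in% c("TTT", "TTC"))
  if (any(bad)) {
    stop("J segment ", j$name[bad][1],
         ": anchor codon not found (expected Phe)", call. = FALSE)
  }
  v$family <- normalize_gene_name(v$name, "family")
  v$cdr_usable <- !is.na(v$cdr1_aa) & !is.na(v$cdr2_aa)
  structure(list(v = v, d = d, j = j), class = "segment_library")
}

#' @export
print.segment_library <- function(x, ...) {
  cat("Germline segment library: ", nrow(x$v), " V (",
      length(unique(x$v$family)), " families), ", nrow(x$d), " D, ",
      nrow(x$j), " J\n", sep = "")
  invisible(x)
}

#' Read a VDJdb-style annotation table
#'
#' Accepts VDJdb column names (`cdr3`, `v.segm`, `species`, `antigen`,
#' `mhc.class`, `vdjdb.score`) and close aliases. Records are filtered to
#' `score >= min_score` and, optionally, to one MHC class; V names are
#' normalized to gene level.
#'
#' @param path Path to the TSV file.
#' @param min_score Minimum confidence score kept (default 1, the usual
#'   curated-database threshold).
#' @param mhc_class `"I"`, `"II"`, or `NULL` for no class filter.
#' @return data.frame with columns `cdr3_aa`, `v_gene`, `label`,
#'   `mhc_class`, `score`.
#' @export
read_annotation_table <- function(path, min_score = 1, mhc_class = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  hdr <- names(tab)
  cdr3 <- .find_col(hdr, c("cdr3", "cdr3_aa", "cdr3aa"))
  vseg <- .find_col(hdr, c("v.segm", "v_gene", "v"))
  lab  <- .find_col(hdr, c("species", "antigen.species", "label",
                           "antigen", "antigen.epitope"))
  mhc  <- .find_col(hdr, c("mhc.class", "mhc_class"))
  sco  <- .find_col(hdr, c("vdjdb.score", "score"))
  for (need in c("cdr3", "vseg", "sco")) {
    if (is.na(get(need))) stop("missing column: ", need, call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(tab[[sco]]))
  if (any(is.na(score))) {
    stop("unparseable score at line ", which(is.na(score))[1] + 1L,
         call. = FALSE)
  }
  out <- data.frame(
    cdr3_aa = tab[[cdr3]],
    v_gene = normalize_gene_name(.first_hit(tab[[vseg]]), "gene"),
    label = if (!is.na(lab)) tab[[lab]] else "annotated",
    mhc_class = if (!is.na(mhc)) as.character(tab[[mhc]])
                else NA_character_,
    score = score, stringsAsFactors = FALSE)
  out$mhc_class <- sub("^MHC", "", out$mhc_class)
  keep <- out$score >= min_score
  if (!is.null(mhc_class)) keep <- keep & out$mhc_class %in% mhc_class
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
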