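# Matching repertoire clonotypes against an annotated TCR table
# (VDJdb-style): same V gene, equal CDR3aa length, Hamming distance at
# most `max_mismatch` (substitutions only — no indels).

.hamming <- function(a, b) {
  # equal-length strings
  sum(strsplit(a, "", fixed = TRUE)[[1]] !=
      strsplit(b, "", fixed = TRUE)[[1]])
}

#' Match clonotypes against an annotation table
#'
#' A functional clonotype matches an annotation record when the
#' gene-level V names are equal, the CDR3 amino-acid lengths are equal,
#' and the Hamming distance is at most `max_mismatch` (default 1;
#' substitutions only, so sequences of different length never match). A
#' clonotype counts once per label even when it hits several records of
#' that label; labels are analyzed independently.
#'
#' @param r A [repertoire] (conventionally downsampled to a fixed UMI
#'   depth upstream).
#' @param annotations data.frame from [read_annotation_table()] (columns
#'   `cdr3_aa`, `v_gene`, `label`).
#' @param max_mismatch Maximum CDR3aa Hamming distance (default 1).
#' @return data.frame, one row per label: `label`, `n_matched`,
#'   `cumulative_frequency`; attribute `"matches"` holds the
#'   per-clonotype match table (clonotype index, annotation index,
#'   mismatches).
#' @export
match_clonotypes <- function(r, annotations, max_mismatch = 1) {
  rf <- filter_functional(r, "functional")
  cl <- rf$clonotypes
  freq <- cl$umi_count / sum(cl$umi_count)
  labels <- unique(annotations$label)
  if (!nrow(annotations)) {
    return(structure(data.frame(label = character(0),
                                n_matched = integer(0),
                                cumulative_frequency = numeric(0)),
                     matches = NULL))
  }
  ckey <- paste(cl$v_gene, nchar(cl$cdr3_aa), sep = "\r")
  akey <- paste(annotations$v_gene, nchar(annotations$cdr3_aa), sep = "\r")
  match_rows <- list()
  for (key in intersect(unique(ckey), unique(akey))) {
    ci <- which(ckey == key)
    ai <- which(akey == key)
    for (i in ci) {
      for (j in ai) {
        mm <- .hamming(cl$cdr3_aa[i], annotations$cdr3_aa[j])
        if (mm <= max_mismatch) {
          match_rows[[length(match_rows) + 1L]] <-
            data.frame(clonotype = i, annotation = j, mismatches = mm,
                       label = annotations$label[j],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows)
             else data.frame(clonotype = integer(0),
                             annotation = integer(0),
                             mismatches = integer(0),
                             label = character(0))
  per_label <- do.call(rbind, lapply(labels, function(lb) {
    idx <- unique(matches$clonotype[matches$label == lb])
    data.frame(label = lb, n_matched = length(idx),
               cumulative_frequency = sum(freq[idx]),
               stringsAsFactors = FALSE)
  }))
  structure(per_label, matches = matches)
}

#' Per-label annotated profile with generation probabilities
#'
#' Extends [match_clonotypes()] with mean in-model generation
#' probabilities: per label the arithmetic mean of [pgen_nt()] over the
#' matched clonotypes' nucleotide sequences, plus the repertoire-wide
#' mean Pgen over all functional clonotypes for comparison. Public,
#' insertion-poor clonotypes are expected to show matched-set means
#' above the repertoire-wide mean.
#'
#' @param r A [repertoire].
#' @param annotations Annotation data.frame.
#' @param model Optional `generative_model`; without it Pgen columns are
#'   `NA`.
#' @param max_mismatch Maximum CDR3aa Hamming distance.
#' @return data.frame per label: `label`, `n_matched`,
#'   `cumulative_frequency`, `mean_pgen`, `repertoire_mean_pgen`.
#' @export
annotated_profile <- function(r, annotations, model = NULL,
                              max_mismatch = 1) {
  res <- match_clonotypes(r, annotations, max_mismatch)
  matches <- attr(res, "matches")
  res$mean_pgen <- NA_real_
  res$repertoire_mean_pgen <- NA_real_
  if (is.null(model)) return(res)
  cl <- filter_functional(r, "functional")$clonotypes
  pg <- pgen_nt(model, cl$cdr3_nt)
  rep_mean <- mean(pg)
  for (i in seq_len(nrow(res))) {
    idx <- unique(matches$clonotype[matches$label == res$label[i]])
    res$mean_pgen[i] <- if (length(idx)) mean(pg[idx]) else NA_real_
    res$repertoire_mean_pgen[i] <- rep_mean
  }
  res
}
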