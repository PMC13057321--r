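# Kidera-factor profiles, binding-strength scores over CDR windows,
# central-region residue frequencies, and length-matched downsampling.

#' Strongly binding residue set and scoring configuration
#'
#' The binding-strength score of a CDR window is the count (or fraction)
#' of its residues belonging to the strongly binding set
#' L, F, I, M, V, W, C, Y — residues expected to promote strong van der
#' Waals and hydrophobic contacts at the TCR interface.
#'
#' @param strong_residues Character vector of one-letter residues.
#' @param cdr3_window Central-window width for CDR3 (default 5).
#' @param score_kind `"count"` or `"fraction"`.
#' @param weighting `"clonotype"` or `"umi"` averaging over clonotypes.
#' @return A list of class `strength_config`.
#' @export
strength_config <- function(strong_residues = c("L", "F", "I", "M",
                                                "V", "W", "C", "Y"),
                            cdr3_window = 5,
                            score_kind = c("count", "fraction"),
                            weighting = c("umi", "clonotype")) {
  stopifnot(all(strong_residues %in% AA_STANDARD), cdr3_window >= 1)
  structure(list(strong_residues = strong_residues,
                 cdr3_window = as.integer(cdr3_window),
                 score_kind = match.arg(score_kind),
                 weighting = match.arg(weighting)),
            class = "strength_config")
}

#' Central window of an amino-acid sequence
#'
#' Returns the `w` central residues (start `floor((len - w)/2)`,
#' 0-based); sequences shorter than `w` yield `NA` — they are excluded
#' from window statistics rather than padded.
#'
#' @param aa Character vector of amino-acid sequences.
#' @param w Window width.
#' @return Character vector of windows (`NA` where `nchar(aa) < w`).
#' @examples
#' central_window("CASSLAPGATNEKLFF", 5)  # "APGAT"
#' @export
central_window <- function(aa, w = 5) {
  len <- nchar(aa)
  start <- (len - w) %/% 2L
  out <- substr(aa, start + 1L, start + w)
  out[len < w] <- NA_character_
  out
}

# eligible functional clonotypes with their windows and normalized weights
.window_set <- function(r, w, weighting) {
  cl <- filter_functional(r, "functional")$clonotypes
  win <- central_window(cl$cdr3_aa, w)
  ok <- !is.na(win)
  if (!any(ok)) {
    stop("empty profile: no functional clonotype with CDR3 of length >= ",
         w, call. = FALSE)
  }
  cl <- cl[ok, , drop = FALSE]
  list(win = win[ok], w = .weights(cl, weighting), cl = cl)
}

#' Kidera-factor profile of a repertoire
#'
#' For each functional clonotype the ten Kidera factors are averaged
#' over the `w` central CDR3 residues; the repertoire profile is the
#' weighted mean over eligible clonotypes (shorter CDR3s excluded).
#'
#' @param r A [repertoire].
#' @param table Kidera matrix from [kidera_factors()].
#' @param w Central-window width (default 5).
#' @param weighting `"clonotype"` or `"umi"`.
#' @return Named numeric vector `kf1`..`kf10`.
#' @export
kidera_profile <- function(r, table = kidera_factors(), w = 5,
                           weighting = c("clonotype", "umi")) {
  weighting <- match.arg(weighting)
  ws <- .window_set(r, w, weighting)
  per_clone <- t(vapply(strsplit(ws$win, "", fixed = TRUE),
                        function(res) colMeans(table[res, , drop = FALSE]),
                        numeric(ncol(table))))
  stats::setNames(colSums(per_clone * ws$w), colnames(table))
}

# strength of one window string under a config
.window_strength <- function(win, cfg) {
  res <- strsplit(win, "", fixed = TRUE)
  cnt <- vapply(res, function(x) sum(x %in% cfg$strong_residues),
                numeric(1))
  if (cfg$score_kind == "fraction") cnt / nchar(win) else cnt
}

#' Binding-strength score of a CDR region
#'
#' Per clonotype: for CDR3 the window is the central `cdr3_window`
#' residues of the CDR3 amino-acid sequence; for CDR1/CDR2 it is the
#' germline CDR of the clonotype's V gene from the segment library
#' (optionally trimmed by `trim` residues at each end). The score is the
#' count (or fraction) of window residues in the strongly binding set;
#' the repertoire value is the weighted mean over functional clonotypes.
#'
#' @param r A [repertoire].
#' @param cfg A [strength_config()].
#' @param region `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @param library Required for CDR1/CDR2: a `segment_library` whose V
#'   entries carry the germline CDR amino acids. Clonotypes whose V gene
#'   is missing from the library (or lacks CDR data) are excluded; their
#'   count is reported via the `"n_excluded"` attribute.
#' @return Weighted mean score (attribute `n_excluded` for CDR1/CDR2).
#' @export
strength_score <- function(r, cfg = strength_config(),
                           region = c("CDR3", "CDR1", "CDR2"),
                           library = NULL) {
  region <- match.arg(region)
  if (region == "CDR3") {
    ws <- .window_set(r, cfg$cdr3_window, cfg$weighting)
    return(sum(.window_strength(ws$win, cfg) * ws$w))
  }
  if (is.null(library)) {
    stop("configuration error: CDR1/CDR2 strength requires a segment ",
         "library", call. = FALSE)
  }
  cl <- filter_functional(r, "functional")$clonotypes
  col <- if (region == "CDR1") "cdr1_aa" else "cdr2_aa"
  cdr <- library$v[[col]][match(cl$v_gene, library$v$name)]
  ok <- !is.na(cdr)
  if (!any(ok)) {
    stop("empty profile: no clonotype with germline ", region,
         " data", call. = FALSE)
  }
  cl <- cl[ok, , drop = FALSE]
  w <- .weights(cl, cfg$weighting)
  out <- sum(.window_strength(cdr[ok], cfg) * w)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Residue frequencies in the central CDR3 region
#'
#' Weighted frequency of each of the 20 standard residues over all
#' central-window positions of eligible functional clonotypes; the
#' returned vector sums to 1.
#'
#' @param r A [repertoire].
#' @param w Window width (default 5).
#' @param weighting `"clonotype"` or `"umi"`.
#' @return Named 20-vector of fractions.
#' @export
residue_frequencies <- function(r, w = 5,
                                weighting = c("clonotype", "umi")) {
  weighting <- match.arg(weighting)
  ws <- .window_set(r, w, weighting)
  freq <- stats::setNames(numeric(length(AA_STANDARD)), AA_STANDARD)
  res <- strsplit(ws$win, "", fixed = TRUE)
  for (i in seq_along(res)) {
    tab <- table(factor(res[[i]], levels = AA_STANDARD))
    freq <- freq + ws$w[i] * as.numeric(tab) / length(res[[i]])
  }
  freq
}

#' Length-matched downsampling across repertoires
#'
#' Equalizes CDR3 amino-acid length distributions: for every length the
#' minimum functional-clonotype count across the repertoires is taken,
#' and each repertoire is downsampled (without replacement, seeded) to
#' exactly that many clonotypes per length. All outputs then share an
#' identical CDR3aa-length histogram, removing length as a confounder
#' for residue-composition comparisons.
#'
#' @param reps List of [repertoire] objects (>= 2).
#' @param seed Integer seed.
#' @return List of length-matched [repertoire] objects.
#' @export
length_match_downsample <- function(reps, seed) {
  stopifnot(length(reps) >= 2)
  reps <- lapply(reps, filter_functional, partition = "functional")
  lens <- lapply(reps, function(r) nchar(r$clonotypes$cdr3_aa))
  all_len <- sort(unique(unlist(lens)))
  env <- vapply(all_len, function(L)
    min(vapply(lens, function(x) sum(x == L), numeric(1))), numeric(1))
  .with_seed(seed, lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    keep <- unlist(lapply(seq_along(all_len), function(k) {
      if (env[k] == 0) return(integer(0))
      at <- which(lens[[i]] == all_len[k])
      if (length(at) == 1L) at else sample(at, env[k])
    }))
    r$clonotypes <- r$clonotypes[sort(keep), , drop = FALSE]
    rownames(r$clonotypes) <- NULL
    r
  }))
}
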