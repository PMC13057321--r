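# Per-repertoire summary statistics: functionality partition, CDR3
# length, insert size, zero-insertion frequency, convergence,
# UMI downsampling and diversity indices.

#' Non-functional fractions of a repertoire
#'
#' Fraction of non-functional (out-of-frame or stop-codon) clonotypes,
#' both by unique nucleotide clonotype and by UMIs.
#'
#' @param r A [repertoire].
#' @return Named numeric vector `c(by_clonotype, by_umi)`.
#' @export
nonfunctional_fractions <- function(r) {
  cl <- r$clonotypes
  nf <- cl$functional != "functional"
  c(by_clonotype = mean(nf),
    by_umi = sum(cl$umi_count[nf]) / sum(cl$umi_count))
}

.weights <- function(cl, weighting) {
  w <- if (weighting == "umi") cl$umi_count else rep(1, nrow(cl))
  w / sum(w)
}

#' Summary features of a repertoire
#'
#' Mean CDR3 nucleotide length, mean total insert size
#' (`vd_insert_len + dj_insert_len`) and zero-insertion frequency (the
#' weighted fraction of clonotypes with no added nucleotides at either
#' junction), restricted to functional clonotypes by default. Weighting
#' is by unique clonotype (default) or by UMIs.
#'
#' @param r A [repertoire].
#' @param functional_only Restrict to functional clonotypes (default
#'   `TRUE`).
#' @param weighting `"clonotype"` or `"umi"`.
#' @return Named numeric vector `c(mean_cdr3_nt_length,
#'   mean_insert_size, zero_insert_freq)`.
#' @export
summary_features <- function(r, functional_only = TRUE,
                             weighting = c("clonotype", "umi")) {
  weighting <- match.arg(weighting)
  if (functional_only) r <- filter_functional(r, "functional")
  cl <- r$clonotypes
  w <- .weights(cl, weighting)
  ins <- cl$vd_insert_len + cl$dj_insert_len
  if (anyNA(ins)) {
    stop("undefined feature: insertion lengths absent for some ",
         "clonotypes; insert-based features cannot be computed",
         call. = FALSE)
  }
  c(mean_cdr3_nt_length = sum(w * nchar(cl$cdr3_nt)),
    mean_insert_size = sum(w * ins),
    zero_insert_freq = sum(w * (ins == 0)))
}

#' Repertoire convergence
#'
#' Ratio of the number of distinct CDR3 nucleotide sequences to the
#' number of distinct CDR3 amino-acid sequences among the `top_n` most
#' abundant functional clonotypes (unique nucleotide sequences, ranked
#' by UMI count; ties broken by CDR3nt lexicographic order). Values
#' above 1 indicate convergent recombination: several nucleotide routes
#' to the same protein sequence.
#'
#' @param r A [repertoire].
#' @param top_n Number of most abundant clonotypes entering the ratio
#'   (default 3000).
#' @param functional_only Restrict to functional clonotypes (default
#'   `TRUE`).
#' @return Numeric ratio >= 1.
#' @export
convergence <- function(r, top_n = 3000, functional_only = TRUE) {
  if (functional_only) r <- filter_functional(r, "functional")
  cl <- r$clonotypes
  ord <- order(-cl$umi_count, cl$cdr3_nt)
  sel <- cl[ord[seq_len(min(top_n, nrow(cl)))], ]
  length(unique(sel$cdr3_nt)) / length(unique(sel$cdr3_aa))
}

#' Downsample a repertoire to a fixed UMI depth
#'
#' Samples `n` UMIs without replacement (multivariate hypergeometric
#' over the clonotype counts); clonotypes left with zero UMIs are
#' dropped. Deterministic given `seed`. Used to equalize sequencing
#' depth before diversity or matching analyses.
#'
#' @param r A [repertoire].
#' @param n Target UMI count; must not exceed `total_umis(r)`.
#' @param seed Integer seed.
#' @return A [repertoire] with `total_umis` equal to `n`.
#' @export
downsample_umis <- function(r, n, seed) {
  tot <- total_umis(r)
  if (n > tot) {
    stop("insufficient depth: requested ", n, " UMIs but repertoire '",
         r$sample_id, "' has ", tot, call. = FALSE)
  }
  cl <- r$clonotypes
  idx <- rep.int(seq_len(nrow(cl)), cl$umi_count)
  take <- .with_seed(seed, sample(idx, n, replace = FALSE))
  cnt <- tabulate(take, nbins = nrow(cl))
  keep <- cnt > 0L
  cl <- cl[keep, , drop = FALSE]
  cl$umi_count <- cnt[keep]
  rownames(cl) <- NULL
  r$clonotypes <- cl
  r
}

#' Diversity indices
#'
#' Observed diversity (clonotype richness) and the normalized
#' Shannon-Wiener index: clonotype-frequency entropy (natural log)
#' divided by the log of the observed diversity, so 1 is a perfectly
#' even repertoire. Defined as 0 for a single-clonotype repertoire.
#' Typically computed after [downsample_umis()].
#'
#' @param r A [repertoire].
#' @return Named vector `c(observed_diversity, normalized_shannon)`.
#' @export
diversity_indices <- function(r) {
  f <- clonotype_frequencies(r)
  s <- length(f)
  h <- -sum(f * log(f))
  c(observed_diversity = s,
    normalized_shannon = if (s == 1L) 0 else h / log(s))
}

#' Full per-repertoire summary
#'
#' Convenience wrapper assembling all Fig-2-style quantities for one
#' sample: non-functional fractions, functional summary features,
#' convergence and (optionally depth-normalized) diversity indices.
#'
#' @param object A [repertoire].
#' @param weighting Weighting for the summary features.
#' @param top_n Convergence selection size.
#' @param diversity_depth UMI depth for diversity downsampling, or
#'   `NULL` to use the full repertoire. Samples shallower than the depth
#'   get `NA` diversity values.
#' @param seed Seed for the diversity downsampling.
#' @param ... Unused.
#' @return Named numeric vector (one FeatureTable row).
#' @export
summary.repertoire <- function(object, weighting = "clonotype",
                               top_n = 3000, diversity_depth = NULL,
                               seed = 1, ...) {
  nf <- nonfunctional_fractions(object)
  sf <- summary_features(object, weighting = weighting)
  cv <- convergence(object, top_n = top_n)
  dv <- if (is.null(diversity_depth)) {
    diversity_indices(filter_functional(object, "functional"))
  } else {
    fr <- filter_functional(object, "functional")
    if (total_umis(fr) < diversity_depth) {
      c(observed_diversity = NA_real_, normalized_shannon = NA_real_)
    } else {
      diversity_indices(downsample_umis(fr, diversity_depth, seed))
    }
  }
  c(pct_nonfunctional_clonotypes = unname(nf["by_clonotype"]),
    pct_nonfunctional_umis = unname(nf["by_umi"]),
    sf, convergence = cv, dv)
}
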