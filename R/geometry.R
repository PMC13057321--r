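# Pairwise repertoire overlap (F2), -log10(F2) distance matrices,
# classical MDS, and z-scored feature PCA / hierarchical clustering.

# frequencies aggregated by (V gene, CDR3aa) over functional clonotypes
.f2_profile <- function(r) {
  cl <- filter_functional(r, "functional")$clonotypes
  f <- cl$umi_count / sum(cl$umi_count)
  key <- paste(cl$v_gene, cl$cdr3_aa, sep = "\r")
  tapply(f, key, sum)
}

#' F2 overlap between two repertoires
#'
#' Sum over shared clonotypes of the geometric mean of their
#' frequencies, where clonotypes are considered shared when they have
#' the same V segment (gene level) and the same CDR3 amino-acid
#' sequence. Computed on functional clonotypes with frequencies
#' renormalized within the functional subset; identical repertoires give
#' 1, disjoint ones 0.
#'
#' @param a,b [repertoire] objects.
#' @return Numeric value in [0, 1].
#' @export
f2_overlap <- function(a, b) {
  pa <- .f2_profile(a)
  pb <- .f2_profile(b)
  shared <- intersect(names(pa), names(pb))
  if (!length(shared)) return(0)
  sum(sqrt(pa[shared] * pb[shared]))
}

#' -log10(F2) distance matrix
#'
#' Pairwise distances `d(i, j) = -log10(max(F2(i, j), floor))` with a
#' zero diagonal. The floor keeps zero-overlap pairs finite so the
#' matrix stays complete for MDS.
#'
#' @param reps List of [repertoire] objects (>= 2).
#' @param floor Smallest F2 value used in the log (default 1e-12, i.e. a
#'   maximum distance of 12).
#' @return List of class `distance_matrix` with `sample_ids` and the
#'   symmetric `values` matrix.
#' @export
f2_distance_matrix <- function(reps, floor = 1e-12) {
  stopifnot(length(reps) >= 2)
  n <- length(reps)
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  prof <- lapply(reps, .f2_profile)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(names(prof[[i]]), names(prof[[j]]))
      f2 <- if (length(shared))
        sum(sqrt(prof[[i]][shared] * prof[[j]][shared])) else 0
      m[i, j] <- m[j, i] <- -log10(max(f2, floor))
    }
  }
  structure(list(sample_ids = ids, values = m), class = "distance_matrix")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering of squared distances and eigendecomposition via
#' [stats::cmdscale()], with a fixed sign convention (each axis's
#' largest-magnitude coordinate is positive) so embeddings are
#' comparable across runs. Dimensions whose eigenvalues are not positive
#' are truncated at zero and flagged.
#'
#' @param d A `distance_matrix` (or plain symmetric matrix).
#' @param k Embedding dimension (default 2); needs `n >= k + 1` samples.
#' @return List of class `repertoire_mds`: `points` (n x k), `eig`,
#'   `negative_truncated` flag, `sample_ids`.
#' @export
classical_mds <- function(d, k = 2) {
  m <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  ids <- if (inherits(d, "distance_matrix")) d$sample_ids else rownames(m)
  stopifnot(nrow(m) >= k + 1)
  fit <- suppressWarnings(stats::cmdscale(m, k = k, eig = TRUE))
  eig <- fit$eig
  if (all(eig <= 1e-12)) {
    stop("degenerate geometry: no positive eigenvalue in the ",
         "double-centered matrix", call. = FALSE)
  }
  pts <- fit$points
  truncated <- ncol(pts) < k || any(eig[seq_len(k)] < 0)
  if (ncol(pts) < k) {   # pad axes whose eigenvalues were not positive
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  dimnames(pts) <- list(ids, paste0("MDS", seq_len(k)))
  structure(list(points = pts, eig = eig,
                 negative_truncated = truncated, sample_ids = ids),
            class = "repertoire_mds")
}

#' @export
print.repertoire_mds <- function(x, ...) {
  cat("Classical MDS embedding: ", nrow(x$points), " samples in ",
      ncol(x$points), " dimensions",
      if (x$negative_truncated) " (non-Euclidean part truncated)", "\n",
      sep = "")
  print(utils::head(x$points))
  invisible(x)
}

#' @export
plot.repertoire_mds <- function(x, col = 1, pch = 19, ...) {
  graphics::plot(x$points[, 1], x$points[, 2], col = col, pch = pch,
                 xlab = "MDS1", ylab = "MDS2", ...)
  graphics::text(x$points[, 1], x$points[, 2], labels = x$sample_ids,
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' Assemble a sample-by-feature table
#'
#' One row per repertoire with the multivariate feature set: convergence,
#' observed diversity and normalized Shannon-Wiener index (at a fixed
#' downsampling depth), mean insert size, mean CDR3nt length, and mean
#' Kidera factors 1-10 of the five central CDR3 residues.
#'
#' @param reps List of [repertoire] objects.
#' @param diversity_depth UMI depth for diversity downsampling (default
#'   4500), or `NULL` for no downsampling.
#' @param seed Seed for the downsampling.
#' @param kidera Kidera matrix.
#' @param weighting Weighting for summary features and Kidera profile.
#' @return data.frame with `sample_id`, `subset`, `age_group` and the
#'   numeric feature columns.
#' @export
feature_table <- function(reps, diversity_depth = 4500, seed = 1,
                          kidera = kidera_factors(),
                          weighting = "clonotype") {
  rows <- lapply(reps, function(r) {
    s <- summary.repertoire(r, weighting = weighting,
                            diversity_depth = diversity_depth, seed = seed)
    kf <- kidera_profile(r, table = kidera, weighting = weighting)
    cbind(data.frame(sample_id = r$sample_id, subset = r$subset,
                     age_group = r$age_group, stringsAsFactors = FALSE),
          as.data.frame(t(c(s, kf))))
  })
  do.call(rbind, rows)
}

#' Z-scored feature PCA and hierarchical clustering
#'
#' Each feature column is z-score standardized across samples (mean 0,
#' sd 1, n-1 denominator); constant columns are dropped with a report.
#' PCA runs on the z-scored table by singular value decomposition with
#' the same sign convention as [classical_mds()]; hierarchical
#' clustering uses Euclidean distances between z-scored rows.
#'
#' @param t A feature data.frame from [feature_table()] (non-numeric
#'   metadata columns are ignored) or a numeric matrix.
#' @param k Number of principal components (default 2).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List: `zscores` matrix, `scores` (n x k), `explained_variance`
#'   (all components), `dropped` (constant columns), `hclust` (whose
#'   `$merge` is the nested merge list).
#' @export
feature_multivariate <- function(t, k = 2, linkage = "average") {
  if (is.data.frame(t)) {
    ids <- if ("sample_id" %in% names(t)) t$sample_id else rownames(t)
    t <- as.matrix(t[vapply(t, is.numeric, logical(1))])
    rownames(t) <- ids
  }
  stopifnot(nrow(t) >= 3)
  sds <- apply(t, 2, stats::sd)
  dropped <- colnames(t)[sds == 0 | is.na(sds)]
  t <- t[, sds > 0 & !is.na(sds), drop = FALSE]
  if (ncol(t) < 2) {
    stop("insufficient features: fewer than 2 non-constant columns",
         call. = FALSE)
  }
  z <- scale(t)
  sv <- svd(z)
  ev <- sv$d^2 / (nrow(z) - 1)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  kk <- min(k, ncol(scores))
  scores <- scores[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(z), paste0("PC", seq_len(kk)))
  hc <- stats::hclust(stats::dist(z), method = linkage)
  list(zscores = z[, ], scores = scores, explained_variance = ev,
       dropped = dropped, hclust = hc)
}
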