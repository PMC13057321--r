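# Nonparametric group comparison of repertoire features:
# Kruskal-Wallis (tie-corrected), Benjamini-Hochberg FDR across
# features, and the Dunn post-hoc test on joint mid-ranks.

.check_groups <- function(groups) {
  if (length(groups) < 2 || any(!vapply(groups, length, integer(1)))) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (sum(lengths(groups)) < 3) {
    stop("need at least 3 observations in total", call. = FALSE)
  }
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#' When every observation is identical the statistic is 0 and p = 1.
#'
#' @param groups List of numeric vectors, one per group.
#' @return Named vector `c(H, p)`.
#' @export
kruskal_wallis <- function(groups) {
  .check_groups(groups)
  x <- unlist(groups)
  if (length(unique(x)) == 1L) return(c(H = 0, p = 1))
  g <- factor(rep.int(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn post-hoc test
#'
#' Pairwise z statistics on joint mid-ranks,
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))` with
#' the tie term `T = sum(t^3 - t)` over tie groups, two-sided normal
#' p-values, and optional Benjamini-Hochberg adjustment over the pair
#' set.
#'
#' @param groups List of numeric vectors (named or indexed).
#' @param adjust `"bh"` (default) or `"none"`.
#' @return data.frame per pair: `group_i`, `group_j`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  .check_groups(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  x <- unlist(groups)
  g <- rep.int(seq_along(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)                      # mid-ranks
  tie <- table(rk)
  T_term <- sum(tie^3 - tie)
  var_core <- N * (N + 1) / 12 - T_term / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  n_i <- lengths(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(var_core * (1 / n_i[pr[1]] + 1 / n_i[pr[2]]))
  })
  z[is.nan(z)] <- 0                  # all observations tied
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(group_i = nm[pairs[1, ]], group_j = nm[pairs[2, ]],
                    z = as.numeric(z), p = p, stringsAsFactors = FALSE)
  out$p_adj <- if (adjust == "bh") bh_fdr(out$p) else out$p
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p_(k) -> min_{j >= k} min(1, p_(j) m / j)`
#' (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare repertoire features across groups
#'
#' Runs the Kruskal-Wallis test per feature column, adjusts the KW
#' p-values across features by Benjamini-Hochberg (the FDR family is
#' the feature set), and attaches a Dunn post-hoc table per feature
#' (BH-adjusted within its own pair set).
#'
#' @param t Feature data.frame (e.g. from [feature_table()]).
#' @param group_col Name of the grouping column (default `"age_group"`).
#' @param features Feature column names; defaults to all numeric
#'   columns.
#' @param fdr `"BH"` (default) or `"BY"`.
#' @return data.frame per feature: `feature`, `kw_H`, `kw_p`,
#'   `kw_p_adj`; attribute `"dunn"` is a named list of Dunn tables.
#' @export
compare_groups <- function(t, group_col = "age_group", features = NULL,
                           fdr = c("BH", "BY")) {
  fdr <- match.arg(fdr)
  if (is.null(features)) {
    features <- names(t)[vapply(t, is.numeric, logical(1))]
  }
  grp <- t[[group_col]]
  res <- do.call(rbind, lapply(features, function(f) {
    groups <- split(t[[f]], grp)
    groups <- lapply(groups, function(x) x[!is.na(x)])
    kw <- kruskal_wallis(groups)
    data.frame(feature = f, kw_H = kw["H"], kw_p = kw["p"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  res$kw_p_adj <- stats::p.adjust(res$kw_p, method = fdr)
  dunn <- lapply(stats::setNames(features, features), function(f) {
    groups <- split(t[[f]], grp)
    dunn_posthoc(lapply(groups, function(x) x[!is.na(x)]))
  })
  structure(res, dunn = dunn)
}
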