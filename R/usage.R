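# TRBV usage profiles (functional vs non-functional partitions),
# family-level germline CDR2 strength, and depletion analysis.

#' V-segment usage profile
#'
#' Normalized usage fractions over the selected functionality partition,
#' at gene or family level, weighted by unique clonotype or by UMIs.
#'
#' @param r A [repertoire].
#' @param level `"gene"` or `"family"`.
#' @param weighting `"umi"` (default) or `"clonotype"`.
#' @param partition `"functional"`, `"nonfunctional"` or `"all"`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
v_usage <- function(r, level = c("family", "gene"),
                    weighting = c("umi", "clonotype"),
                    partition = c("functional", "nonfunctional", "all")) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  partition <- match.arg(partition)
  cl <- filter_functional(r, partition)$clonotypes
  key <- normalize_gene_name(cl$v_gene, level)
  w <- if (weighting == "umi") cl$umi_count else rep(1, nrow(cl))
  out <- tapply(w, key, sum)
  out <- out / sum(out)
  stats::setNames(as.numeric(out), names(out))
}

#' Germline CDR2 binding strength per V family
#'
#' Per family, the unweighted mean over member genes (present in the
#' library with CDR2 data) of the strongly-binding-residue count (or
#' fraction) of the germline CDR2. Families without any CDR2 data are
#' excluded and reported via the `"excluded"` attribute. The ascending
#' order of the result is the conventional sort order for usage plots.
#'
#' @param library A `segment_library`.
#' @param cfg A [strength_config()].
#' @return Named numeric vector, one value per family, ascending.
#' @export
family_cdr2_strength <- function(library, cfg = strength_config()) {
  v <- library$v
  ok <- !is.na(v$cdr2_aa)
  excluded <- setdiff(unique(v$family), unique(v$family[ok]))
  v <- v[ok, , drop = FALSE]
  if (!nrow(v)) stop("no V entry with CDR2 data", call. = FALSE)
  s <- .window_strength(v$cdr2_aa, cfg)
  out <- tapply(s, v$family, mean)
  out <- sort(stats::setNames(as.numeric(out), names(out)))
  attr(out, "excluded") <- excluded
  out
}

#' Depletion analysis: remove V families and rescore CDR2 strength
#'
#' Removes every clonotype whose V family belongs to
#' `families_to_remove`, renormalizes, and recomputes the repertoire
#' CDR2 strength score. With group labels the between-group spread
#' (difference of group means) is reported before and after depletion:
#' if a cohort contrast is driven by the removed families it collapses
#' toward zero. Fully depleted repertoires are flagged and excluded from
#' the spread statistic.
#'
#' @param reps List of [repertoire] objects.
#' @param families_to_remove Character vector of family names (possibly
#'   empty, which is the identity).
#' @param cfg A [strength_config()].
#' @param library A `segment_library` with CDR2 data.
#' @param groups Optional vector of group labels aligned with `reps`.
#' @return data.frame per sample: `sample_id`, `group`, `before`,
#'   `after`, `fully_depleted`; attribute `"spread"` with the
#'   between-group mean difference before/after when `groups` is given.
#' @export
deplete_and_rescore <- function(reps, families_to_remove,
                                cfg = strength_config(), library,
                                groups = NULL) {
  known <- unique(library$v$family)
  bad <- setdiff(families_to_remove, known)
  if (length(bad)) {
    stop("unknown V family: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    before <- as.numeric(strength_score(r, cfg, "CDR2", library))
    fam <- normalize_gene_name(r$clonotypes$v_gene, "family")
    keep <- !(fam %in% families_to_remove)
    if (!any(keep)) {
      return(data.frame(sample_id = r$sample_id, before = before,
                        after = NA_real_, fully_depleted = TRUE,
                        stringsAsFactors = FALSE))
    }
    r$clonotypes <- r$clonotypes[keep, , drop = FALSE]
    data.frame(sample_id = r$sample_id, before = before,
               after = as.numeric(strength_score(r, cfg, "CDR2", library)),
               fully_depleted = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- if (is.null(groups)) NA_character_ else as.character(groups)
  out <- out[, c("sample_id", "group", "before", "after",
                 "fully_depleted")]
  if (!is.null(groups)) {
    ok <- !out$fully_depleted
    gs <- unique(out$group[ok])
    if (length(gs) == 2) {
      spread <- function(x) {
        mean(x[ok & out$group == gs[1]]) - mean(x[ok & out$group == gs[2]])
      }
      attr(out, "spread") <- c(before = spread(out$before),
                               after = spread(out$after))
    }
  }
  out
}
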