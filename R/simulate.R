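# V(D)J rearrangement simulator. All draws run under a locally seeded
# RNG (global .Random.seed is saved and restored), so calls are
# reproducible and leave no global state behind.

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# truncated geometric on 0..M: P(k) = q^k (1-q) / (1 - q^(M+1))
.tgeom_pmf <- function(k, q, M) {
  ifelse(k >= 0 & k <= M, q^k * (1 - q) / (1 - q^(M + 1)), 0)
}

# vectorized inverse-CDF sampler with per-draw cap M
.tgeom_sample <- function(n, q, M) {
  u <- stats::runif(n)
  k <- ceiling(log(1 - u * (1 - q^(M + 1))) / log(q)) - 1
  pmin(pmax(as.integer(k), 0L), M)
}

# zero-inflated shifted-geometric insert run lengths
.ins_len_sample <- function(n, pi0, p) {
  ifelse(stats::runif(n) < pi0, 0L, stats::rgeom(n, p) + 1L)
}

# draw `sum(len)` bases from nt_comp and glue them into per-draw runs
.ins_strings <- function(len, comp) {
  tot <- sum(len)
  if (tot == 0L) return(rep("", length(len)))
  bases <- sample(names(comp), tot, replace = TRUE, prob = comp)
  grp <- factor(rep.int(seq_along(len), len), levels = seq_along(len))
  vapply(split(bases, grp), paste, character(1), collapse = "")
}

#' Simulate raw V(D)J rearrangement scenarios
#'
#' Draws `n` independent rearrangements from the generative model and
#' returns the full scenario table (segments, per-end deletions, insert
#' runs and the assembled CDR3 nucleotide sequence). V-end deletions are
#' capped so the conserved Cys codon survives, J deletions so the Phe
#' anchor codon survives; D may be fully trimmed away. Deterministic
#' given `seed`.
#'
#' @param model A `generative_model`.
#' @param n Number of rearrangements (>= 1).
#' @param seed Integer seed.
#' @return data.frame with one row per rearrangement: `v_name`,
#'   `d_name`, `j_name`, `del_v`, `del_d5`, `del_d3`, `del_j`, `ins_vd`,
#'   `ins_dj`, `d_skipped`, `cdr3_nt`.
#' @export
simulate_rearrangements <- function(model, n, seed) {
  stopifnot(inherits(model, "generative_model"), n >= 1)
  lib <- model$library
  .with_seed(seed, {
    iv <- sample.int(nrow(lib$v), n, replace = TRUE, prob = model$v_weights)
    id <- sample.int(nrow(lib$d), n, replace = TRUE, prob = model$d_weights)
    ij <- sample.int(nrow(lib$j), n, replace = TRUE, prob = model$j_weights)
    skip <- stats::runif(n) < model$d_skip_prob

    v3 <- lib$v$nt_3prime[iv]
    Mv <- pmin(model$max_deletion, nchar(v3) - 3L)
    del_v <- .tgeom_sample(n, model$q, Mv)
    v_part <- substr(v3, 1L, nchar(v3) - del_v)

    dn <- lib$d$nt[id]
    M5 <- pmin(model$max_deletion, nchar(dn))
    del_d5 <- .tgeom_sample(n, model$q, M5)
    M3 <- pmin(model$max_deletion, nchar(dn) - del_d5)
    del_d3 <- .tgeom_sample(n, model$q, M3)
    d_part <- substring(dn, del_d5 + 1L, nchar(dn) - del_d3)

    jn <- lib$j$nt[ij]
    anchor <- lib$j$anchor_offset[ij]
    Mj <- pmin(model$max_deletion, anchor)
    del_j <- .tgeom_sample(n, model$q, Mj)
    j_part <- substring(jn, del_j + 1L, anchor + 3L)

    l1 <- .ins_len_sample(n, model$pi0, model$ins_p)
    l2 <- .ins_len_sample(n, model$pi0, model$ins_p)
    l2[skip] <- 0L
    ins_vd <- .ins_strings(l1, model$nt_comp)
    ins_dj <- .ins_strings(l2, model$nt_comp)

    d_part[skip] <- ""
    data.frame(
      v_name = lib$v$name[iv],
      d_name = ifelse(skip, NA_character_, lib$d$name[id]),
      j_name = lib$j$name[ij],
      del_v = del_v,
      del_d5 = ifelse(skip, NA_integer_, del_d5),
      del_d3 = ifelse(skip, NA_integer_, del_d3),
      del_j = del_j,
      ins_vd = ins_vd, ins_dj = ins_dj, d_skipped = skip,
      cdr3_nt = paste0(v_part, ins_vd, d_part, ins_dj, j_part),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a UMI-counted repertoire
#'
#' Draws `n_rearrangements` scenarios, assigns each a log-normal clone
#' weight (sd `clone_size_sigma`), samples `n_umis` UMIs multinomially
#' over the normalized weights, drops clones that received no UMI, and
#' collapses identical (V gene, CDR3nt, J gene) keys. Insert lengths are
#' recorded from the generating scenario (the first scenario seen for a
#' collapsed key). Deterministic given `seed`.
#'
#' @param model A `generative_model`.
#' @param n_rearrangements Number of independent rearrangement draws.
#' @param n_umis Total UMIs to distribute.
#' @param seed Integer seed.
#' @param sample_id,subset,age_group Repertoire metadata.
#' @return A [repertoire]; `sum(umi_count)` equals `n_umis`.
#' @export
simulate_repertoire <- function(model, n_rearrangements, n_umis, seed,
                                sample_id = paste0("sim", seed),
                                subset = NA_character_,
                                age_group = NA_character_) {
  stopifnot(n_rearrangements >= 1, n_umis >= 1)
  re <- simulate_rearrangements(model, n_rearrangements, seed)
  cnt <- .with_seed(seed + 1L, {
    w <- stats::rlnorm(n_rearrangements, 0, model$clone_size_sigma)
    as.vector(stats::rmultinom(1, n_umis, w / sum(w)))
  })
  keep <- cnt > 0L
  re <- re[keep, , drop = FALSE]
  repertoire(
    data.frame(cdr3_nt = re$cdr3_nt, v_gene = re$v_name,
               d_gene = re$d_name, j_gene = re$j_name,
               umi_count = cnt[keep],
               vd_insert_len = nchar(re$ins_vd),
               dj_insert_len = nchar(re$ins_dj),
               stringsAsFactors = FALSE),
    sample_id = sample_id, subset = subset, age_group = age_group)
}

#' Simulate repertoires from a generative model
#'
#' [stats::simulate()] method: returns a list of `nsim` repertoires with
#' seeds `seed`, `seed + 1`, ...
#'
#' @param object A `generative_model`.
#' @param nsim Number of repertoires.
#' @param seed Base integer seed.
#' @param n_rearrangements,n_umis Sizes passed to
#'   [simulate_repertoire()].
#' @param ... Further arguments passed to [simulate_repertoire()].
#' @return List of [repertoire] objects.
#' @export
simulate.generative_model <- function(object, nsim = 1, seed = 1,
                                      n_rearrangements = 3000,
                                      n_umis = 5000, ...) {
  lapply(seq_len(nsim) - 1L, function(i)
    simulate_repertoire(object, n_rearrangements, n_umis,
                        seed = seed + 17L * i, ...))
}
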