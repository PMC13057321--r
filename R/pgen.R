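# Exact in-model generation probability: the probability that the
# recombination model emits a given CDR3 nucleotide sequence, summed
# over every (V, D, J, deletions, insertions) scenario consistent with
# it. Computed by enumerating junction split points with scenario
# probabilities aggregated by the realized sequence fragments.

# candidate trimmed fragments with probabilities, aggregated by string
.trim_table <- function(seqs, probs, q, M_each, side) {
  out_str <- character(0); out_p <- numeric(0)
  for (i in seq_along(seqs)) {
    M <- M_each[i]
    for (k in 0:M) {
      frag <- switch(side,
        right = substr(seqs[i], 1L, nchar(seqs[i]) - k),  # V: trim 3' end
        left  = substring(seqs[i], k + 1L))               # J: trim 5' end
      out_str <- c(out_str, frag)
      out_p <- c(out_p, probs[i] * .tgeom_pmf(k, q, M))
    }
  }
  list(str = out_str, p = out_p)
}

# every (del5, del3) trimming of each D, probability aggregated by the
# surviving substring (periodic D sequences make distinct trims collide)
.d_table <- function(dn, dp, q, maxdel) {
  str <- character(0); p <- numeric(0)
  for (i in seq_along(dn)) {
    len <- nchar(dn[i])
    M5 <- min(maxdel, len)
    for (d5 in 0:M5) {
      M3 <- min(maxdel, len - d5)
      for (d3 in 0:M3) {
        str <- c(str, substring(dn[i], d5 + 1L, len - d3))
        p <- c(p, dp[i] * .tgeom_pmf(d5, q, M5) * .tgeom_pmf(d3, q, M3))
      }
    }
  }
  agg <- tapply(p, str, sum)
  list(str = names(agg), p = as.numeric(agg))
}

# probability of one non-template insert run realizing string s
.run_prob <- function(s, pi0, p, comp) {
  L <- nchar(s)
  len_p <- if (L == 0L) pi0 else (1 - pi0) * p * (1 - p)^(L - 1)
  if (L == 0L) return(len_p)
  len_p * prod(comp[strsplit(s, "", fixed = TRUE)[[1]]])
}

#' Generation probability of a CDR3 nucleotide sequence
#'
#' Sums the scenario probabilities of all recombination scenarios under
#' the model that assemble exactly `cdr3_nt`: every V 3'-trim that is a
#' prefix, every J 5'-trim that is a suffix, every D trim placed at
#' every consistent offset in between (plus D-less scenarios when the
#' model allows them), with the two junction gaps scored as non-template
#' insert runs. Returns 0 when no scenario exists; the result is a
#' probability in [0, 1].
#'
#' @param model A `generative_model`.
#' @param cdr3_nt Character vector of CDR3 nucleotide sequences (A/C/G/T).
#' @param library Segment library; defaults to the model's own.
#' @return Numeric vector of generation probabilities.
#' @examples
#' lib <- synthetic_segment_library(toy = TRUE)
#' m <- generative_model(lib, pi0 = 1, max_deletion = 0)
#' pgen_nt(m, "TGTGCCAGTGGGACAGGGGGCAATGAGCAGTTCTTC")
#' @export
pgen_nt <- function(model, cdr3_nt, library = model$library) {
  stopifnot(inherits(model, "generative_model"))
  if (any(!nzchar(cdr3_nt)) || any(grepl("[^ACGT]", cdr3_nt))) {
    stop("cdr3_nt must be non-empty A/C/G/T", call. = FALSE)
  }
  vt <- .trim_table(library$v$nt_3prime, model$v_weights, model$q,
                    pmin(model$max_deletion, nchar(library$v$nt_3prime) - 3L),
                    side = "right")
  j_cdr3 <- substr(library$j$nt, 1L, library$j$anchor_offset + 3L)
  jt <- .trim_table(j_cdr3, model$j_weights, model$q,
                    pmin(model$max_deletion, library$j$anchor_offset),
                    side = "left")
  dt <- .d_table(library$d$nt, model$d_weights, model$q, model$max_deletion)
  vapply(cdr3_nt, .pgen_one, numeric(1), model = model,
         vt = vt, jt = jt, dt = dt, USE.NAMES = FALSE)
}

.pgen_one <- function(s, model, vt, jt, dt) {
  n <- nchar(s)
  pi0 <- model$pi0; insp <- model$ins_p; comp <- model$nt_comp
  pskip <- model$d_skip_prob
  total <- 0
  for (a_i in seq_along(vt$str)) {
    vp <- vt$str[a_i]
    a <- nchar(vp)
    if (a > n || substr(s, 1L, a) != vp) next
    for (b_i in seq_along(jt$str)) {
      jp <- jt$str[b_i]
      b <- n - nchar(jp)
      if (b < a || substring(s, b + 1L) != jp) next
      mid <- substr(s, a + 1L, b)
      base_p <- vt$p[a_i] * jt$p[b_i]
      # D present: mid = ins_vd + d_fragment + ins_dj
      if (pskip < 1) {
        for (d_i in seq_along(dt$str)) {
          dp_str <- dt$str[d_i]
          dl <- nchar(dp_str)
          if (dl > nchar(mid)) next
          for (off in 0:(nchar(mid) - dl)) {
            if (dl > 0L && substr(mid, off + 1L, off + dl) != dp_str) next
            total <- total + base_p * (1 - pskip) * dt$p[d_i] *
              .run_prob(substr(mid, 1L, off), pi0, insp, comp) *
              .run_prob(substring(mid, off + dl + 1L), pi0, insp, comp)
          }
        }
      }
      # D skipped: mid is a single insert run
      if (pskip > 0) {
        total <- total + base_p * pskip *
          .run_prob(mid, pi0, insp, comp)
      }
    }
  }
  total
}
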