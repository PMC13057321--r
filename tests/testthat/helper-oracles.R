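# Independent oracles. These re-derive expected values by naive
# enumeration or textbook formulas, sharing no code path with the
# package internals they check.

.o_tgeom <- function(k, q, M) q^k * (1 - q) / (1 - q^(M + 1))

.o_runlen <- function(L, pi0, p) {
  if (L == 0) pi0 else (1 - pi0) * p * (1 - p)^(L - 1)
}

.o_strprob <- function(s, comp) {
  if (!nzchar(s)) return(1)
  prod(comp[strsplit(s, "", fixed = TRUE)[[1]]])
}

# Brute-force generation probability: iterate every scenario tuple and
# carve the target sequence by the implied length composition; no
# prefix/suffix search, no fragment aggregation.
pgen_oracle <- function(model, s) {
  lib <- model$library
  n <- nchar(s)
  total <- 0
  for (vi in seq_len(nrow(lib$v))) {
    v3 <- lib$v$nt_3prime[vi]
    Mv <- min(model$max_deletion, nchar(v3) - 3)
    for (del_v in 0:Mv) {
      a <- nchar(v3) - del_v
      if (a > n || substr(s, 1, a) != substr(v3, 1, a)) next
      p_v <- model$v_weights[vi] * .o_tgeom(del_v, model$q, Mv)
      for (ji in seq_len(nrow(lib$j))) {
        jn <- lib$j$nt[ji]
        anc <- lib$j$anchor_offset[ji]
        Mj <- min(model$max_deletion, anc)
        for (del_j in 0:Mj) {
          cpart <- substr(jn, del_j + 1, anc + 3)
          cc <- nchar(cpart)
          if (a + cc > n || substring(s, n - cc + 1) != cpart) next
          p_vj <- p_v * model$j_weights[ji] *
            .o_tgeom(del_j, model$q, Mj)
          rem_all <- n - a - cc
          # D-present scenarios
          if (model$d_skip_prob < 1) {
            for (di in seq_len(nrow(lib$d))) {
              dn <- lib$d$nt[di]
              M5 <- min(model$max_deletion, nchar(dn))
              for (d5 in 0:M5) {
                M3 <- min(model$max_deletion, nchar(dn) - d5)
                for (d3 in 0:M3) {
                  dpart <- substr(dn, d5 + 1, nchar(dn) - d3)
                  dl <- nchar(dpart)
                  rem <- rem_all - dl
                  if (rem < 0) next
                  p_d <- model$d_weights[di] *
                    .o_tgeom(d5, model$q, M5) *
                    .o_tgeom(d3, model$q, M3)
                  for (l1 in 0:rem) {
                    if (dl > 0 &&
                        substr(s, a + l1 + 1, a + l1 + dl) != dpart) next
                    ins1 <- substr(s, a + 1, a + l1)
                    ins2 <- substr(s, a + l1 + dl + 1, n - cc)
                    total <- total + p_vj * (1 - model$d_skip_prob) *
                      p_d *
                      .o_runlen(l1, model$pi0, model$ins_p) *
                      .o_strprob(ins1, model$nt_comp) *
                      .o_runlen(rem - l1, model$pi0, model$ins_p) *
                      .o_strprob(ins2, model$nt_comp)
                  }
                }
              }
            }
          }
          # D-less scenario: one insert run spans the junction
          if (model$d_skip_prob > 0) {
            mid <- substr(s, a + 1, n - cc)
            total <- total + p_vj * model$d_skip_prob *
              .o_runlen(rem_all, model$pi0, model$ins_p) *
              .o_strprob(mid, model$nt_comp)
          }
        }
      }
    }
  }
  unname(total)
}

# All generable sequences (and probabilities) of a zero-insertion
# model, by direct scenario enumeration.
enumerate_sequences <- function(model) {
  stopifnot(model$pi0 == 1, model$d_skip_prob == 0)
  lib <- model$library
  out <- new.env()
  add <- function(s, p) {
    assign(s, p + (if (exists(s, out)) get(s, out) else 0), out)
  }
  for (vi in seq_len(nrow(lib$v))) {
    v3 <- lib$v$nt_3prime[vi]
    Mv <- min(model$max_deletion, nchar(v3) - 3)
    for (del_v in 0:Mv) {
      vp <- substr(v3, 1, nchar(v3) - del_v)
      p_v <- model$v_weights[vi] * .o_tgeom(del_v, model$q, Mv)
      for (di in seq_len(nrow(lib$d))) {
        dn <- lib$d$nt[di]
        M5 <- min(model$max_deletion, nchar(dn))
        for (d5 in 0:M5) {
          M3 <- min(model$max_deletion, nchar(dn) - d5)
          for (d3 in 0:M3) {
            dp <- substr(dn, d5 + 1, nchar(dn) - d3)
            p_vd <- p_v * model$d_weights[di] *
              .o_tgeom(d5, model$q, M5) * .o_tgeom(d3, model$q, M3)
            for (ji in seq_len(nrow(lib$j))) {
              jn <- lib$j$nt[ji]
              anc <- lib$j$anchor_offset[ji]
              Mj <- min(model$max_deletion, anc)
              for (del_j in 0:Mj) {
                jp <- substr(jn, del_j + 1, anc + 3)
                add(paste0(vp, dp, jp),
                    p_vd * model$j_weights[ji] *
                      .o_tgeom(del_j, model$q, Mj))
              }
            }
          }
        }
      }
    }
  }
  seqs <- ls(out)
  data.frame(cdr3_nt = seqs,
             prob = vapply(seqs, get, numeric(1), envir = out),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Textbook Kruskal-Wallis with tie correction, from scratch.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep.int(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(lengths(groups) * Rbar^2) - 3 * (N + 1)
  tie <- table(x)
  H <- H / (1 - sum(tie^3 - tie) / (N^3 - N))
  p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  c(H = unname(H), p = unname(p))
}

# Dunn z/p by explicit loops, with mid-ranks computed by sorting runs
# rather than rank().
dunn_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep.int(seq_along(groups), lengths(groups))
  N <- length(x)
  ord <- order(x)
  r <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  tie <- table(x)
  core <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  out <- NULL
  for (a in seq_len(length(groups) - 1)) {
    for (b in (a + 1):length(groups)) {
      z <- (mean(r[g == a]) - mean(r[g == b])) /
        sqrt(core * (1 / sum(g == a) + 1 / sum(g == b)))
      out <- rbind(out, data.frame(
        i = a, j = b, z = z, p = 2 * stats::pnorm(-abs(z))))
    }
  }
  out
}
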