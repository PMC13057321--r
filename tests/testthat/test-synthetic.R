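test_that("preset models order TdT activity and validate overrides", {
  lib <- synthetic_segment_library()
  pre <- build_preset_model(lib, "preterm_like")
  ter <- build_preset_model(lib, "term_like")
  adu <- build_preset_model(lib, "adult_like")
  expect_gt(pre$pi0, ter$pi0)
  expect_gt(ter$pi0, adu$pi0)
  m <- build_preset_model(lib, "preterm_like", overrides = list(pi0 = 1))
  expect_equal(m$pi0, 1)
  expect_error(build_preset_model(lib, "preterm_like",
                                  overrides = list(pi0 = 1.5)),
               "parameter out of range")
  expect_error(build_preset_model(lib, "adult_like",
                                  overrides = list(q = 0)),
               "parameter out of range")
  expect_error(build_preset_model(lib, "adult_like",
                                  overrides = list(bogus = 1)),
               "unknown model parameter")
})

test_that("model serialization round-trips through YAML", {
  lib <- synthetic_segment_library(toy = TRUE)
  m <- build_preset_model(lib, "term_like",
                          overrides = list(d_skip_prob = 0.1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  m2 <- read_model(path)
  for (f in c("v_weights", "j_weights", "q", "max_deletion", "pi0",
              "ins_p", "nt_comp", "clone_size_sigma", "d_skip_prob")) {
    expect_equal(m2[[f]], m[[f]], info = f)
  }
  expect_equal(m2$library$v$nt_3prime, m$library$v$nt_3prime)
})

test_that("simulated repertoires conserve UMIs and are seed-deterministic", {
  lib <- synthetic_segment_library()
  m <- build_preset_model(lib, "term_like")
  r1 <- simulate_repertoire(m, 500, 1200, seed = 7)
  r2 <- simulate_repertoire(m, 500, 1200, seed = 7)
  expect_identical(r1, r2)
  expect_equal(total_umis(r1), 1200)
  r3 <- simulate_repertoire(m, 500, 1200, seed = 8)
  expect_false(identical(r1$clonotypes, r3$clonotypes))
})

test_that("pi0 = 1 forces zero insertions everywhere", {
  lib <- synthetic_segment_library()
  m <- build_preset_model(lib, "preterm_like", overrides = list(pi0 = 1))
  r <- simulate_repertoire(m, 400, 1000, seed = 3)
  expect_true(all(r$clonotypes$vd_insert_len == 0))
  expect_true(all(r$clonotypes$dj_insert_len == 0))
  expect_equal(unname(summary_features(r)["zero_insert_freq"]), 1)
})

test_that("simulated CDR3 assembly matches its scenario parts", {
  lib <- synthetic_segment_library()
  m <- build_preset_model(lib, "term_like",
                          overrides = list(d_skip_prob = 0.2))
  re <- simulate_rearrangements(m, 300, seed = 11)
  v3 <- lib$v$nt_3prime[match(re$v_name, lib$v$name)]
  vp <- substr(v3, 1, nchar(v3) - re$del_v)
  jn <- lib$j$nt[match(re$j_name, lib$j$name)]
  anc <- lib$j$anchor_offset[match(re$j_name, lib$j$name)]
  jp <- substring(jn, re$del_j + 1, anc + 3)
  dn <- lib$d$nt[match(re$d_name, lib$d$name)]
  dp <- ifelse(re$d_skipped, "",
               substring(dn, re$del_d5 + 1, nchar(dn) - re$del_d3))
  expect_equal(re$cdr3_nt, paste0(vp, re$ins_vd, dp, re$ins_dj, jp))
  expect_true(all(re$ins_dj[re$d_skipped] == ""))
})

test_that("forced toy model gives pgen 1 for its unique product, 0 otherwise", {
  m <- generative_model(lib_forced(), pi0 = 1, max_deletion = 0)
  expect_equal(pgen_nt(m, "TGTGCCGGGTTT"), 1.0)
  expect_equal(pgen_nt(m, "TGTGCCAAATTT"), 0.0)
  expect_error(pgen_nt(m, "TGTGCCNNNTTT"), "A/C/G/T")
})

test_that("pgen matches brute-force scenario enumeration", {
  m <- generative_model(lib_small(), pi0 = 0.5, max_deletion = 2,
                        ins_p = 0.5, q = 0.3)
  seqs <- unique(simulate_rearrangements(m, 60, seed = 5)$cdr3_nt)
  got <- pgen_nt(m, seqs)
  want <- vapply(seqs, function(s) pgen_oracle(m, s), numeric(1),
                 USE.NAMES = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got > 0 & got <= 1))

  # also with D-less scenarios enabled
  m2 <- generative_model(lib_small(), pi0 = 0.4, max_deletion = 2,
                         ins_p = 0.5, q = 0.3, d_skip_prob = 0.25)
  seqs2 <- unique(simulate_rearrangements(m2, 40, seed = 6)$cdr3_nt)
  expect_equal(pgen_nt(m2, seqs2),
               vapply(seqs2, function(s) pgen_oracle(m2, s), numeric(1),
                      USE.NAMES = FALSE),
               tolerance = 1e-12)
})

test_that("pgen sums to 1 over the sequences of an enumerable model", {
  m <- generative_model(lib_small(), pi0 = 1, max_deletion = 2, q = 0.3)
  enum <- enumerate_sequences(m)
  expect_equal(sum(enum$prob), 1, tolerance = 1e-9)
  expect_equal(sum(pgen_nt(m, enum$cdr3_nt)), 1, tolerance = 1e-9)
  expect_equal(pgen_nt(m, enum$cdr3_nt), enum$prob, tolerance = 1e-12)
})

test_that("empirical sequence frequencies agree with pgen", {
  m <- generative_model(lib_small(), pi0 = 0.6, max_deletion = 1,
                        ins_p = 0.5, q = 0.3)
  n <- 30000
  re <- simulate_rearrangements(m, n, seed = 21)
  tab <- sort(table(re$cdr3_nt), decreasing = TRUE)[1:10]
  pg <- pgen_nt(m, names(tab))
  # 99% binomial CI around the model probability
  for (i in seq_along(tab)) {
    se <- sqrt(pg[i] * (1 - pg[i]) / n)
    expect_lt(abs(tab[i] / n - pg[i]), 2.576 * se + 1e-12)
  }
})

test_that("mean CDR3 length decreases with the zero-insertion probability", {
  lib <- synthetic_segment_library()
  mean_len <- vapply(c(1.0, 0.5, 0.1), function(p0) {
    m <- build_preset_model(lib, "term_like", overrides = list(pi0 = p0))
    mean(nchar(simulate_rearrangements(m, 10000, seed = 31)$cdr3_nt))
  }, numeric(1))
  expect_true(all(diff(mean_len) > 0))
})

test_that("zero-insert rearrangement frequency recovers pi0 squared", {
  lib <- synthetic_segment_library()
  for (p0 in c(0.3, 0.7)) {
    m <- build_preset_model(lib, "term_like",
                            overrides = list(pi0 = p0, max_deletion = 0))
    re <- simulate_rearrangements(m, 10000, seed = 101)
    zf <- mean(re$ins_vd == "" & re$ins_dj == "")
    se <- sqrt(p0^2 * (1 - p0^2) / 10000)
    expect_lt(abs(zf - p0^2), 3 * se)
  }
})
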