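test_that("functionality classification follows frame and stop rules", {
  expect_equal(classify_functionality("TGTGCCAGCTTTGCAGGC"), "functional")
  expect_equal(classify_functionality(strrep("A", 41)), "out_of_frame")
  expect_equal(classify_functionality("TGTTGAAGC"), "stop_codon")
  # out-of-frame takes precedence even if a stop appears
  expect_equal(classify_functionality("TGTTGAA"), "out_of_frame")
})

test_that("non-functional fractions count clonotypes and UMIs separately", {
  r <- quick_repertoire(
    nt = c("TGTTGAAGCGCA", "TGTGCAAGCGCA", "TGTGCCAGCGCG", "TGTGCAGCGGCA"),
    counts = c(10, 5, 3, 2),
    j = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ1-1"))
  expect_equal(sum(r$clonotypes$functional != "functional"), 1)
  expect_equal(unname(nonfunctional_fractions(r)),
               c(0.25, 0.5))
  all_fun <- quick_repertoire(c("TGTGCAAGC", "TGTGCCAGC"), c(1, 1),
                              j = c("TRBJ1-1", "TRBJ1-2"))
  expect_equal(unname(nonfunctional_fractions(all_fun)), c(0, 0))
  # invariance under uniform count scaling
  r10 <- quick_repertoire(
    nt = c("TGTTGAAGCGCA", "TGTGCAAGCGCA", "TGTGCCAGCGCG", "TGTGCAGCGGCA"),
    counts = 10 * c(10, 5, 3, 2),
    j = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ1-1"))
  expect_equal(nonfunctional_fractions(r10), nonfunctional_fractions(r))
})

test_that("summary features average with the requested weighting", {
  r <- quick_repertoire(
    nt = c("TGTGCAAGCGCAGCAGCAGCAGCAGCAGCAGCAGCAGCA",  # 39 nt
           "TGTGCCAGCGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCA"),  # 45 nt
    counts = c(3, 1), j = c("TRBJ1-1", "TRBJ1-2"),
    vd = c(0, 2), dj = c(0, 3))
  sf <- summary_features(r, weighting = "clonotype")
  expect_equal(unname(sf["mean_cdr3_nt_length"]), 42)
  expect_equal(unname(sf["mean_insert_size"]), 2.5)
  expect_equal(unname(sf["zero_insert_freq"]), 0.5)
  sfu <- summary_features(r, weighting = "umi")
  expect_equal(unname(sfu["mean_insert_size"]), 1.25)
  expect_equal(unname(sfu["zero_insert_freq"]), 0.75)
  # absent insert lengths are an error, not silent zeros
  r_na <- quick_repertoire("TGTGCAAGC", 1)
  expect_error(summary_features(r_na), "undefined feature")
})

test_that("convergence is the nt/aa richness ratio over the top selection", {
  r <- quick_repertoire(nt = c("AAAGCG", "AAGGCG", "AATGCA"),
                        counts = c(5, 4, 3),
                        j = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1"))
  expect_equal(r$clonotypes$cdr3_aa[order(r$clonotypes$cdr3_nt)],
               c("KA", "KA", "NA"))
  expect_equal(convergence(r), 1.5)
  # injective nt -> aa map gives exactly 1
  r1 <- quick_repertoire(nt = c("AAAGCG", "AATGCA"), counts = c(2, 1),
                         j = c("TRBJ1-1", "TRBJ1-2"))
  expect_equal(convergence(r1), 1)
  # top_n = 2 on counts (10, 5, 1): only the two most abundant enter
  r2 <- quick_repertoire(nt = c("AAAGCG", "AAGGCG", "AATGCA"),
                         counts = c(10, 5, 1),
                         j = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1"))
  expect_equal(convergence(r2, top_n = 2), 2 / 1)
  expect_gte(convergence(r2), 1)
})

test_that("UMI downsampling is exact, seeded, and hypergeometric", {
  r <- quick_repertoire(nt = c("TGTGCAAGC", "TGTGCCAGC", "TGTGCGAGC"),
                        counts = c(50, 30, 20),
                        j = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1"))
  full <- downsample_umis(r, 100, seed = 1)
  expect_equal(full$clonotypes$umi_count, r$clonotypes$umi_count)
  d <- downsample_umis(r, 40, seed = 1)
  expect_equal(total_umis(d), 40)
  expect_identical(downsample_umis(r, 40, seed = 1), d)
  expect_error(downsample_umis(r, 101, seed = 1), "insufficient depth")

  one <- quick_repertoire("TGTGCAAGC", 100)
  expect_equal(downsample_umis(one, 7, seed = 2)$clonotypes$umi_count, 7)

  # inclusion probability of a singleton at half depth is ~ 1/2
  r2 <- quick_repertoire(nt = c("TGTGCAAGC", "TGTGCCAGC"),
                         counts = c(9999, 1),
                         j = c("TRBJ1-1", "TRBJ1-2"))
  hits <- vapply(1:200, function(s)
    nrow(downsample_umis(r2, 5000, seed = s)$clonotypes) == 2, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 2.576 * sqrt(0.25 / 200))

  # expected counts are n * f_i within 3 standard errors
  cnts <- vapply(1:200, function(s)
    downsample_umis(r, 40, seed = s)$clonotypes$umi_count[1], numeric(1))
  se <- sqrt(40 * 0.5 * 0.5 * (100 - 40) / (100 - 1)) / sqrt(200)
  expect_lt(abs(mean(cnts) - 20), 3 * se)
})

test_that("diversity indices match the entropy formula", {
  r_even <- quick_repertoire(sprintf("TGTGC%s", strrep("A", 1:10)),
                             counts = rep(2, 10))
  expect_equal(unname(diversity_indices(r_even)), c(10, 1))
  r_one <- quick_repertoire("TGTGCAAGC", 5)
  expect_equal(unname(diversity_indices(r_one)), c(1, 0))
  r_skew <- quick_repertoire(c("TGTGCAAGC", "TGTGCCAGC", "TGTGCGAGC"),
                             counts = c(2, 1, 1),
                             j = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1"))
  h <- -(0.5 * log(0.5) + 2 * 0.25 * log(0.25))
  expect_equal(unname(diversity_indices(r_skew)),
               c(3, h / log(3)), tolerance = 1e-12)
  expect_lt(diversity_indices(r_skew)["normalized_shannon"], 1)
})
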