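test_that("simple-dialect clonotype tables parse, aggregate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "cdr3_nt\tcdr3_aa\tv_gene\td_gene\tj_gene\tcount\tvd_insert\tdj_insert",
    "TGTGCCAGCTTT\tCASF\tTRBV4-1\tTRBD1\tTRBJ1-1\t10\t0\t0",
    "TGTGCCGGGTTC\tCAGF\tTRBV4-1\t\tTRBJ1-1\t5\t1\t2",
    "TGTGCCAGTTTC\tCASF\tTRBV7-2\tTRBD1\tTRBJ1-2\t1\t3\t0"), path)
  r <- read_clonotype_table(path, "simple")
  expect_s3_class(r, "repertoire")
  expect_equal(nrow(r$clonotypes), 3)
  expect_equal(total_umis(r), 16)

  # duplicate (V, nt, J) keys aggregate by summing counts
  writeLines(c(
    "cdr3_nt\tv_gene\tj_gene\tcount",
    "TGTGCCAGCTTT\tTRBV4-1\tTRBJ1-1\t4",
    "TGTGCCAGCTTT\tTRBV4-1*01\tTRBJ1-1\t6"), path)
  r2 <- read_clonotype_table(path, "simple")
  expect_equal(nrow(r2$clonotypes), 1)
  expect_equal(r2$clonotypes$umi_count, 10)

  # order independence of aggregation
  writeLines(c(
    "cdr3_nt\tv_gene\tj_gene\tcount",
    "TGTGCCAGCTTT\tTRBV4-1\tTRBJ1-1\t6",
    "TGTGCCAGCTTT\tTRBV4-1*01\tTRBJ1-1\t4"), path)
  expect_equal(read_clonotype_table(path, "simple")$clonotypes,
               r2$clonotypes)

  # round trip preserves keys, counts, inserts
  rt_path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(r, rt_path)
  rt <- read_clonotype_table(rt_path, "simple")
  expect_equal(rt$clonotypes[c("cdr3_nt", "v_gene", "j_gene", "umi_count",
                               "vd_insert_len", "dj_insert_len")],
               r$clonotypes[c("cdr3_nt", "v_gene", "j_gene", "umi_count",
                              "vd_insert_len", "dj_insert_len")])
})

test_that("format and record errors are reported with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3_nt\tv_gene\tj_gene",
               "TGTGCC\tTRBV4-1\tTRBJ1-1"), path)
  expect_error(read_clonotype_table(path, "simple"),
               "missing column: count")
  writeLines(c("cdr3_nt\tv_gene\tj_gene\tcount",
               "TGTGCC\tTRBV4-1\tTRBJ1-1\t0"), path)
  expect_error(read_clonotype_table(path, "simple"), "line 2")
})

test_that("mixcr-like dialect maps headers and derives insert lengths", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "cloneCount\tnSeqCDR3\taaSeqCDR3\tbestVHit\tbestDHit\tbestJHit\trefPoints",
    "12\tTGTGCCAGCGGGACATTT\tCASGTF\tTRBV4-1*00(933)\tTRBD1*00\tTRBJ1-1*00\t9:11:15:17",
    "3\tTGTGCCAGCAAATTT\tCASKF\tTRBV4-1\t\tTRBJ1-1\t9:::12"), path)
  r <- read_clonotype_table(path, "mixcr_like")
  cl <- r$clonotypes[order(-r$clonotypes$umi_count), ]
  expect_equal(cl$v_gene, c("TRBV4-1", "TRBV4-1"))
  expect_equal(cl$vd_insert_len, c(2, 3))  # D-less row carries full run
  expect_equal(cl$dj_insert_len, c(2, 0))
})

test_that("segment library validation enforces anchors and bounds", {
  lib <- synthetic_segment_library(toy = TRUE)
  expect_equal(nrow(lib$v), 3)
  expect_equal(length(unique(lib$v$family)), 3)
  expect_true(all(substr(lib$v$nt_3prime, 1, 3) %in% c("TGT", "TGC")))

  expect_error(segment_library(
    v = data.frame(name = "TRBV1", cdr1_aa = NA_character_,
                   cdr2_aa = NA_character_, nt_3prime = "AAAGCC"),
    d = data.frame(name = "TRBD1", nt = "GGG"),
    j = data.frame(name = "TRBJ1", nt = "TTTTTC", anchor_offset = 0L)),
    "Cys codon")
  expect_error(segment_library(
    v = data.frame(name = "TRBV1", cdr1_aa = NA_character_,
                   cdr2_aa = NA_character_, nt_3prime = "TGTGCC"),
    d = data.frame(name = "TRBD1", nt = "GGG"),
    j = data.frame(name = "TRBJ1", nt = "TTTTTC", anchor_offset = 9L)),
    "TRBJ1")
  # V entries without CDR data are kept but flagged
  lib2 <- segment_library(
    v = data.frame(name = c("TRBV1", "TRBV2"),
                   cdr1_aa = c("MGHRA", NA), cdr2_aa = c("VFLMV", NA),
                   nt_3prime = "TGTGCC"),
    d = data.frame(name = "TRBD1", nt = "GGG"),
    j = data.frame(name = "TRBJ1", nt = "TTTTTC", anchor_offset = 0L))
  expect_equal(lib2$v$cdr_usable, c(TRUE, FALSE))
})

test_that("annotation tables filter on score and MHC class", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "cdr3\tv.segm\tspecies\tmhc.class\tvdjdb.score",
    "CASSLGQAYEQYF\tTRBV7-2*01\tCMV\tMHCI\t0",
    "CASSLAPGATNEKLFF\tTRBV4-1\tEBV\tMHCI\t1",
    "CASSFGREQYF\tTRBV7-9\tCMV\tMHCI\t1",
    "CASSPDRGAYEQYF\tTRBV4-2\tHIV\tMHCII\t2",
    "CASRDRTGNGYTF\tTRBV28\tSARS-CoV-2\tMHCI\t3"), path)
  expect_equal(nrow(read_annotation_table(path, min_score = 1)), 4)
  only1 <- read_annotation_table(path, min_score = 1, mhc_class = "I")
  expect_equal(nrow(only1), 3)
  expect_true(all(only1$mhc_class == "I"))
  all5 <- read_annotation_table(path, min_score = 0)
  expect_equal(nrow(all5), 5)
  expect_equal(all5$v_gene[1], "TRBV7-2")  # allele stripped
})

test_that("gene name normalization strips alleles and families idempotently", {
  expect_equal(normalize_gene_name("TRBV12-3*01", "gene"), "TRBV12-3")
  expect_equal(normalize_gene_name("TRBV12-3*01", "family"), "TRBV12")
  expect_equal(normalize_gene_name("TRBV28", "family"), "TRBV28")
  for (lv in c("gene", "family")) {
    once <- normalize_gene_name(c("TRBV12-3*01", "TRBJ2-7", "TRBD1"), lv)
    expect_equal(normalize_gene_name(once, lv), once)
  }
  expect_error(normalize_gene_name("", "gene"), "empty")
  expect_error(normalize_gene_name("IGHV1-2", "gene"), "prefix")
})

test_that("out-of-frame CDR3s translate codon-wise with trailing marker", {
  expect_equal(translate_cdr3("TGTGCCAGC"), "CAS")
  expect_equal(translate_cdr3("TGTGCCAG"), "CA_")
  expect_equal(translate_cdr3("TGTTAAAGC"), "C*S")
  expect_error(translate_cdr3("TGTNNN"), "ACGT")
})
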