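# Variant data model and file I/O.

write_test_vcf <- function(rows, sample_col = "S1") {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_col), collapse = "\t"),
    rows), path)
  path
}

write_test_annotation <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  path
}

test_that("chromosome normalization strips prefixes, is idempotent and case-insensitive", {
  expect_equal(normalize_chrom(c("chr7", "CHR7", "Chr7", "7")),
               rep("7", 4))
  expect_equal(normalize_chrom("chrX"), "X")
  expect_equal(normalize_chrom(normalize_chrom("chrX")), "X")
})

test_that("a well-formed VCF joins its annotation table row by row", {
  vcf <- write_test_vcf(c(
    "chr7\t100\t.\tA\tG\t55.5\tPASS\t.\tGT\t0/1",
    "chr7\t200\t.\tC\tT\t80\tPASS\t.\tGT\t1/1"))
  ann <- write_test_annotation(data.frame(
    chrom = c("7", "7"), pos = c(100, 200), ref = c("A", "C"),
    alt = c("G", "T"), gene = c("GA", "GB"),
    max_af = c(0.001, NA), SIFT = c(0.9, 0.2)))
  case <- load_patient_case(vcf, ann, list(patient_id = "p1", sex = "male",
                                           keywords = "seizure"))
  expect_s3_class(case, "patient_case")
  expect_equal(nrow(case$variants), 2L)
  # prefix-normalized join carried annotation over
  expect_equal(case$variants$gene, c("GA", "GB"))
  expect_equal(case$variants$max_af, c(0.001, NA))
  expect_equal(case$variants$SIFT, c(0.9, 0.2))
  expect_equal(case$variants$quality, c(55.5, 80))
  # GT mapping
  expect_equal(case$variants$genotype, c("het", "hom"))
})

test_that("GT field maps to genotype categories including hemizygous and missing", {
  vcf <- write_test_vcf(c(
    "1\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "1\t20\t.\tA\tG\t50\tPASS\t.\tGT\t1/1",
    "X\t30\t.\tA\tG\t50\tPASS\t.\tGT\t1",
    "1\t40\t.\tA\tG\t50\tPASS\t.\tGT\t./."))
  ann <- write_test_annotation(data.frame(chrom = "1", pos = 10, ref = "A",
                                          alt = "G", gene = "GA"))
  case <- suppressWarnings(
    load_patient_case(vcf, ann, list(patient_id = "p", sex = "female")))
  expect_equal(case$variants$genotype, c("het", "hom", "hem", NA))
})

test_that("multi-allelic rows split into one record per ALT", {
  vcf <- write_test_vcf("1\t10\t.\tA\tG,T\t50\tPASS\t.\tGT\t1/2")
  ann <- write_test_annotation(data.frame(chrom = "1", pos = 10,
                                          ref = "A", alt = "G",
                                          gene = "GA"))
  case <- load_patient_case(vcf, ann, list(patient_id = "p"))
  expect_equal(nrow(case$variants), 2L)
  expect_equal(case$variants$alt, c("G", "T"))
  # each allele present once in 1/2 -> het for both
  expect_equal(case$variants$genotype, c("het", "het"))
  expect_equal(case$variants$gene, c("GA", NA))
})

test_that("prefix-normalized join matches a hand-joined five-row table", {
  vcf <- write_test_vcf(c(
    "chr7\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "chr7\t200\t.\tC\tT\t50\tPASS\t.\tGT\t0/1",
    "chrX\t300\t.\tG\tA\t50\tPASS\t.\tGT\t1",
    "chr2\t400\t.\tT\tC\t50\tPASS\t.\tGT\t1/1",
    "chr2\t500\t.\tA\tT\t50\tPASS\t.\tGT\t0/1"))
  ann <- write_test_annotation(data.frame(
    chrom = c("7", "7", "X", "2", "2"),
    pos = c(100, 200, 300, 400, 500),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "T"),
    gene = paste0("G", 1:5),
    hgmd_rank = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  case <- load_patient_case(vcf, ann, list(patient_id = "p"))
  # hand-joined expectation: annotation order equals VCF order here
  expect_equal(case$variants$gene, paste0("G", 1:5))
  expect_equal(case$variants$hgmd_rank, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(variant_key(case$variants)[3], "X:300:G:A")
})

test_that("unmatched annotation rows warn; unmatched VCF rows stay all-missing", {
  vcf <- write_test_vcf("1\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/1")
  ann <- write_test_annotation(data.frame(
    chrom = c("1", "1"), pos = c(10, 99), ref = c("A", "C"),
    alt = c("G", "T"), gene = c("GA", "GZ")))
  expect_warning(case <- load_patient_case(vcf, ann, list(patient_id = "p")),
                 "annotation row")
  expect_equal(case$variants$gene, "GA")

  ann2 <- write_test_annotation(data.frame(chrom = "1", pos = 99, ref = "C",
                                           alt = "T", gene = "GZ"))
  suppressWarnings(case2 <- load_patient_case(vcf, ann2,
                                              list(patient_id = "p")))
  expect_true(is.na(case2$variants$gene))
})

test_that("format and data errors are raised with the offending key", {
  bad_vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tINFO\tFORMAT\tS1",
               "1\t10\t.\tA\tG\t50\t.\tGT\t0/1"), bad_vcf)
  ann <- write_test_annotation(data.frame(chrom = "1", pos = 10, ref = "A",
                                          alt = "G", gene = "GA"))
  expect_error(load_patient_case(bad_vcf, ann, list(patient_id = "p")),
               "format error")

  dup_vcf <- write_test_vcf(c("1\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
                              "chr1\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/1"))
  expect_error(load_patient_case(dup_vcf, ann, list(patient_id = "p")),
               "1:10:A:G")
})

test_that("patient_case validates causative keys and variant invariants", {
  v <- mk_variant(pos = 5L)
  expect_error(patient_case("p", "male", v, causative_keys = "1:999:A:G"),
               "causative")
  bad <- mk_variant(max_af = 1.5)
  expect_error(patient_case("p", "male", bad), "max_af")
  dup <- rbind(mk_variant(), mk_variant())
  expect_error(patient_case("p", "male", dup), "duplicate")
})

test_that("ranked output round-trips exactly and validates its inputs", {
  ranked <- data.frame(
    rank = c(1L, 2L, 3L), probability = c(0.9123456789, 0.5, 0.1),
    chrom = c("1", "2", "X"), pos = c(10L, 20L, 30L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    gene = c("GA", "GB", "GC"), acmg_score = c(9, 0, -2),
    sim_max = c(1000, 500, 0), sim_min = c(10, 0, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_variants(path, ranked)
  back <- read_ranked_variants(path)
  expect_equal(back$rank, ranked$rank)
  expect_equal(back$probability, ranked$probability)
  expect_equal(back$acmg_score, ranked$acmg_score)
  expect_equal(back[c("chrom", "pos", "ref", "alt", "gene")],
               ranked[c("chrom", "pos", "ref", "alt", "gene")])

  # empty list -> header-only file
  write_ranked_variants(path, ranked[0, ])
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_ranked_variants(path)), 0L)

  bad <- ranked; bad$rank <- c(1L, 1L, 3L)
  expect_error(write_ranked_variants(path, bad), "permutation")
  bad2 <- ranked; bad2$probability[1] <- 1.2
  expect_error(write_ranked_variants(path, bad2), "\\[0,1\\]")
})

test_that("cohort write/load round trip is lossless for serialized fields", {
  inputs <- small_fit_inputs(seed = 31, n_patients = 2, n_variants = 30)
  dir <- withr::local_tempdir()
  write_cohort(dir, inputs$cases, inputs$corpora)
  back <- read_cohort(dir)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    a <- inputs$cases[[i]]; b <- back[[i]]
    expect_equal(b$patient_id, a$patient_id)
    expect_equal(b$sex, a$sex)
    expect_equal(b$keywords, a$keywords)
    expect_setequal(b$causative_keys, a$causative_keys)
    ka <- variant_key(a$variants); kb <- variant_key(b$variants)
    expect_setequal(kb, ka)
    idx <- match(ka, kb)
    expect_equal(b$variants$gene[idx], a$variants$gene)
    expect_equal(b$variants$max_af[idx], a$variants$max_af)
    expect_equal(b$variants$acmg_evidence[idx], a$variants$acmg_evidence)
    expect_equal(b$variants$SIFT[idx], a$variants$SIFT)
    expect_equal(b$variants$genotype[idx], a$variants$genotype)
  }
  # corpus JSON-lines round trip preserves term statistics
  corp_back <- read_corpus_jsonl(file.path(dir, "corpus.jsonl"))
  expect_equal(length(corp_back), length(inputs$corpora))
  expect_equal(corp_back[[1]]$N, inputs$corpora[[1]]$N)
  expect_equal(sort(names(corp_back[[1]]$tf)),
               sort(names(inputs$corpora[[1]]$tf)))
  g <- names(inputs$corpora[[1]]$tf)[1]
  expect_equal(sort(corp_back[[1]]$tf[[g]]),
               sort(inputs$corpora[[1]]$tf[[g]]))
})
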