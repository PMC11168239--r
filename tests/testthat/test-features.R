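# ACMG scoring, per-field feature rules and preprocessing.

test_that("acmg_score sums printed weights with benign evidence subtracting", {
  expect_equal(acmg_score(character()), 0)
  expect_equal(acmg_score(c("PVS1", "PM2", "PP3")), 9)
  expect_equal(acmg_score("BA1"), -9)
  expect_equal(acmg_score(c("PVS1", "BA1")), -3)
  # comma-delimited string form
  expect_equal(acmg_score("PVS1,PM2,PP3"), 9)
  # unweighted criteria are ignored silently, unknown codes warn
  expect_equal(acmg_score(c("PVS1", "PS2", "PP1")), 6)
  expect_warning(s <- acmg_score(c("PVS1", "XXX")), "unknown")
  expect_equal(s, 6)
})

test_that("acmg_score is additive over disjoint evidence sets", {
  set.seed(9)
  codes <- names(acmg_weights()$weights)
  for (i in 1:10) {
    pick <- sample(codes, 6)
    a <- pick[1:3]; b <- pick[4:6]
    expect_equal(acmg_score(c(a, b)), acmg_score(a) + acmg_score(b))
  }
})

test_that("MaxEntScan significance follows the printed rule with missing defaulting to 0", {
  expect_equal(maxentscan_significance(2.0, 0.20), 1L)
  expect_equal(maxentscan_significance(5.0, 0.20), 0L)
  expect_equal(maxentscan_significance(2.0, 0.35), 0L)
  expect_equal(maxentscan_significance(2.0, -0.20), 1L)  # |variation| rule
  expect_equal(maxentscan_significance(NA, 0.20), 0L)
  expect_equal(maxentscan_significance(2.0, NA), 0L)
})

test_that("hemizygous correction applies only to male chromosome X", {
  expect_equal(fix_hemizygous("het", "X", "male"), "hem")
  expect_equal(fix_hemizygous("het", "chrX", "male"), "hem")
  expect_equal(fix_hemizygous("het", "X", "female"), "het")
  expect_equal(fix_hemizygous("hom", "2", "male"), "hom")
  expect_equal(fix_hemizygous("het", "X", "unknown"), "het")
  expect_equal(fix_hemizygous(c("het", "hom"), c("X", "1"), "male"),
               c("hem", "hom"))
})

test_that("inheritance patterns are counted per canonical pattern", {
  counts <- inheritance_counts(c("AD", "AR", "AD"))
  expect_equal(counts[["AD"]], 2L)
  expect_equal(counts[["AR"]], 1L)
  expect_equal(sum(counts), 3L)
  expect_equal(sum(inheritance_counts(character())), 0L)
  expect_equal(inheritance_counts("AD,mitochondrial")[["mitochondrial"]], 1L)
  expect_equal(inheritance_counts("weirdtoken")[["other"]], 1L)
})

build_tiny_fm <- function() {
  corpora <- toy_corpora()
  v1 <- mk_variant(chrom = "1", pos = 10L, gene = "GA",
                   genotype = "het", func_region = "exonic",
                   exonic_func = "nonsynonymous SNV",
                   consequence = "missense_variant",
                   acmg_evidence = "PVS1,PM2", SIFT = 0.9, CADD = 0.8,
                   quality = 50, read_depth = 40, max_af = 0.001,
                   clinvar_sig = "Pathogenic", hgmd_rank = 0.9,
                   inheritance = "AD")
  v2 <- mk_variant(chrom = "X", pos = 20L, gene = "GB", genotype = "het",
                   func_region = "exonic", exonic_func = "synonymous SNV",
                   consequence = "synonymous_variant", quality = 20,
                   read_depth = 10, max_af = 0.005)
  case <- patient_case("p1", "male", rbind(v1, v2),
                       keywords = c("seizure", "ataxia"),
                       causative_keys = "1:10:A:G")
  build_feature_matrix(list(case), corpora)
}

test_that("the built matrix has the declared 94 columns and correct labels", {
  fm <- build_tiny_fm()
  expect_equal(ncol(fm$x), 94L)
  expect_equal(colnames(fm$x), feature_schema()$name)
  expect_equal(nrow(fm$x), 2L)
  expect_equal(fm$labels, c(1L, 0L))
  expect_equal(fm$x[1, "acmg_score"], 8)
  expect_equal(unname(fm$x[1, c("acmg_PVS1", "acmg_PM2", "acmg_PP3")]),
               c(1, 1, 0))
  # phenotype similarity features came from the patient's keywords
  expect_equal(fm$x[1, "sim_max"], 1000)
})

test_that("genotype one-hot is [0,1,0] for het and male chrX becomes hem", {
  fm <- build_tiny_fm()
  expect_equal(unname(fm$x[1, c("gt_hom", "gt_het", "gt_hem")]), c(0, 1, 0))
  # second variant is on X of a male patient -> hem despite het input
  expect_equal(unname(fm$x[2, c("gt_hom", "gt_het", "gt_hem")]), c(0, 0, 1))
})

test_that("one-hot blocks sum to 1 for known categories and 0 for missing", {
  fm <- build_tiny_fm()
  clin_cols <- grep("^clinvar_", colnames(fm$x))
  expect_equal(sum(fm$x[1, clin_cols]), 1)   # Pathogenic
  expect_equal(sum(fm$x[2, clin_cols]), 0)   # missing ClinVar
  vt_cols <- grep("^vt_", colnames(fm$x))
  expect_equal(unname(rowSums(fm$x[, vt_cols])), c(1, 1))
})

test_that("rows with all-missing prediction scores still build", {
  corpora <- toy_corpora()
  v <- mk_variant(gene = "GA", genotype = "hom")
  case <- patient_case("p", "female", v, keywords = "seizure")
  fm <- build_feature_matrix(list(case), corpora)
  expect_equal(nrow(fm$x), 1L)
  expect_true(all(is.na(fm$x[1, paste0("rs_", pred_score_names())])))
  fitted <- fit_transform(fm, "fit")
  expect_true(all(!is.na(fitted$x)))
})

test_that("min-max normalization follows the printed formula with clipping", {
  fm <- build_tiny_fm()
  # splice three rows with a known quality column through the machinery
  fm$x[, "quality"] <- c(2, 4)
  fitted <- fit_transform(fm, "fit")
  expect_equal(unname(fitted$x[, "quality"]), c(0, 1))
  expect_true(all(fitted$x >= 0 & fitted$x <= 1, na.rm = TRUE))

  # hand example [2,4,6] -> [0,0.5,1] via the stored state
  state <- fitted$fit_state
  state$xmin["quality"] <- 2; state$xmax["quality"] <- 6
  fm2 <- fm
  fm2$x[, "quality"] <- c(4, 6)
  out <- fit_transform(fm2, "transform", state = state)
  expect_equal(unname(out$x[, "quality"]), c(0.5, 1))

  # value above the training max clips to 1
  fm3 <- fm
  fm3$x[, "quality"] <- c(100, 2)
  out3 <- fit_transform(fm3, "transform", state = state)
  expect_equal(unname(out3$x[1, "quality"]), 1)
})

test_that("constant columns map to 0 and transform-before-fit errors", {
  fm <- build_tiny_fm()
  fm$x[, "read_depth"] <- c(7, 7)
  fitted <- fit_transform(fm, "fit")
  expect_equal(unname(fitted$x[, "read_depth"]), c(0, 0))
  expect_error(fit_transform(build_tiny_fm(), "transform"), "fit")
})

test_that("transform is deterministic and idempotent on the identity state", {
  fm <- build_tiny_fm()
  fitted <- fit_transform(fm, "fit")
  again <- fit_transform(fm, "transform", state = fitted$fit_state)
  expect_identical(again$x, fitted$x)
  # with Xmin=0, Xmax=1 and zero imputation, transforming twice = once
  id_state <- fitted$fit_state
  id_state$impute[] <- 0
  id_state$xmin[] <- 0
  id_state$xmax[] <- 1
  once <- fit_transform(fitted, "transform", state = id_state)
  twice <- fit_transform(once, "transform", state = id_state)
  expect_identical(twice$x, once$x)
})
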