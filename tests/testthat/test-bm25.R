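# Okapi BM25 / RSJ-weighted RANK scoring.

test_that("idf matches hand evaluation and decreases with document frequency", {
  cp <- build_corpus(list(A = "seizure hypotonia seizure", B = "anemia"),
                     "s1")
  expect_equal(idf("seizure", cp), log(2), tolerance = 1e-12)
  cp1 <- build_corpus(list(A = "seizure"), "s1")
  expect_equal(idf("seizure", cp1), log(4 / 3), tolerance = 1e-12)
  # absent term: n = 0, strictly larger than any present term's idf
  expect_equal(idf("absent", cp), log(6), tolerance = 1e-12)
  expect_gt(idf("absent", cp), idf("seizure", cp))
})

test_that("bm25 reproduces the two-document worked example", {
  cp <- build_corpus(list(A = c("seizure", "hypotonia", "seizure"),
                          B = "anemia"), "s1")
  # idf = ln 2, tf = 2, |D| = 3, avgdl = 2:
  # ln2 * (2 * 2.2) / (2 + 1.2 * (0.2 + 0.8 * 1.5)) = ln2 * 4.4 / 3.68
  expect_equal(bm25_score("A", make_query("seizure"), cp),
               log(2) * 4.4 / 3.68, tolerance = 1e-12)
  expect_equal(bm25_score("A", make_query("seizure"), cp), 0.8288,
               tolerance = 1e-4)
})

test_that("bm25 is zero on empty overlap and linear in duplicated keywords", {
  cp <- build_corpus(list(A = "seizure hypotonia", B = "anemia"), "s1")
  expect_equal(bm25_score("A", make_query("xyz"), cp), 0)
  expect_equal(bm25_score("B", make_query("xyz"), cp), 0)
  single <- bm25_score("A", make_query("seizure"), cp)
  double <- bm25_score("A", make_query(c("seizure", "seizure")), cp)
  expect_equal(double, 2 * single, tolerance = 1e-12)
})

test_that("rank score reduces to the documented closed forms", {
  # N=2, n=1, R=r=0: omega = ln(1.5/1.5) = 0 -> score 0
  cp <- build_corpus(list(A = "seizure hypotonia seizure", B = "anemia"),
                     "s1")
  expect_equal(rank_score("A", make_query("seizure"), cp), 0)
  # N=10, n=1, tf=1, dl=avgdl, qtf=1: score = ln(9.5/1.5)
  docs <- c(list(A = c("term", "pad", "pad")),
            lapply(1:9, function(i) c("x", "y", "z")))
  names(docs) <- c("A", paste0("B", 1:9))
  cp10 <- build_corpus(docs, "s1")
  expect_equal(rank_score("A", make_query("term"), cp10), log(9.5 / 1.5),
               tolerance = 1e-12)
})

test_that("rank score is monotone non-decreasing in query term frequency", {
  docs <- c(list(A = c("term", "pad", "pad")),
            lapply(1:9, function(i) c("x", "y", "z")))
  names(docs) <- c("A", paste0("B", 1:9))
  cp <- build_corpus(docs, "s1")
  scores <- vapply(1:10, function(q)
    rank_score("A", make_query(rep("term", q)), cp), numeric(1))
  expect_true(all(diff(scores) >= 0))
  # the qtf factor saturates below (k3 + 1) = 9 times its qtf = 1 value
  expect_lt(scores[10], 9 * scores[1])
})

test_that("bm25 and rank agree with a naive double-loop oracle", {
  set.seed(11)
  for (i in 1:30) {
    case <- random_scoring_case()
    cp <- build_corpus(case$doc_tokens, "s1")
    for (g in names(case$doc_tokens)) {
      expect_equal(bm25_score(g, make_query(case$terms), cp),
                   oracle_bm25(g, case$terms, case$doc_tokens),
                   tolerance = 1e-9)
      expect_equal(rank_score(g, make_query(case$terms), cp),
                   oracle_rank(g, case$terms, case$doc_tokens),
                   tolerance = 1e-9)
    }
  }
})

test_that("bm25 is non-decreasing in term frequency at fixed document length", {
  # same dl, increasing tf of the query term
  docs <- list(A = c("t", "p", "p", "p"), B = c("t", "t", "p", "p"),
               C = c("t", "t", "t", "p"))
  cp <- build_corpus(docs, "s1")
  s <- vapply(c("A", "B", "C"), function(g)
    bm25_score(g, make_query("t"), cp), numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("scaled similarity features span 0..1000 and collapse degenerate cases", {
  corpora <- toy_corpora()
  tab <- score_genes(c("seizure", "ataxia"), corpora)
  expect_true(all(tab$sim_max >= 0 & tab$sim_max <= 1000))
  expect_true(all(tab$sim_min <= tab$sim_max))
  # the planted gene attains the per-source maximum 1000
  expect_equal(tab$sim_max[tab$gene == "GA"], 1000)
  # single source: max == min
  tab1 <- score_genes("anemia", corpora[1])
  expect_equal(tab1$sim_max, tab1$sim_min)
  # no term matches anywhere: all scores stay 0
  tab0 <- score_genes("nonexistenttoken", corpora)
  expect_true(all(tab0$sim_max == 0 & tab0$sim_min == 0))
  # empty keyword list warns and returns zeros
  expect_warning(tabe <- score_genes(character(), corpora), "empty")
  expect_true(all(tabe$sim_max == 0))
  expect_equal(gene_similarity_features("GB", "anemia", corpora)[["sim_max"]],
               1000)
})

test_that("a gene absent from a corpus scores 0 with a logged miss", {
  cp <- build_corpus(list(A = "seizure"), "s1")
  expect_message(s <- bm25_score("NOPE", make_query("seizure"), cp),
                 "absent")
  expect_equal(s, 0)
})

test_that("brute-force scoring of a five-gene corpus puts planted keywords on top", {
  docs1 <- list(G1 = "alpha beta pad pad", G2 = "gamma delta pad pad",
                G3 = "epsilon zeta pad pad", G4 = "eta theta pad pad",
                G5 = "iota kappa pad pad")
  docs2 <- list(G1 = "alpha pad", G2 = "gamma pad", G3 = "epsilon pad",
                G4 = "eta pad", G5 = "iota pad")
  corpora <- list(build_corpus(docs1, "s1"), build_corpus(docs2, "s2"))
  tab <- score_genes(c("alpha", "beta"), corpora)
  expect_equal(tab$sim_max[tab$gene == "G1"], 1000)
  expect_true(all(tab$sim_max[tab$gene != "G1"] < 1000))
})
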