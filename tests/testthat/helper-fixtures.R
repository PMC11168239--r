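# Shared builders: hand-made variant rows, tiny corpora, and naive
# double-loop scoring oracles kept independent of the package's BM25 code
# path.

# one variant row with sensible defaults, overridable field by field
mk_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                       gene = "GENE1", ...) {
  v <- variant_table(1L)
  v$chrom <- chrom; v$pos <- as.integer(pos); v$ref <- ref; v$alt <- alt
  v$gene <- gene
  v$variant_type <- "snv"
  dots <- list(...)
  for (nm in names(dots)) v[[nm]] <- dots[[nm]]
  v
}

mk_variants <- function(...) do.call(rbind, list(...))

# two-source toy corpora over distinct per-gene marker tokens
toy_corpora <- function() {
  docs1 <- list(
    GA = "seizure hypotonia seizure ataxia common common",
    GB = "anemia pallor fatigue common common",
    GC = "deafness vertigo common common common")
  docs2 <- list(
    GA = "seizure spasm common filler",
    GB = "anemia bruising filler filler",
    GC = "deafness tinnitus filler common")
  list(build_corpus(docs1, "src1"), build_corpus(docs2, "src2"))
}

# ---- independent scoring oracles (brute force over doc token lists) ----

oracle_idf <- function(term, doc_tokens) {
  N <- length(doc_tokens)
  n <- sum(vapply(doc_tokens, function(d) term %in% d, logical(1)))
  log((N - n + 0.5) / (n + 0.5) + 1)
}

oracle_bm25 <- function(gene, terms, doc_tokens, k1 = 1.2, b = 0.8) {
  D <- doc_tokens[[gene]]
  dls <- vapply(doc_tokens, length, numeric(1))
  avgdl <- mean(dls)
  total <- 0
  for (q in terms) {
    f <- sum(D == q)
    total <- total + oracle_idf(q, doc_tokens) * f * (k1 + 1) /
      (f + k1 * (1 - b + b * length(D) / avgdl))
  }
  total
}

oracle_rank <- function(gene, terms, doc_tokens, k1 = 1.2, b = 0.75,
                        k3 = 8, R = 0, r = 0) {
  D <- doc_tokens[[gene]]
  N <- length(doc_tokens)
  dls <- vapply(doc_tokens, length, numeric(1))
  avgdl <- mean(dls)
  K <- k1 * ((1 - b) + b * length(D) / avgdl)
  qtf_tab <- table(terms)
  total <- 0
  for (q in names(qtf_tab)) {
    n <- sum(vapply(doc_tokens, function(d) q %in% d, logical(1)))
    w <- log(((r + 0.5) * (N - n - R + r + 0.5)) /
             ((R - r + 0.5) * (n - r + 0.5)))
    w <- max(0, w)
    tf <- sum(D == q)
    qtf <- as.numeric(qtf_tab[[q]])
    total <- total + w * ((k1 + 1) * tf / (K + tf)) *
      ((k3 + 1) * qtf / (k3 + qtf))
  }
  total
}

# a random tiny corpus + query for oracle-equivalence sweeps
random_scoring_case <- function() {
  vocab <- c(letters[1:10], "zz", "qq")
  n_docs <- sample(2:10, 1)
  doc_tokens <- lapply(seq_len(n_docs), function(i)
    sample(vocab, sample(5:30, 1), replace = TRUE))
  names(doc_tokens) <- paste0("G", seq_len(n_docs))
  terms <- sample(c(vocab, "unseen"), sample(1:5, 1), replace = TRUE)
  list(doc_tokens = doc_tokens, terms = terms)
}

# small fitted cohort shared by feature/model tests
small_fit_inputs <- function(seed = 21, n_patients = 6, n_variants = 80,
                             signal = "strong") {
  cfg <- sim_config(seed = seed, n_genes = 60, vocab_size = 600,
                    n_sources = 2, n_patients = n_patients,
                    variants_per_patient = n_variants, signal = signal,
                    universe_seed = 500)
  corpora <- generate_corpus(cfg)
  list(cfg = cfg, corpora = corpora,
       cases = generate_cohort(cfg, corpora))
}
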