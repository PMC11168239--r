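# Gene-phenotype similarity scoring.
#
# Gene descriptions (one document per gene per source, emulating OMIM,
# GeneReviews, Entrez Gene and PubTator) are ranked against the patient's
# free-text phenotype keywords with Okapi BM25, and with the RANK variant of
# BM25 in which the IDF term is replaced by the Robertson-Sparck-Jones
# relevance weight and a query-term-frequency saturation factor (k3) is
# added. Per (query, source), RANK scores over all genes are min-max scaled
# to ordinal integers 0..1000; the per-gene maximum and minimum across
# sources become the two model features.

#' Tokenize free text
#'
#' Lowercases and splits on any non-alphanumeric character; no stemming or
#' stop-word removal.
#'
#' @param text Character vector.
#' @return Character vector of tokens.
#' @export
tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(as.character(text)), "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

#' Build a scoring corpus from gene documents
#'
#' @param docs Named list (or named character vector) mapping gene symbol to
#'   document text, or to a pre-tokenized character vector.
#' @param source Source label (e.g. `"omim"`).
#' @return A `bm25_corpus`: per-gene term-frequency tables, document
#'   frequencies `df`, document count `N`, document lengths `dl` and their
#'   mean `avgdl`.
#' @export
build_corpus <- function(docs, source = "corpus") {
  stopifnot(length(docs) == 0L || !is.null(names(docs)))
  tf <- lapply(docs, function(d) table(tokenize(d)))
  tf <- lapply(tf, function(tb) {
    v <- as.integer(tb)
    names(v) <- names(tb)
    v
  })
  dl <- vapply(tf, sum, numeric(1))
  all_terms <- unlist(lapply(tf, names), use.names = FALSE)
  df_tab <- table(all_terms)
  df <- as.integer(df_tab)
  names(df) <- names(df_tab)
  structure(list(source = source, tf = tf, df = df,
                 N = length(tf), dl = dl,
                 avgdl = if (length(dl) > 0L) mean(dl) else 0),
            class = "bm25_corpus")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' @export
print.bm25_corpus <- function(x, ...) {
  cat("<bm25_corpus> source=", x$source, " N=", x$N,
      " avgdl=", round(x$avgdl, 1), " vocab=", length(x$df), "\n", sep = "")
  invisible(x)
}

#' BM25 scoring constants
#'
#' @param k1 Term-frequency saturation constant (default 1.2).
#' @param b_bm25 Length-normalization constant used by [bm25_score()]
#'   (default 0.8).
#' @param b_rank Length-normalization constant used inside the `K` factor of
#'   [rank_score()] (default 0.75).
#' @param k3 Query-term-frequency saturation constant of [rank_score()]
#'   (default 8).
#' @param R Number of known relevant documents (default 0: no relevance
#'   judgments).
#' @param r Number of relevant documents containing the term (default 0).
#' @return A `bm25_params` list.
#' @export
bm25_params <- function(k1 = 1.2, b_bm25 = 0.8, b_rank = 0.75, k3 = 8,
                        R = 0, r = 0) {
  stopifnot(k1 > 0, k3 > 0, b_bm25 >= 0, b_bm25 <= 1, b_rank >= 0,
            b_rank <= 1, r >= 0, R >= r)
  structure(list(k1 = k1, b_bm25 = b_bm25, b_rank = b_rank, k3 = k3,
                 R = R, r = r), class = "bm25_params")
}

#' Build a query from free-text keywords
#'
#' Multi-word keywords are decomposed into tokens; all tokens enter one
#' query (duplicates preserved, they increase the query term frequency).
#'
#' @param keywords Character vector of phenotype terms.
#' @return A list with `terms` (all token instances) and `qtf` (named counts
#'   per unique term).
#' @export
make_query <- function(keywords) {
  terms <- tokenize(keywords)
  tb <- table(terms)
  qtf <- as.integer(tb)
  names(qtf) <- names(tb)
  list(terms = terms, qtf = qtf)
}

#' Inverse document frequency
#'
#' `ln(((N - n + 0.5) / (n + 0.5)) + 1)` with `n` the number of documents
#' containing `term`; strictly decreasing in `n`, defined for `n = 0`.
#'
#' @param term A single token.
#' @param corpus A [build_corpus()] object.
#' @return Non-negative IDF weight.
#' @export
idf <- function(term, corpus) {
  n <- corpus$df[term]
  n <- if (is.na(n)) 0 else as.numeric(n)
  log((corpus$N - n + 0.5) / (n + 0.5) + 1)
}

#' Okapi BM25 score of one gene's document for a query
#'
#' Sums `IDF(q) * f(q,D) * (k1 + 1) / (f(q,D) + k1 * (1 - b + b * |D|/avgdl))`
#' over all query term instances (a duplicated keyword contributes its
#' summand twice), with `b = b_bm25`.
#'
#' @param gene Gene symbol; a gene absent from the corpus scores 0 (logged
#'   as a message, not an error).
#' @param query A [make_query()] object (or character vector of keywords).
#' @param corpus A [build_corpus()] object.
#' @param params [bm25_params()].
#' @return Non-negative score; 0 when no query term occurs in the document.
#' @export
bm25_score <- function(gene, query, corpus, params = bm25_params()) {
  if (is.character(query)) query <- make_query(query)
  tfv <- corpus$tf[[gene]]
  if (is.null(tfv)) {
    message("gene '", gene, "' absent from corpus '", corpus$source,
            "'; BM25 score 0")
    return(0)
  }
  if (length(query$terms) == 0L) return(0)
  dl <- corpus$dl[[gene]]
  denom_len <- params$k1 * (1 - params$b_bm25 +
                            params$b_bm25 * dl / corpus$avgdl)
  total <- 0
  for (q in query$terms) {
    tf <- tfv[q]
    tf <- if (is.na(tf)) 0 else as.numeric(tf)
    if (tf == 0) next
    total <- total + idf(q, corpus) * tf * (params$k1 + 1) / (tf + denom_len)
  }
  total
}

#' Robertson-Sparck-Jones term weight
#'
#' `log(((r + 0.5)(N - n - R + r + 0.5)) / ((R - r + 0.5)(n - r + 0.5)))`,
#' floored at 0 so a term can never contribute negative similarity. With no
#' relevance judgments (`R = r = 0`) it reduces to
#' `log((N - n + 0.5)/(n + 0.5))`.
#'
#' @param term A single token.
#' @param corpus A [build_corpus()] object.
#' @param params [bm25_params()] carrying `R` and `r`.
#' @return Non-negative weight.
#' @export
rsj_weight <- function(term, corpus, params = bm25_params()) {
  n <- corpus$df[term]
  n <- if (is.na(n)) 0 else as.numeric(n)
  R <- params$R; r <- params$r
  w <- log(((r + 0.5) * (corpus$N - n - R + r + 0.5)) /
           ((R - r + 0.5) * (n - r + 0.5)))
  max(0, w)
}

#' RANK score of one gene's document for a query
#'
#' The BM25 variant behind the 0-1000 RANK feature: per unique query term,
#' `w * ((k1 + 1) * tf / (K + tf)) * ((k3 + 1) * qtf / (k3 + qtf))` where
#' `w` is the RSJ weight, `tf` the term's document frequency, `qtf` its
#' query frequency and `K = k1 * ((1 - b) + b * dl/avgdl)` with `b = b_rank`.
#'
#' @inheritParams bm25_score
#' @return Non-negative score; non-decreasing in `qtf`.
#' @export
rank_score <- function(gene, query, corpus, params = bm25_params()) {
  if (is.character(query)) query <- make_query(query)
  tfv <- corpus$tf[[gene]]
  if (is.null(tfv)) {
    message("gene '", gene, "' absent from corpus '", corpus$source,
            "'; RANK score 0")
    return(0)
  }
  if (length(query$qtf) == 0L) return(0)
  dl <- corpus$dl[[gene]]
  K <- params$k1 * ((1 - params$b_rank) + params$b_rank * dl / corpus$avgdl)
  total <- 0
  for (q in names(query$qtf)) {
    tf <- tfv[q]
    tf <- if (is.na(tf)) 0 else as.numeric(tf)
    if (tf == 0) next
    qtf <- as.numeric(query$qtf[[q]])
    total <- total + rsj_weight(q, corpus, params) *
      ((params$k1 + 1) * tf / (K + tf)) *
      ((params$k3 + 1) * qtf / (params$k3 + qtf))
  }
  total
}

# RANK scores for every gene in a corpus (one query), unscaled
.rank_scores_all <- function(query, corpus, params) {
  genes <- names(corpus$tf)
  out <- numeric(length(genes))
  names(out) <- genes
  if (length(query$qtf) == 0L || length(genes) == 0L) return(out)
  K_all <- params$k1 * ((1 - params$b_rank) +
                        params$b_rank * corpus$dl / corpus$avgdl)
  for (q in names(query$qtf)) {
    w <- rsj_weight(q, corpus, params)
    if (w == 0) next
    qtf <- as.numeric(query$qtf[[q]])
    qpart <- (params$k3 + 1) * qtf / (params$k3 + qtf)
    tfq <- vapply(corpus$tf, function(v) {
      x <- v[q]; if (is.na(x)) 0 else as.numeric(x)
    }, numeric(1))
    out <- out + w * ((params$k1 + 1) * tfq / (K_all + tfq)) * qpart
  }
  out
}

# min-max scale a score vector to ordinal integers 0..1000; constant
# (including all-zero) vectors stay 0
.scale_rank <- function(scores) {
  if (length(scores) == 0L) return(scores)
  rng <- range(scores)
  if (rng[2] <= rng[1]) return(stats::setNames(rep(0, length(scores)),
                                               names(scores)))
  round(1000 * (scores - rng[1]) / (rng[2] - rng[1]))
}

#' Scaled gene-similarity scores for one query over all corpora
#'
#' Computes the RANK score of every gene in every source, min-max scales
#' each source's scores to ordinal integers 0..1000 for this query, and
#' reports each gene's maximum and minimum across sources (a gene absent
#' from a source contributes 0 for that source).
#'
#' @param keywords Character vector of phenotype terms.
#' @param corpora A list of [build_corpus()] objects (1-4 sources).
#' @param params [bm25_params()].
#' @return A data.frame with `gene`, one scaled-score column per source, and
#'   `sim_max` / `sim_min`.
#' @export
score_genes <- function(keywords, corpora, params = bm25_params()) {
  stopifnot(length(corpora) >= 1L)
  query <- make_query(keywords)
  if (length(query$terms) == 0L)
    warning("empty keyword list: all similarity scores are 0")
  genes <- sort(unique(unlist(lapply(corpora, function(cp) names(cp$tf)))))
  mat <- matrix(0, nrow = length(genes), ncol = length(corpora))
  src_names <- vapply(seq_along(corpora), function(i)
    corpora[[i]]$source %||% paste0("source", i), character(1))
  colnames(mat) <- make.unique(src_names)
  rownames(mat) <- genes
  for (i in seq_along(corpora)) {
    sc <- .scale_rank(.rank_scores_all(query, corpora[[i]], params))
    mat[names(sc), i] <- sc
  }
  data.frame(gene = genes,
             mat,
             sim_max = if (length(genes)) apply(mat, 1, max) else numeric(),
             sim_min = if (length(genes)) apply(mat, 1, min) else numeric(),
             row.names = NULL, check.names = FALSE)
}

#' Max/min similarity features for one gene
#'
#' @param gene Gene symbol.
#' @param keywords Character vector of phenotype terms; empty list returns
#'   `c(0, 0)` with a warning.
#' @param corpora List of [build_corpus()] objects.
#' @param params [bm25_params()].
#' @return Named numeric `c(sim_max = , sim_min = )` of the scaled RANK
#'   scores across sources.
#' @export
gene_similarity_features <- function(gene, keywords, corpora,
                                     params = bm25_params()) {
  tab <- score_genes(keywords, corpora, params)
  row <- tab[tab$gene == gene, , drop = FALSE]
  if (nrow(row) == 0L)
    return(c(sim_max = 0, sim_min = 0))
  c(sim_max = row$sim_max[1], sim_min = row$sim_min[1])
}
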