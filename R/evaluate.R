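# Top-k and cumulative rank statistics for causative-variant recovery.
#
# Three denominators: variant mode (each causative variant contributes its
# own rank; denominator = causative variants), patient mode (a patient
# counts at k if any of its causative variants ranks <= k; denominator =
# patients), and gene mode (variant ranks collapse to genes by each gene's
# best-ranked variant with dense re-ranking; the best causative gene's rank
# per patient is used; denominator = patients).

#' Top-k recovery statistics
#'
#' @param ranked_lists Named list (by patient id) of ranked data.frames as
#'   returned by [rank_patient()] (columns `rank`, `key`, `gene`).
#' @param truth Named list of causative-key character vectors per patient;
#'   `NULL` takes the `label` column carried in the ranked lists. A
#'   causative key absent from its patient's list is an error (denominators
#'   contain only retained, diagnosed variants).
#' @param mode `"variant"`, `"patient"` or `"gene"`.
#' @param ks Rank cut-offs reported (default 1, 5, 10, 20, 50, 100).
#' @return A `rank_summary`: `mode`, `top_k` (named percentages,
#'   non-decreasing in k), `denominator` and the achieved `ranks`.
#' @export
topk_stats <- function(ranked_lists, truth = NULL,
                       mode = c("variant", "patient", "gene"),
                       ks = c(1, 5, 10, 20, 50, 100)) {
  mode <- match.arg(mode)
  if (is.null(truth))
    truth <- lapply(ranked_lists, function(rl) rl$key[rl$label == 1L])
  ranks <- numeric(0)
  for (pid in names(ranked_lists)) {
    rl <- ranked_lists[[pid]]
    keys <- truth[[pid]]
    if (is.null(keys) || length(keys) == 0L)
      stop("no causative key recorded for patient ", pid)
    missing <- setdiff(keys, rl$key)
    if (length(missing) > 0L)
      stop("causative key(s) absent from ranked list of patient ", pid,
           ": ", paste(missing, collapse = ", "))
    if (mode == "variant") {
      ranks <- c(ranks, rl$rank[match(keys, rl$key)])
    } else if (mode == "patient") {
      ranks <- c(ranks, min(rl$rank[match(keys, rl$key)]))
    } else {
      best <- tapply(rl$rank, rl$gene, min)
      gene_rank <- rank(best, ties.method = "first")
      causal_genes <- unique(rl$gene[match(keys, rl$key)])
      ranks <- c(ranks, min(gene_rank[causal_genes]))
    }
  }
  top_k <- vapply(ks, function(k) 100 * mean(ranks <= k), numeric(1))
  names(top_k) <- paste0("top", ks)
  structure(list(mode = mode, top_k = top_k, denominator = length(ranks),
                 ranks = as.numeric(ranks)),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat("<rank_summary> mode=", x$mode, " n=", x$denominator, "\n", sep = "")
  for (nm in names(x$top_k))
    cat(sprintf("  %-8s %5.1f%%\n", nm, x$top_k[[nm]]))
  invisible(x)
}

#' Cumulative rank distribution
#'
#' Monotone non-decreasing step curve of the percentage of causative
#' variants (or patients / genes, per the summary's mode) recovered at or
#' below each rank; reaches 100 at the maximum achieved rank.
#'
#' @param summary A `rank_summary` from [topk_stats()].
#' @return A data.frame with `k` (1..max rank) and `cumulative_percentage`.
#' @export
cumulative_distribution <- function(summary) {
  stopifnot(inherits(summary, "rank_summary"))
  kmax <- max(summary$ranks)
  ks <- seq_len(kmax)
  pct <- vapply(ks, function(k) 100 * mean(summary$ranks <= k), numeric(1))
  data.frame(k = ks, cumulative_percentage = pct)
}
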