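# Candidate-variant filtering.
#
# An exome carries ~40,000 variants per proband; the filter keeps only those
# that are plausibly deleterious: rare (max allele frequency <= 0.01, or
# unobserved in population databases) AND matching at least one damaging
# consequence class. The allele-frequency gate is conjunctive; the
# consequence classes are a union — within a class, any listed column
# containing any listed value is a match.

#' Default consequence filter criteria
#'
#' One entry per consequence class. Each entry lists the variant-table
#' columns searched (`exonic_func`, `consequence`, `func_region`,
#' `variant_type`) and the values that count as a match. Values match
#' case-insensitively against comma/semicolon/ampersand-delimited tokens of
#' the column, either whole-token or as a whitespace-separated word of the
#' token (so `"nonsynonymous"` matches `"nonsynonymous SNV"` and
#' `"deletion"` matches `"frameshift deletion"`).
#'
#' The `exon_splice_site` class is a catch-all over exonic/splicing regions;
#' its `synonymous_guard` suppresses region-based matches for records whose
#' only stated consequence is synonymous, which would otherwise sweep every
#' synonymous exonic variant into the candidate set.
#'
#' @return A named list of filter definitions, user-overridable.
#' @export
default_filter_criteria <- function() {
  list(
    nonsynonymous = list(
      columns = "exonic_func",
      values = "nonsynonymous"),
    stop_gain = list(
      columns = c("consequence", "exonic_func"),
      values = c("stop_gained", "stopgain")),
    splice = list(
      columns = c("consequence", "func_region"),
      values = c("splice_region_variant", "splice_acceptor_variant",
                 "splice_donor_variant", "splicing")),
    frameshift = list(
      columns = c("consequence", "exonic_func"),
      values = c("frameshift_variant", "feature_truncation",
                 "feature_elongation", "frameshift")),
    initial_codon = list(
      columns = "consequence",
      values = "start_lost"),
    deletion = list(
      columns = c("variant_type", "consequence", "exonic_func"),
      values = "deletion"),
    insertion = list(
      columns = c("variant_type", "consequence", "exonic_func"),
      values = "insertion"),
    inframe_deletion = list(
      columns = c("consequence", "exonic_func"),
      values = c("inframe_deletion", "nonframeshift deletion")),
    exon_splice_site = list(
      columns = c("func_region", "consequence"),
      values = c("exonic", "splicing", "coding_sequence_variant",
                 "frameshift_variant", "incomplete_terminal_codon_variant",
                 "inframe_deletion", "inframe_insertion", "missense_variant",
                 "splice_acceptor_variant", "splice_donor_variant",
                 "splice_region_variant"),
      synonymous_guard = TRUE)
  )
}

# split an annotation field into lowercase trimmed tokens
.field_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  toks <- strsplit(tolower(x), "[,;&]")[[1]]
  toks <- trimws(toks)
  toks[nzchar(toks)]
}

# does any token match any value (whole-token or word-of-token)?
.tokens_match <- function(tokens, values) {
  if (length(tokens) == 0L) return(FALSE)
  values <- tolower(values)
  if (any(tokens %in% values)) return(TRUE)
  words <- unlist(strsplit(tokens, "[[:space:]]+"))
  any(words %in% values)
}

.SYNONYMOUS_TOKENS <- c("synonymous snv", "synonymous_variant")

# TRUE when the record affirms a consequence and everything it affirms is
# synonymous -- such records must not pass via the exonic/splicing catch-all
.is_synonymous_only <- function(exonic_func, consequence) {
  toks <- c(.field_tokens(exonic_func), .field_tokens(consequence))
  length(toks) > 0L && all(toks %in% .SYNONYMOUS_TOKENS)
}

.filter_match_one <- function(variant_row, filt) {
  syn_only <- isTRUE(filt$synonymous_guard) &&
    .is_synonymous_only(variant_row$exonic_func, variant_row$consequence)
  for (col in filt$columns) {
    if (syn_only && col == "func_region") next
    if (.tokens_match(.field_tokens(variant_row[[col]]), filt$values))
      return(TRUE)
  }
  FALSE
}

#' Filter variants down to deleterious candidates
#'
#' A variant is retained iff its max allele frequency is `<= af_threshold`
#' or missing (absence from population databases is treated as rarity), and
#' it matches at least one consequence class of `criteria`. Input order is
#' preserved.
#'
#' @param variants A variant table ([variant_table()] columns).
#' @param criteria Filter definitions; see [default_filter_criteria()].
#' @param af_threshold Maximum allele frequency retained (default 0.01).
#' @return A list with `variants` (the retained rows) and `report`, a
#'   `filter_report` holding `input_count`, `output_count` and
#'   `per_filter_matches` (matches per class among retained variants).
#' @export
filter_variants <- function(variants, criteria = default_filter_criteria(),
                            af_threshold = 0.01) {
  n <- nrow(variants)
  af_pass <- is.na(variants$max_af) | variants$max_af <= af_threshold
  match_mat <- matrix(FALSE, nrow = n, ncol = length(criteria),
                      dimnames = list(NULL, names(criteria)))
  if (n > 0L) {
    for (i in seq_len(n)) {
      row <- variants[i, , drop = FALSE]
      for (f in seq_along(criteria))
        match_mat[i, f] <- .filter_match_one(row, criteria[[f]])
    }
  }
  cons_pass <- if (length(criteria) > 0L) rowSums(match_mat) > 0L
               else rep(FALSE, n)
  keep <- af_pass & cons_pass
  per_filter <- if (n > 0L) colSums(match_mat[keep, , drop = FALSE])
                else stats::setNames(rep(0, length(criteria)), names(criteria))
  report <- structure(
    list(input_count = n, output_count = sum(keep),
         per_filter_matches = as.list(per_filter)),
    class = "filter_report")
  list(variants = variants[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$input_count, " -> ", x$output_count,
      " variants\n", sep = "")
  for (nm in names(x$per_filter_matches))
    cat(sprintf("  %-18s %d\n", nm, as.integer(x$per_filter_matches[[nm]])))
  invisible(x)
}
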