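# Data model and I/O for annotated patient variants.
#
# Variants live in a plain data.frame (one row per (chrom,pos,ref,alt)) whose
# column set is fixed by variant_table(); a patient is a light S3 list around
# that table plus sex, free-text phenotype keywords and the diagnosed
# causative keys.

#' Names of the functional-prediction rank-score columns
#'
#' The 20 deleteriousness predictors whose ANNOVAR-converted rank scores
#' (each in \[0,1\], higher = more damaging) enter the feature matrix.
#'
#' @return Character vector of length 20.
#' @export
pred_score_names <- function() {
  c("SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT", "MutationTaster",
    "MutationAssessor", "FATHMM", "PROVEAN", "MetaSVM", "MetaLR", "M_CAP",
    "CADD", "GERP", "DANN", "fathmm_MKL", "GenoCanyon", "fitCons", "PhyloP",
    "PhastCons", "SiPhy")
}

.annotation_cols <- function() {
  c("gene", "genotype", "read_depth", "func_region", "exonic_func",
    "consequence", "max_af", pred_score_names(), "maxent_alt",
    "maxent_variation", "clinvar_sig", "hgmd_rank", "acmg_evidence",
    "pli", "prec", "syn_z", "mis_z", "inheritance")
}

.variant_cols <- function() {
  c("chrom", "pos", "ref", "alt", "quality", "variant_type",
    .annotation_cols())
}

#' Create an empty (or n-row) variant table
#'
#' @param n Number of rows; all fields initialised to missing.
#' @return A data.frame with the canonical variant columns: identity keys
#'   (`chrom`, `pos`, `ref`, `alt`), `quality`, `variant_type`
#'   (snv/insertion/deletion), and the annotation fields (gene symbol,
#'   genotype hom/het/hem, read depth, region and coding consequence,
#'   Sequence-Ontology terms in `consequence` (comma-separated), max allele
#'   frequency, 20 prediction rank scores, MaxEntScan alt/variation, ClinVar
#'   significance, HGMD rank, ACMG evidence codes (comma-separated), gnomAD
#'   constraints pLI/pRec/syn_z/mis_z, OMIM inheritance patterns
#'   (comma-separated)).
#' @export
variant_table <- function(n = 0L) {
  chr_cols <- c("chrom", "ref", "alt", "gene", "genotype", "variant_type",
                "func_region", "exonic_func", "consequence", "clinvar_sig",
                "acmg_evidence", "inheritance")
  num_cols <- c("quality", "read_depth", "max_af", pred_score_names(),
                "maxent_alt", "maxent_variation", "hgmd_rank",
                "pli", "prec", "syn_z", "mis_z")
  df <- data.frame(pos = rep(NA_integer_, n))
  for (cc in chr_cols) df[[cc]] <- rep(NA_character_, n)
  for (cc in num_cols) df[[cc]] <- rep(NA_real_, n)
  df <- df[, .variant_cols(), drop = FALSE]
  df
}

#' Normalize a chromosome name
#'
#' Strips any `chr` prefix (case-insensitively) and upper-cases X/Y/M/MT, so
#' that `"chr7"`, `"CHR7"` and `"7"` all compare equal. Idempotent.
#'
#' @param chrom Character vector of chromosome names.
#' @return Normalized character vector without prefix.
#' @export
normalize_chrom <- function(chrom) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  toupper(out)
}

#' Variant identity key
#'
#' @param variants A variant table (or any data.frame with chrom/pos/ref/alt).
#' @return Character vector `"chrom:pos:ref:alt"` with normalized chromosome.
#' @export
variant_key <- function(variants) {
  paste(normalize_chrom(variants$chrom), variants$pos,
        variants$ref, variants$alt, sep = ":")
}

.validate_variants <- function(variants, patient_id = "?") {
  stopifnot(is.data.frame(variants))
  miss <- setdiff(.variant_cols(), names(variants))
  if (length(miss) > 0L)
    stop("variant table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(variants) > 0L) {
    if (any(!is.na(variants$pos) & variants$pos < 1L))
      stop("variant positions must be >= 1")
    af <- variants$max_af
    if (any(!is.na(af) & (af < 0 | af > 1)))
      stop("max_af outside [0,1]")
    key <- variant_key(variants)
    dup <- key[duplicated(key)]
    if (length(dup) > 0L)
      stop("duplicate variant key(s) for patient ", patient_id, ": ",
           paste(unique(dup), collapse = ", "))
  }
  invisible(variants)
}

#' Construct a patient case
#'
#' @param patient_id Identifier string.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param variants A variant table (see [variant_table()]).
#' @param keywords Character vector of free-text phenotype terms.
#' @param causative_keys Character vector of `"chrom:pos:ref:alt"` keys of
#'   the diagnosed causative variants (may be empty for undiagnosed cases).
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(patient_id, sex = c("female", "male", "unknown"),
                         variants = variant_table(), keywords = character(),
                         causative_keys = character()) {
  sex <- match.arg(sex)
  .validate_variants(variants, patient_id)
  keys <- variant_key(variants)
  bad <- setdiff(causative_keys, keys)
  if (length(bad) > 0L)
    stop("causative key(s) not present in variant table for patient ",
         patient_id, ": ", paste(bad, collapse = ", "))
  structure(list(patient_id = as.character(patient_id), sex = sex,
                 variants = variants,
                 keywords = as.character(keywords),
                 causative_keys = as.character(causative_keys)),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat("<patient_case> ", x$patient_id, " (", x$sex, ")\n", sep = "")
  cat("  variants:  ", nrow(x$variants), "\n", sep = "")
  cat("  keywords:  ", length(x$keywords), "\n", sep = "")
  cat("  causative: ", length(x$causative_keys), "\n", sep = "")
  invisible(x)
}

# GT field -> genotype category. 0/1 -> het, 1/1 -> hom, 1 -> hem (single
# allele), anything containing '.' -> missing. `allele` is the 1-based ALT
# index the record was split on.
.gt_to_genotype <- function(gt, allele = 1L) {
  gt <- sub(":.*$", "", gt)           # GT is the first FORMAT subfield
  if (is.na(gt) || gt == "" || grepl("\\.", gt)) return(NA_character_)
  parts <- strsplit(gt, "[/|]")[[1]]
  hits <- sum(parts == as.character(allele))
  if (length(parts) == 1L) {
    if (hits == 1L) return("hem")
    return(NA_character_)
  }
  if (hits >= 2L) return("hom")
  if (hits == 1L) return("het")
  NA_character_
}

.read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c(".", "", "NA"),
                           quote = "", comment.char = "")
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L)
    stop("annotation table missing key column(s): ",
         paste(miss, collapse = ", "))
  num_cols <- intersect(c("read_depth", "max_af", pred_score_names(),
                          "maxent_alt", "maxent_variation", "hgmd_rank",
                          "pli", "prec", "syn_z", "mis_z"), names(ann))
  for (cc in num_cols) ann[[cc]] <- as.numeric(ann[[cc]])
  ann$pos <- as.integer(ann$pos)
  ann
}

#' Load a patient case from a VCF and an annotation table
#'
#' Reads the core VCF columns (first sample's GT), splits multi-allelic rows
#' into one record per ALT allele, and joins the tab-separated annotation
#' table on the normalized `(chrom, pos, ref, alt)` key. Unmatched annotation
#' rows are dropped with a warning; unmatched VCF rows keep all-missing
#' annotations.
#'
#' @param vcf_path Path to an (uncompressed) VCF 4.x file.
#' @param annotation_path Path to a UTF-8 TSV with a header naming at least
#'   `chrom`, `pos`, `ref`, `alt` plus any annotation columns of
#'   [variant_table()]; `"."` or empty cells are missing.
#' @param meta A list with `patient_id`, `sex`, `keywords`, and optionally
#'   `causative_keys`.
#' @return A [patient_case()].
#' @export
load_patient_case <- function(vcf_path, annotation_path, meta) {
  stopifnot(is.list(meta), !is.null(meta$patient_id))
  header <- .vcf_check_columns(vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    variants <- variant_table(0L)
  } else {
    gt_col <- if (ncol(vcf@gt) >= 2L) vcf@gt[, 2L] else rep(NA_character_, nrow(fix))
    rows <- vector("list", nrow(fix))
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      sub <- variant_table(length(alts))
      sub$chrom <- normalize_chrom(fix[i, "CHROM"])
      sub$pos <- as.integer(fix[i, "POS"])
      sub$ref <- fix[i, "REF"]
      sub$alt <- alts
      q <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
      sub$quality <- q
      for (j in seq_along(alts))
        sub$genotype[j] <- .gt_to_genotype(gt_col[i], allele = j)
      sub$variant_type <- ifelse(
        nchar(sub$ref) == 1L & nchar(sub$alt) == 1L, "snv",
        ifelse(nchar(sub$alt) > nchar(sub$ref), "insertion", "deletion"))
      rows[[i]] <- sub
    }
    variants <- do.call(rbind, rows)
  }
  key <- variant_key(variants)
  if (anyDuplicated(key))
    stop("duplicate variant key(s) in VCF for patient ", meta$patient_id,
         ": ", paste(unique(key[duplicated(key)]), collapse = ", "))

  ann <- .read_annotation_table(annotation_path)
  akey <- paste(normalize_chrom(ann$chrom), ann$pos, ann$ref, ann$alt,
                sep = ":")
  if (anyDuplicated(akey))
    stop("duplicate key(s) in annotation table: ",
         paste(unique(akey[duplicated(akey)]), collapse = ", "))
  unmatched <- setdiff(akey, key)
  if (length(unmatched) > 0L)
    warning(length(unmatched), " annotation row(s) without a VCF record ",
            "ignored: ", paste(utils::head(unmatched, 5L), collapse = ", "))
  idx <- match(key, akey)
  keep_cols <- setdiff(intersect(.annotation_cols(), names(ann)), "genotype")
  for (cc in keep_cols) variants[[cc]] <- ann[[cc]][idx]

  patient_case(meta$patient_id,
               sex = if (is.null(meta$sex)) "unknown" else meta$sex,
               variants = variants,
               keywords = if (is.null(meta$keywords)) character() else meta$keywords,
               causative_keys = if (is.null(meta$causative_keys)) character()
                                else meta$causative_keys)
}

.vcf_check_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines, value = TRUE)
  if (length(hdr) != 1L)
    stop("VCF format error: expected exactly one #CHROM header line in ", path)
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  need <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT")
  if (length(cols) < 9L || !identical(cols[1:9], need))
    stop("VCF format error: first 9 columns must be ",
         paste(need, collapse = ", "))
  if (anyDuplicated(cols))
    stop("VCF format error: duplicated column name(s): ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  invisible(cols)
}

#' Read a keyword file (one phenotype term per line)
#'
#' @param path UTF-8 text file; blank lines ignored.
#' @return Character vector of terms.
#' @export
read_keywords <- function(path) {
  kw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  kw <- trimws(kw)
  kw[nzchar(kw)]
}

#' Write a ranked variant list to TSV
#'
#' @param path Output file path.
#' @param ranked A data.frame as returned by [rank_patient()]: columns
#'   `rank`, `probability`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `acmg_score`, `sim_max`, `sim_min`. Ranks must be a permutation of
#'   `1..n` and probabilities in \[0,1\].
#' @return Invisibly, the path. Probabilities are written at full precision
#'   so that [read_ranked_variants()] reproduces them exactly.
#' @export
write_ranked_variants <- function(path, ranked) {
  cols <- c("rank", "probability", "chrom", "pos", "ref", "alt", "gene",
            "acmg_score", "sim_max", "sim_min")
  miss <- setdiff(cols, names(ranked))
  if (length(miss) > 0L)
    stop("ranked table missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(ranked)
  if (n > 0L) {
    if (!setequal(ranked$rank, seq_len(n)))
      stop("ranks must be a permutation of 1..n")
    if (any(ranked$probability < 0 | ranked$probability > 1))
      stop("probabilities must lie in [0,1]")
  }
  out <- ranked[order(ranked$rank), cols, drop = FALSE]
  num <- function(v) sprintf("%.17g", v)
  lines <- c(paste(cols, collapse = "\t"),
             if (n > 0L) paste(out$rank, num(out$probability), out$chrom,
                               out$pos, out$ref, out$alt, out$gene,
                               num(out$acmg_score), num(out$sim_max),
                               num(out$sim_min), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked variant list written by [write_ranked_variants()]
#'
#' @param path TSV path.
#' @return A data.frame with the serialized columns.
#' @export
read_ranked_variants <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  for (cc in c("probability", "acmg_score", "sim_max", "sim_min"))
    df[[cc]] <- as.numeric(df[[cc]])
  df$rank <- as.integer(df$rank)
  df$pos <- as.integer(df$pos)
  df
}
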