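# Feature engineering: the 94-column numeric design matrix.
#
# Each retained variant becomes one row: 20 functional-prediction rank
# scores, MaxEntScan significance, ClinVar one-hot, HGMD rank, the weighted
# ACMG score plus indicators for its 14 weighted criteria, gnomAD gene
# constraints, OMIM inheritance-pattern counts, genotype one-hot (after the
# male-chrX hemizygous correction), region/coding-consequence/variant-type
# one-hots, VCF quality, read depth, max allele frequency, the max/min
# gene-phenotype similarity scores and a sex indicator. The label is 1 for
# diagnosed causative variants, 0 otherwise.

.ACMG_ALL <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
               "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

#' ACMG/AMP evidence weights
#'
#' The 14 weighted criteria of the ACMG pathogenicity score: PVS1:6, PS1:4,
#' PM1:2, PM2:2, PM4:2, PM5:2, PP2:1, PP3:1 count toward pathogenicity;
#' BA1:9, BS1:3, BS2:3, BP3:1, BP4:1, BP7:2 are benign evidence and
#' subtract their weight.
#'
#' @return An `acmg_weights` list with `weights` (named positive integers)
#'   and `benign_codes`.
#' @export
acmg_weights <- function() {
  structure(list(
    weights = c(PVS1 = 6, PS1 = 4, PM1 = 2, PM2 = 2, PM4 = 2, PM5 = 2,
                PP2 = 1, PP3 = 1, BA1 = 9, BS1 = 3, BS2 = 3, BP3 = 1,
                BP4 = 1, BP7 = 2),
    benign_codes = c("BA1", "BS1", "BS2", "BP3", "BP4", "BP7")),
    class = "acmg_weights")
}

#' Weighted ACMG pathogenicity score
#'
#' Sum of the weights of the satisfied pathogenic criteria minus the weights
#' of the satisfied benign criteria. Criteria without a weight are ignored;
#' codes outside the 28 ACMG/AMP criteria raise a warning and are ignored.
#'
#' @param evidence Character vector of satisfied criteria codes (e.g.
#'   `c("PVS1", "PM2")`), or a single comma/semicolon-delimited string.
#' @param weights An [acmg_weights()] object.
#' @return Numeric score (can be negative under strong benign evidence).
#' @export
acmg_score <- function(evidence, weights = acmg_weights()) {
  codes <- .parse_codes(evidence)
  unknown <- setdiff(codes, .ACMG_ALL)
  if (length(unknown) > 0L) {
    warning("ignoring unknown ACMG code(s): ", paste(unknown, collapse = ", "))
    codes <- setdiff(codes, unknown)
  }
  codes <- intersect(codes, names(weights$weights))
  if (length(codes) == 0L) return(0)
  sign <- ifelse(codes %in% weights$benign_codes, -1, 1)
  sum(sign * weights$weights[codes])
}

.parse_codes <- function(evidence) {
  if (length(evidence) == 1L && (is.na(evidence) || !nzchar(evidence)))
    return(character())
  codes <- unlist(strsplit(as.character(evidence), "[,;[:space:]]+"))
  unique(toupper(codes[nzchar(codes)]))
}

#' MaxEntScan splice significance indicator
#'
#' 1 iff the MaxEntScan alternate-allele score is below 3 and the relative
#' score change is below 30 percent in absolute value, both values present;
#' 0 otherwise (including any missing input).
#'
#' @param alt MaxEntScan alternate score (numeric or NA).
#' @param variation MaxEntScan relative change as a fraction (numeric or NA).
#' @return Integer vector of 0/1.
#' @export
maxentscan_significance <- function(alt, variation) {
  out <- as.integer(!is.na(alt) & !is.na(variation) &
                    alt < 3 & abs(variation) < 0.30)
  out
}

#' Hemizygous genotype correction for male chromosome X
#'
#' Upstream genotype annotation carries no hemizygous calls, so every
#' chromosome-X genotype of a male patient is replaced by `hem`. Other
#' genotypes pass through unchanged (unknown sex is treated as female: no
#' replacement).
#'
#' @param genotype Character vector of genotype categories.
#' @param chrom Character vector of chromosome names.
#' @param sex Patient sex (`"male"`, `"female"`, `"unknown"`).
#' @return Corrected genotype vector.
#' @export
fix_hemizygous <- function(genotype, chrom, sex) {
  if (identical(sex, "male")) {
    on_x <- normalize_chrom(chrom) == "X"
    genotype[on_x] <- "hem"
  }
  genotype
}

.INHERITANCE_LEVELS <- c("AD", "AR", "XLD", "XLR", "XL", "YL",
                         "mitochondrial", "digenic", "somatic",
                         "multifactorial", "other")

.canon_inheritance <- function(token) {
  t <- toupper(trimws(token))
  if (t %in% c("AD", "AR", "XLD", "XLR", "XL", "YL")) return(t)
  if (t %in% c("MT", "MI", "MITOCHONDRIAL")) return("mitochondrial")
  if (t %in% c("DD", "DR", "DIGENIC")) return("digenic")
  if (t %in% c("SMU", "SM", "SOMATIC")) return("somatic")
  if (t %in% c("MU", "MF", "MULTIFACTORIAL")) return("multifactorial")
  "other"
}

#' Count OMIM inheritance patterns
#'
#' @param patterns Character vector of pattern tokens, or a single
#'   comma/semicolon-delimited string (e.g. `"AD,AR,AD"`). Recognized
#'   canonical patterns: AD, AR, XLD, XLR, XL, YL, mitochondrial, digenic,
#'   somatic, multifactorial; anything else is counted under `other`.
#' @return Named integer vector of counts over all canonical patterns
#'   (all zeros for an empty list).
#' @export
inheritance_counts <- function(patterns) {
  counts <- stats::setNames(integer(length(.INHERITANCE_LEVELS)),
                            .INHERITANCE_LEVELS)
  if (length(patterns) == 0L) return(counts)
  if (length(patterns) == 1L && (is.na(patterns) || !nzchar(patterns)))
    return(counts)
  toks <- unlist(strsplit(as.character(patterns), "[,;]+"))
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  for (t in toks) {
    canon <- .canon_inheritance(t)
    counts[canon] <- counts[canon] + 1L
  }
  counts
}

.CLINVAR_LEVELS <- c("pathogenic", "likely_pathogenic",
                     "uncertain_significance", "likely_benign", "benign",
                     "conflicting_interpretations", "drug_response", "other")

.canon_clinvar <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  v <- gsub("[ /]+", "_", tolower(trimws(x)))
  if (grepl("conflicting", v)) return("conflicting_interpretations")
  if (v %in% .CLINVAR_LEVELS) return(v)
  if (grepl("likely_pathogenic", v)) return("likely_pathogenic")
  if (grepl("likely_benign", v)) return("likely_benign")
  if (grepl("pathogenic", v)) return("pathogenic")
  if (grepl("benign", v)) return("benign")
  if (grepl("uncertain", v)) return("uncertain_significance")
  if (grepl("drug", v)) return("drug_response")
  "other"
}

.FUNC_REGION_LEVELS <- c("exonic", "splicing", "exonic_splicing",
                         "ncrna_exonic", "ncrna_splicing", "ncrna_intronic",
                         "intronic", "utr5", "utr3", "upstream",
                         "downstream", "intergenic")

.canon_func_region <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  v <- gsub("[;,/ ]+", "_", tolower(trimws(x)))
  if (v %in% .FUNC_REGION_LEVELS) return(v)
  if (v %in% c("exonic_splicing", "splicing_exonic")) return("exonic_splicing")
  "other"
}

.EXONIC_FUNC_LEVELS <- c("nonsynonymous_snv", "synonymous_snv", "stopgain",
                         "stoploss", "startloss", "frameshift_insertion",
                         "frameshift_deletion", "nonframeshift_insertion",
                         "nonframeshift_deletion", "unknown")

.canon_exonic_func <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  v <- gsub("[ ]+", "_", tolower(trimws(x)))
  if (v %in% .EXONIC_FUNC_LEVELS) return(v)
  "other"
}

.onehot <- function(values, levels, prefix) {
  mat <- matrix(0, nrow = length(values), ncol = length(levels),
                dimnames = list(NULL, paste0(prefix, levels)))
  idx <- match(values, levels)
  ok <- which(!is.na(idx))
  mat[cbind(ok, idx[ok])] <- 1
  mat
}

#' The 94-column feature schema
#'
#' One registry declaring every model feature: its name, role
#' (`continuous`, `count`, `binary`, `onehot`) and imputation policy
#' (`mean` = training-column mean; `zero` = semantic zero). Continuous and
#' count columns are min-max normalized by [fit_transform()]; binary and
#' one-hot columns are already 0/1.
#'
#' @return A data.frame with columns `name`, `role`, `impute` (94 rows
#'   under the defaults).
#' @export
feature_schema <- function() {
  sch <- rbind(
    data.frame(name = paste0("rs_", pred_score_names()),
               role = "continuous", impute = "mean"),
    data.frame(name = "maxent_significance", role = "binary", impute = "zero"),
    data.frame(name = "hgmd_rank", role = "continuous", impute = "zero"),
    data.frame(name = paste0("clinvar_", .CLINVAR_LEVELS),
               role = "onehot", impute = "zero"),
    data.frame(name = "acmg_score", role = "continuous", impute = "zero"),
    data.frame(name = paste0("acmg_", names(acmg_weights()$weights)),
               role = "binary", impute = "zero"),
    data.frame(name = c("pli", "prec", "syn_z", "mis_z"),
               role = "continuous", impute = "mean"),
    data.frame(name = paste0("inh_", .INHERITANCE_LEVELS),
               role = "count", impute = "zero"),
    data.frame(name = paste0("gt_", c("hom", "het", "hem")),
               role = "onehot", impute = "zero"),
    data.frame(name = paste0("fr_", .FUNC_REGION_LEVELS),
               role = "onehot", impute = "zero"),
    data.frame(name = paste0("ef_", .EXONIC_FUNC_LEVELS),
               role = "onehot", impute = "zero"),
    data.frame(name = paste0("vt_", c("snv", "insertion", "deletion")),
               role = "onehot", impute = "zero"),
    data.frame(name = c("quality", "read_depth"),
               role = "continuous", impute = "mean"),
    data.frame(name = "max_af", role = "continuous", impute = "zero"),
    data.frame(name = c("sim_max", "sim_min"),
               role = "continuous", impute = "zero"),
    data.frame(name = "sex_male", role = "binary", impute = "zero")
  )
  rownames(sch) <- NULL
  sch
}

# feature rows for the variants of one patient (matrix with NAs preserved)
.case_features <- function(case, sim_table, weights) {
  v <- case$variants
  n <- nrow(v)
  rs <- as.matrix(v[, pred_score_names(), drop = FALSE])
  colnames(rs) <- paste0("rs_", pred_score_names())
  maxent <- maxentscan_significance(v$maxent_alt, v$maxent_variation)
  clin <- .onehot(vapply(v$clinvar_sig, .canon_clinvar, character(1)),
                  .CLINVAR_LEVELS, "clinvar_")
  codes <- lapply(v$acmg_evidence, .parse_codes)
  acmg <- vapply(codes, function(cc)
    acmg_score(if (length(cc)) paste(cc, collapse = ",") else ""), numeric(1))
  acmg_ind <- t(vapply(codes, function(cc)
    as.numeric(names(weights$weights) %in% cc),
    numeric(length(weights$weights))))
  colnames(acmg_ind) <- paste0("acmg_", names(weights$weights))
  inh <- t(vapply(v$inheritance, function(p)
    as.numeric(inheritance_counts(if (is.na(p)) character() else p)),
    numeric(length(.INHERITANCE_LEVELS))))
  colnames(inh) <- paste0("inh_", .INHERITANCE_LEVELS)
  gt <- fix_hemizygous(v$genotype, v$chrom, case$sex)
  gt_oh <- .onehot(gt, c("hom", "het", "hem"), "gt_")
  fr <- .onehot(vapply(v$func_region, .canon_func_region, character(1)),
                .FUNC_REGION_LEVELS, "fr_")
  ef <- .onehot(vapply(v$exonic_func, .canon_exonic_func, character(1)),
                .EXONIC_FUNC_LEVELS, "ef_")
  vt <- .onehot(tolower(v$variant_type), c("snv", "insertion", "deletion"),
                "vt_")
  sim_idx <- match(v$gene, sim_table$gene)
  sim_max <- ifelse(is.na(sim_idx), 0, sim_table$sim_max[sim_idx])
  sim_min <- ifelse(is.na(sim_idx), 0, sim_table$sim_min[sim_idx])
  cbind(rs,
        maxent_significance = maxent,
        hgmd_rank = v$hgmd_rank,
        clin,
        acmg_score = acmg,
        acmg_ind,
        pli = v$pli, prec = v$prec, syn_z = v$syn_z, mis_z = v$mis_z,
        inh,
        gt_oh, fr, ef, vt,
        quality = v$quality, read_depth = v$read_depth,
        max_af = v$max_af,
        sim_max = sim_max, sim_min = sim_min,
        sex_male = as.numeric(identical(case$sex, "male")) + numeric(n))
}

#' Build the feature matrix for a set of patient cases
#'
#' Scores each patient's keywords against the corpora once, engineers the
#' full feature row for every variant and attaches the 0/1 causative label.
#' The result is unfitted: call [fit_transform()] to impute and normalize.
#'
#' @param cases List of [patient_case()] objects (already filtered).
#' @param corpora List of [build_corpus()] objects.
#' @param params [bm25_params()].
#' @param weights [acmg_weights()].
#' @param schema Feature registry; defaults to [feature_schema()].
#' @return A `feature_matrix`: list with `x` (numeric matrix, NAs preserved),
#'   `labels`, `patient_id`, `key`, `acmg` (raw ACMG score per row, used for
#'   rank tie-breaks), `schema`, `fit_state` (NULL until fitted).
#' @export
build_feature_matrix <- function(cases, corpora, params = bm25_params(),
                                 weights = acmg_weights(),
                                 schema = feature_schema()) {
  blocks <- vector("list", length(cases))
  ids <- character(); keys <- character(); labels <- integer()
  genes <- character()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    sim_table <- score_genes(case$keywords, corpora, params)
    m <- .case_features(case, sim_table, weights)
    blocks[[i]] <- m
    k <- variant_key(case$variants)
    ids <- c(ids, rep(case$patient_id, nrow(m)))
    keys <- c(keys, k)
    genes <- c(genes, case$variants$gene)
    labels <- c(labels, as.integer(k %in% case$causative_keys))
  }
  x <- do.call(rbind, blocks)
  if (!identical(colnames(x), schema$name)) {
    extra <- setdiff(colnames(x), schema$name)
    miss <- setdiff(schema$name, colnames(x))
    stop("feature schema mismatch (", ncol(x), " built vs ",
         nrow(schema), " declared)",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  }
  structure(list(x = x, labels = labels, patient_id = ids, key = keys,
                 gene = genes, acmg = unname(x[, "acmg_score"]),
                 sim_max = unname(x[, "sim_max"]),
                 sim_min = unname(x[, "sim_min"]),
                 schema = schema, fit_state = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " variants x ", ncol(x$x),
      " features (", sum(x$labels), " causative, ",
      length(unique(x$patient_id)), " patients, ",
      if (is.null(x$fit_state)) "unfitted" else "fitted", ")\n", sep = "")
  invisible(x)
}

#' Impute and min-max normalize a feature matrix
#'
#' In `fit` mode, learns per-column imputation values (training mean for
#' `mean`-policy columns, 0 otherwise) and training min/max for every
#' continuous or count column, stores them as `fit_state` and returns the
#' transformed matrix. In `transform` mode, applies a previously learned
#' `fit_state` (values are clipped to \[0,1\]; columns constant in training
#' map to 0; one-hot and binary cells have missing replaced by 0).
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param mode `"fit"` or `"transform"`.
#' @param state A `fit_state` from a fitted matrix (required for
#'   `"transform"` unless `fm` already carries one).
#' @return The transformed `feature_matrix` with `fit_state` attached.
#' @export
fit_transform <- function(fm, mode = c("fit", "transform"), state = NULL) {
  mode <- match.arg(mode)
  x <- fm$x
  sch <- fm$schema
  scaled_roles <- c("continuous", "count")
  if (mode == "fit") {
    state <- list(impute = numeric(ncol(x)), xmin = numeric(ncol(x)),
                  xmax = numeric(ncol(x)))
    names(state$impute) <- names(state$xmin) <- names(state$xmax) <- sch$name
    for (j in seq_len(ncol(x))) {
      col <- x[, j]
      imp <- if (sch$impute[j] == "mean") {
        if (all(is.na(col))) 0 else mean(col, na.rm = TRUE)
      } else 0
      state$impute[j] <- imp
      col[is.na(col)] <- imp
      state$xmin[j] <- min(col)
      state$xmax[j] <- max(col)
    }
  } else {
    state <- state %||% fm$fit_state
    if (is.null(state))
      stop("transform before fit: no fit_state available")
  }
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    col[is.na(col)] <- state$impute[j]
    if (sch$role[j] %in% scaled_roles) {
      rng <- state$xmax[j] - state$xmin[j]
      col <- if (rng <= 0) rep(0, length(col))
             else pmin(1, pmax(0, (col - state$xmin[j]) / rng))
    }
    x[, j] <- col
  }
  fm$x <- x
  fm$fit_state <- state
  fm
}
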