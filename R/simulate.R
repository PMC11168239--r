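# Synthetic corpora and patient cohorts.
#
# The generator emulates the statistical structure the pipeline assumes:
# per-source gene-description documents over a Zipf-like vocabulary with
# each gene carrying a handful of planted phenotype tokens, and exome-like
# variant tables where most variants are common or benign (so the filter
# has work to do) while causal variants are rare and, under the signalled
# presets, carry elevated pathogenicity evidence and keywords drawn from
# their gene's phenotype tokens. Everything is reproducible from one seed.

#' Simulation configuration
#'
#' @param seed Integer seed fixing the full output.
#' @param n_genes Number of genes shared by corpus and cohort.
#' @param vocab_size Vocabulary size of the corpus generator.
#' @param n_sources Number of description sources (1-4).
#' @param n_patients Cohort size.
#' @param variants_per_patient Variants per exome after upstream calling
#'   (default 741, the typical candidate load times the filter's pass rate
#'   headroom).
#' @param causal_per_patient Causative variants per patient (>= 1).
#' @param signal `"strong"`, `"moderate"` or `"null"`: how far causal rows'
#'   pathogenicity evidence, prediction scores, allele frequencies and
#'   planted keywords are shifted from the background distributions (`null`
#'   plants no signal at all: causal rows are background draws conditioned
#'   only on surviving the filter, and keywords are distractors).
#' @param universe_seed Seed of the shared gene universe (gene/chromosome
#'   map, constraints, inheritance, phenotype tokens, corpus documents).
#'   Defaults to `seed`; give train and test cohorts the same
#'   `universe_seed` but different `seed`s so they share genes and corpora
#'   without sharing patients.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 200, vocab_size = 2000,
                       n_sources = 2, n_patients = 20,
                       variants_per_patient = 741, causal_per_patient = 1,
                       signal = c("strong", "moderate", "null"),
                       universe_seed = NULL) {
  signal <- match.arg(signal)
  if (is.null(universe_seed)) universe_seed <- seed
  stopifnot(n_genes >= 1, vocab_size >= 50, n_sources >= 1, n_sources <= 4,
            n_patients >= 1, variants_per_patient >= 1,
            causal_per_patient >= 1)
  if (variants_per_patient < causal_per_patient)
    stop("variants_per_patient must be >= causal_per_patient")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 vocab_size = as.integer(vocab_size),
                 n_sources = as.integer(n_sources),
                 n_patients = as.integer(n_patients),
                 variants_per_patient = as.integer(variants_per_patient),
                 causal_per_patient = as.integer(causal_per_patient),
                 signal = signal,
                 universe_seed = as.integer(universe_seed)),
            class = "sim_config")
}

.sim_preset <- function(signal) {
  switch(signal,
    strong = list(planted_keywords = 4, distractor_keywords = 3,
                  pred_shape1 = 8, pred_shape2 = 2,
                  p_pvs1 = 0.8, p_pm2 = 0.9, p_pp3 = 0.8,
                  p_clinvar_path = 0.6, hgmd_shape1 = 8, hgmd_shape2 = 2,
                  p_af_missing = 0.9, af_max = 0.001),
    moderate = list(planted_keywords = 2, distractor_keywords = 4,
                    pred_shape1 = 4, pred_shape2 = 3,
                    p_pvs1 = 0.4, p_pm2 = 0.5, p_pp3 = 0.4,
                    p_clinvar_path = 0.25, hgmd_shape1 = 3, hgmd_shape2 = 3,
                    p_af_missing = 0.7, af_max = 0.005),
    null = list(planted_keywords = 0, distractor_keywords = 5,
                pred_shape1 = NA, pred_shape2 = NA,
                p_pvs1 = NA, p_pm2 = NA, p_pp3 = NA,
                p_clinvar_path = NA, hgmd_shape1 = NA, hgmd_shape2 = NA,
                p_af_missing = NA, af_max = NA))
}

# derive a stream seed from (seed, k); the multiplicative mixing ensures
# that distinct (seed, k) pairs with equal seed + c*k do not collide the
# way a purely additive scheme would
.sub_seed <- function(seed, k) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  x <- (x * 69069 + 1) %% m
  x <- ((x + as.numeric(k)) * 69069 + 1) %% m
  x <- (x * 40503 + 12345) %% m
  as.integer(x)
}

.sim_vocab <- function(config) {
  vocab <- sprintf("w%05d", seq_len(config$vocab_size))
  n_common <- max(10L, floor(0.7 * config$vocab_size))
  list(common = vocab[seq_len(n_common)],
       pheno = vocab[(n_common + 1L):config$vocab_size])
}

# deterministic gene table shared by corpus and cohort generation:
# symbol, chromosome, gnomAD-style constraints, OMIM inheritance pattern
# set and planted phenotype tokens
.sim_genes <- function(config) {
  set.seed(.sub_seed(config$universe_seed, 17L))
  voc <- .sim_vocab(config)
  n <- config$n_genes
  gene <- sprintf("GENE%04d", seq_len(n))
  chrom <- sample(c(as.character(1:22), "X"), n, replace = TRUE,
                  prob = c(rep(0.95 / 22, 22), 0.05))
  inh <- character(n)
  for (i in seq_len(n)) {
    inh[i] <- if (chrom[i] == "X") sample(c("XLR", "XLD", "XL"), 1)
              else sample(c("AD", "AR", "AD,AR", "AR,AR", "AD,mitochondrial"),
                          1, prob = c(0.35, 0.35, 0.15, 0.1, 0.05))
  }
  pheno_tokens <- lapply(seq_len(n), function(i)
    sample(voc$pheno, sample(3:8, 1)))
  data_frame <- data.frame(gene = gene, chrom = chrom,
                           pli = stats::rbeta(n, 0.4, 0.4),
                           prec = stats::rbeta(n, 0.5, 0.5),
                           syn_z = stats::rnorm(n, 0, 1.5),
                           mis_z = stats::rnorm(n, 0.5, 1.5),
                           inheritance = inh,
                           stringsAsFactors = FALSE)
  data_frame$pheno_tokens <- pheno_tokens
  data_frame
}

#' Generate per-source gene-description corpora
#'
#' Each source holds one document per gene: background tokens drawn from a
#' Zipf-weighted common vocabulary plus the gene's planted phenotype tokens
#' repeated with elevated frequency. Fully reproducible from the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list of `n_sources` [build_corpus()] objects.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- .sim_genes(config)
  voc <- .sim_vocab(config)
  zipf <- 1 / seq_along(voc$common)
  corpora <- vector("list", config$n_sources)
  src_names <- c("omim", "genereviews", "entrez", "pubtator")
  for (s in seq_len(config$n_sources)) {
    set.seed(.sub_seed(config$universe_seed, 31L + s))
    docs <- vector("list", nrow(genes))
    names(docs) <- genes$gene
    for (i in seq_len(nrow(genes))) {
      len <- 60L + stats::rpois(1, 40)
      background <- sample(voc$common, len, replace = TRUE, prob = zipf)
      planted <- rep(genes$pheno_tokens[[i]],
                     times = 2L + stats::rpois(length(genes$pheno_tokens[[i]]),
                                               3))
      docs[[i]] <- c(background, planted)
    }
    corpora[[s]] <- build_corpus(docs, source = src_names[s])
  }
  corpora
}

.BG_CATEGORIES <- data.frame(
  name = c("nonsynonymous", "synonymous", "stopgain", "frameshift_ins",
           "frameshift_del", "splice", "inframe_del", "intronic", "utr",
           "updown"),
  prob = c(0.40, 0.12, 0.03, 0.03, 0.03, 0.05, 0.02, 0.12, 0.12, 0.08),
  stringsAsFactors = FALSE)

# annotation fields implied by a consequence category
.category_fields <- function(cat) {
  switch(cat,
    nonsynonymous = list(func_region = "exonic",
                         exonic_func = "nonsynonymous SNV",
                         consequence = "missense_variant", type = "snv"),
    synonymous = list(func_region = "exonic", exonic_func = "synonymous SNV",
                      consequence = "synonymous_variant", type = "snv"),
    stopgain = list(func_region = "exonic", exonic_func = "stopgain",
                    consequence = "stop_gained", type = "snv"),
    frameshift_ins = list(func_region = "exonic",
                          exonic_func = "frameshift insertion",
                          consequence = "frameshift_variant",
                          type = "insertion"),
    frameshift_del = list(func_region = "exonic",
                          exonic_func = "frameshift deletion",
                          consequence = "frameshift_variant",
                          type = "deletion"),
    splice = list(func_region = "splicing", exonic_func = NA_character_,
                  consequence = "splice_donor_variant", type = "snv"),
    inframe_del = list(func_region = "exonic",
                       exonic_func = "nonframeshift deletion",
                       consequence = "inframe_deletion", type = "deletion"),
    intronic = list(func_region = "intronic", exonic_func = NA_character_,
                    consequence = "intron_variant", type = "snv"),
    utr = list(func_region = "UTR3", exonic_func = NA_character_,
               consequence = "3_prime_UTR_variant", type = "snv"),
    updown = list(func_region = "upstream", exonic_func = NA_character_,
                  consequence = "upstream_gene_variant", type = "snv"))
}

.DAMAGING_CATEGORIES <- c("nonsynonymous", "stopgain", "frameshift_ins",
                          "frameshift_del", "splice", "inframe_del")

.rand_allele <- function(n, type) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ins <- type == "insertion"
  del <- type == "deletion"
  alt[ins] <- paste0(ref[ins], "ACG")
  ref2 <- ref
  ref2[del] <- paste0(ref[del], "TTG")
  alt[del] <- substr(ref2[del], 1, 1)
  list(ref = ref2, alt = alt)
}

# one background variant row (fields only; identity set by caller).
# `force_candidate` conditions on surviving the filter (rare AF + damaging
# consequence) without shifting any other distribution.
.bg_variant <- function(gene_row, force_candidate = FALSE) {
  cat_tab <- .BG_CATEGORIES
  if (force_candidate)
    cat_tab <- cat_tab[cat_tab$name %in% .DAMAGING_CATEGORIES, ]
  cat <- sample(cat_tab$name, 1, prob = cat_tab$prob)
  fields <- .category_fields(cat)
  u <- stats::runif(1)
  max_af <- if (force_candidate) {
    if (u < 0.4) NA_real_ else stats::runif(1, 0, 0.01)
  } else if (u < 0.45) stats::runif(1, 0.02, 0.5)
    else if (u < 0.8) stats::runif(1, 0, 0.01)
    else NA_real_
  scores <- stats::rbeta(20, 2, 5)
  scores[stats::runif(20) < 0.1] <- NA_real_
  acmg <- {
    v <- stats::runif(1)
    if (v < 0.10) "PM2" else if (v < 0.15) "BP4"
    else if (v < 0.18) "PP3" else NA_character_
  }
  hgmd <- if (stats::runif(1) < 0.2) stats::rbeta(1, 1.5, 5) else NA_real_
  clinvar <- {
    v <- stats::runif(1)
    if (v < 0.7) NA_character_
    else if (v < 0.85) "uncertain_significance"
    else if (v < 0.95) "benign" else "likely_benign"
  }
  genotype <- sample(c("het", "hom", NA_character_), 1,
                     prob = c(0.7, 0.25, 0.05))
  list(category = cat, fields = fields, max_af = max_af, scores = scores,
       acmg = acmg, hgmd = hgmd, clinvar = clinvar, genotype = genotype,
       maxent_alt = if (cat == "splice") stats::runif(1, 0, 8) else NA_real_,
       maxent_variation = if (cat == "splice") stats::runif(1, -0.6, 0.6)
                          else NA_real_)
}

# a causal variant row under the preset's shifted distributions
.causal_variant <- function(gene_row, preset, signal) {
  if (signal == "null")
    return(.bg_variant(gene_row, force_candidate = TRUE))
  cat <- sample(c("nonsynonymous", "stopgain", "frameshift_del", "splice"),
                1, prob = c(0.55, 0.2, 0.15, 0.1))
  fields <- .category_fields(cat)
  max_af <- if (stats::runif(1) < preset$p_af_missing) NA_real_
            else stats::runif(1, 0, preset$af_max)
  scores <- stats::rbeta(20, preset$pred_shape1, preset$pred_shape2)
  acmg <- c(if (stats::runif(1) < preset$p_pvs1) "PVS1",
            if (stats::runif(1) < preset$p_pm2) "PM2",
            if (stats::runif(1) < preset$p_pp3) "PP3")
  inh <- strsplit(gene_row$inheritance, ",")[[1]][1]
  genotype <- if (inh %in% c("AR")) "hom" else "het"
  list(category = cat, fields = fields, max_af = max_af, scores = scores,
       acmg = if (length(acmg)) paste(acmg, collapse = ",") else NA_character_,
       hgmd = stats::rbeta(1, preset$hgmd_shape1, preset$hgmd_shape2),
       clinvar = if (stats::runif(1) < preset$p_clinvar_path) "pathogenic"
                 else NA_character_,
       genotype = genotype,
       maxent_alt = if (cat == "splice") stats::runif(1, 0, 2.5) else NA_real_,
       maxent_variation = if (cat == "splice") stats::runif(1, -0.25, 0.25)
                          else NA_real_)
}

.assemble_variant_row <- function(draw, gene_row, pos) {
  v <- variant_table(1L)
  al <- .rand_allele(1L, draw$fields$type)
  v$chrom <- gene_row$chrom
  v$pos <- pos
  v$ref <- al$ref
  v$alt <- al$alt
  v$gene <- gene_row$gene
  v$genotype <- draw$genotype
  v$quality <- round(stats::rgamma(1, shape = 20, rate = 0.4), 2)
  v$read_depth <- stats::rpois(1, 60) + 1
  v$func_region <- draw$fields$func_region
  v$exonic_func <- draw$fields$exonic_func
  v$consequence <- draw$fields$consequence
  v$variant_type <- draw$fields$type
  v$max_af <- draw$max_af
  v[, pred_score_names()] <- as.list(round(draw$scores, 4))
  v$maxent_alt <- draw$maxent_alt
  v$maxent_variation <- draw$maxent_variation
  v$clinvar_sig <- draw$clinvar
  v$hgmd_rank <- if (is.na(draw$hgmd)) NA_real_ else round(draw$hgmd, 4)
  v$acmg_evidence <- draw$acmg
  v$pli <- round(gene_row$pli, 4)
  v$prec <- round(gene_row$prec, 4)
  v$syn_z <- round(gene_row$syn_z, 3)
  v$mis_z <- round(gene_row$mis_z, 3)
  v$inheritance <- gene_row$inheritance
  v
}

#' Generate a synthetic patient cohort
#'
#' Each patient receives a causal gene, keywords (a noisy subset of that
#' gene's planted phenotype tokens plus distractors; pure distractors under
#' the `null` preset), `variants_per_patient` background variants and
#' `causal_per_patient` causal variants that are guaranteed to survive the
#' deleteriousness filter. Reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @param corpora The corpora from [generate_corpus()] on the same config
#'   (used to check gene consistency).
#' @return A list of [patient_case()] objects.
#' @export
generate_cohort <- function(config, corpora) {
  stopifnot(inherits(config, "sim_config"))
  genes <- .sim_genes(config)
  if (!missing(corpora) && !is.null(corpora)) {
    corpus_genes <- names(corpora[[1]]$tf)
    tf1 <- corpora[[1]]$tf[[genes$gene[1]]]
    if (!all(genes$gene %in% corpus_genes) ||
        !all(genes$pheno_tokens[[1]] %in% names(tf1)))
      stop("corpora were generated under a different gene universe; ",
           "use the same universe_seed")
  }
  preset <- .sim_preset(config$signal)
  voc <- .sim_vocab(config)
  cases <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    set.seed(.sub_seed(config$seed, 1000L + p))
    sex <- sample(c("male", "female"), 1)
    causal_idx <- sample(nrow(genes), 1)
    # male-only sampling for X-linked causal genes keeps genotypes coherent
    if (genes$chrom[causal_idx] == "X" && sex == "female")
      sex <- "male"
    causal_gene <- genes[causal_idx, , drop = FALSE]
    n_bg <- config$variants_per_patient - config$causal_per_patient
    bg_gene_idx <- sample(nrow(genes), n_bg, replace = TRUE)
    pos_pool <- sample.int(5e7L, config$variants_per_patient)
    rows <- vector("list", config$variants_per_patient)
    for (i in seq_len(n_bg))
      rows[[i]] <- .assemble_variant_row(.bg_variant(genes[bg_gene_idx[i], ]),
                                         genes[bg_gene_idx[i], ],
                                         pos_pool[i])
    for (j in seq_len(config$causal_per_patient))
      rows[[n_bg + j]] <- .assemble_variant_row(
        .causal_variant(causal_gene, preset, config$signal),
        causal_gene, pos_pool[n_bg + j])
    variants <- do.call(rbind, rows)
    perm <- sample(nrow(variants))
    causal_keys <- variant_key(variants[(n_bg + 1):nrow(variants), ,
                                        drop = FALSE])
    variants <- variants[perm, , drop = FALSE]
    rownames(variants) <- NULL
    planted <- if (preset$planted_keywords > 0)
      sample(causal_gene$pheno_tokens[[1]],
             min(preset$planted_keywords,
                 length(causal_gene$pheno_tokens[[1]])))
      else character()
    distractors <- sample(voc$common[1:50], preset$distractor_keywords)
    cases[[p]] <- patient_case(sprintf("P%04d", p), sex, variants,
                               keywords = c(planted, distractors),
                               causative_keys = causal_keys)
  }
  cases
}

#' Write a cohort and corpora to disk in the pipeline's file formats
#'
#' Emits, per patient, a minimal VCF (`<id>.vcf`), the annotation TSV
#' (`<id>.annotation.tsv`), a keyword file (`<id>.keywords.txt`), plus a
#' cohort-wide `truth.tsv` (patient, sex, causative keys) and the corpora
#' as JSON-lines `corpus.jsonl` records `{gene, source, text}`.
#'
#' @param dir Output directory (created if needed).
#' @param cases List of [patient_case()] objects.
#' @param corpora List of [build_corpus()] objects (optional).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(dir, cases, corpora = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- character()
  for (case in cases) {
    v <- case$variants
    gt_str <- c(het = "0/1", hom = "1/1", hem = "1")[v$genotype]
    gt_str[is.na(gt_str)] <- "./."
    vcf_lines <- c(
      "##fileformat=VCFv4.2",
      "##source=varranker-simulate",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", case$patient_id), collapse = "\t"),
      paste(v$chrom, v$pos, ".", v$ref, v$alt,
            ifelse(is.na(v$quality), ".", as.character(v$quality)), "PASS", ".",
            "GT", gt_str, sep = "\t"))
    writeLines(vcf_lines, file.path(dir, paste0(case$patient_id, ".vcf")))
    ann_cols <- c("chrom", "pos", "ref", "alt",
                  setdiff(.annotation_cols(), "genotype"))
    ann <- v[, ann_cols, drop = FALSE]
    utils::write.table(ann, file.path(dir, paste0(case$patient_id,
                                                  ".annotation.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    writeLines(case$keywords,
               file.path(dir, paste0(case$patient_id, ".keywords.txt")))
    truth <- c(truth, paste(case$patient_id, case$sex,
                            paste(case$causative_keys, collapse = ","),
                            sep = "\t"))
  }
  writeLines(c("patient_id\tsex\tcausative_keys", truth),
             file.path(dir, "truth.tsv"))
  if (!is.null(corpora)) {
    con <- file(file.path(dir, "corpus.jsonl"), "w")
    on.exit(close(con))
    for (cp in corpora) {
      for (g in names(cp$tf)) {
        text <- paste(rep(names(cp$tf[[g]]), cp$tf[[g]]), collapse = " ")
        writeLines(jsonlite::toJSON(list(gene = g, source = cp$source,
                                         text = text), auto_unbox = TRUE),
                   con)
      }
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the per-patient files and `truth.tsv`.
#' @return A list of [patient_case()] objects.
#' @export
read_cohort <- function(dir) {
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             colClasses = "character")
  cases <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    pid <- truth$patient_id[i]
    keys <- strsplit(truth$causative_keys[i], ",", fixed = TRUE)[[1]]
    cases[[i]] <- load_patient_case(
      file.path(dir, paste0(pid, ".vcf")),
      file.path(dir, paste0(pid, ".annotation.tsv")),
      meta = list(patient_id = pid, sex = truth$sex[i],
                  keywords = read_keywords(file.path(
                    dir, paste0(pid, ".keywords.txt"))),
                  causative_keys = keys))
  }
  cases
}

#' Read corpora from a JSON-lines file
#'
#' @param path File of records `{gene, source, text}`, one per line.
#' @return A list of [build_corpus()] objects, one per source (in order of
#'   first appearance).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  sources <- unique(vapply(recs, `[[`, character(1), "source"))
  lapply(sources, function(s) {
    sel <- Filter(function(r) r$source == s, recs)
    docs <- stats::setNames(lapply(sel, `[[`, "text"),
                            vapply(sel, `[[`, character(1), "gene"))
    build_corpus(docs, source = s)
  })
}
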