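# Pipeline wiring: one structured config drives simulate -> train (filter,
# phenotype scoring and featurization happen inside the fit) -> rank ->
# evaluate, each stage leaving a file artifact and the run leaving a
# manifest with the config hash, so an identical config/seed reproduces
# identical outputs.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "varranker_run",
    sim_train = list(n_genes = 200, vocab_size = 2000, n_sources = 2,
                     n_patients = 20, variants_per_patient = 300,
                     causal_per_patient = 1, signal = "strong"),
    sim_test = list(n_patients = 10),
    af_threshold = 0.01,
    bm25 = list(k1 = 1.2, b_bm25 = 0.8, b_rank = 0.75, k3 = 8, R = 0, r = 0),
    percentile = 60,
    model = list(num_trees = 500, max_depth = 0, mtry = "sqrt",
                 grid = NULL, cv_folds = 10, top_k = 10),
    eval_mode = "variant")
}

#' Build (or load) a pipeline configuration
#'
#' Starts from fully-defaulted settings, optionally overlaid with a YAML
#' file and/or a list of overrides. Unknown keys are rejected.
#'
#' @param path Optional YAML file.
#' @param overrides Optional named list merged over the file/defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- .pipeline_defaults()
  merge_in <- function(cfg, upd, where = "config") {
    unknown <- setdiff(names(upd), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
    for (nm in names(upd)) {
      if (is.list(cfg[[nm]]) && is.list(upd[[nm]]))
        cfg[[nm]] <- merge_in(cfg[[nm]], upd[[nm]], nm)
      else cfg[[nm]] <- upd[[nm]]
    }
    cfg
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

.sim_config_from <- function(config, which = c("train", "test")) {
  which <- match.arg(which)
  base <- config$sim_train
  if (which == "test")
    base[names(config$sim_test)] <- config$sim_test
  do.call(sim_config, c(list(seed = .sub_seed(config$seed,
                                              if (which == "train") 1L
                                              else 2L),
                             universe_seed = .sub_seed(config$seed, 100L)),
                        base))
}

.require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path))
    stop("stage '", needed_by, "' requires artifact '", path,
         "' produced by stage '", stage, "'")
  invisible(path)
}

#' Run the prioritization pipeline
#'
#' Executes the requested stages in order: `simulate` writes the synthetic
#' corpora and the train/test cohorts; `train` fits the
#' [variant_prioritizer()] on the training cohort (deleteriousness
#' filtering, phenotype scoring and featurization happen inside the fit)
#' and saves the model; `rank` writes one ranked TSV per test patient;
#' `evaluate` writes top-k and cumulative rank reports. Each stage checks
#' that its upstream artifacts exist; a manifest records the config hash
#' and seed.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of `c("simulate", "train", "rank", "evaluate")`.
#' @return Invisibly, a list with the evaluation summaries (when run) and
#'   the manifest path.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "train", "rank",
                                    "evaluate")) {
  stages <- match.arg(stages, c("simulate", "train", "rank", "evaluate"),
                      several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out, "data")
  model_path <- file.path(out, "model.rds")
  ranked_dir <- file.path(out, "ranked")
  params <- do.call(bm25_params, config$bm25)
  result <- list()

  if ("simulate" %in% stages) {
    cfg_train <- .sim_config_from(config, "train")
    cfg_test <- .sim_config_from(config, "test")
    if (!identical(cfg_train$n_genes, cfg_test$n_genes) ||
        !identical(cfg_train$vocab_size, cfg_test$vocab_size))
      stop("sim_test may not change n_genes/vocab_size/n_sources")
    corpora <- generate_corpus(cfg_train)
    train_cases <- generate_cohort(cfg_train, corpora)
    test_cases <- generate_cohort(cfg_test, corpora)
    write_cohort(file.path(data_dir, "train"), train_cases, corpora)
    write_cohort(file.path(data_dir, "test"), test_cases)
  }

  if ("train" %in% stages) {
    .require_artifact(file.path(data_dir, "train", "truth.tsv"), "simulate",
                      "train")
    .require_artifact(file.path(data_dir, "train", "corpus.jsonl"),
                      "simulate", "train")
    corpora <- read_corpus_jsonl(file.path(data_dir, "train", "corpus.jsonl"))
    train_cases <- read_cohort(file.path(data_dir, "train"))
    grid <- if (!is.null(config$model$grid))
      do.call(prioritizer_grid, config$model$grid) else NULL
    fit <- variant_prioritizer(
      train_cases, corpora, params = params,
      percentile = config$percentile,
      num_trees = config$model$num_trees,
      max_depth = config$model$max_depth, mtry = config$model$mtry,
      grid = grid, cv_folds = config$model$cv_folds,
      top_k = config$model$top_k, seed = .sub_seed(config$seed, 3L))
    saveRDS(fit, model_path)
    result$fit <- fit
  }

  if ("rank" %in% stages) {
    .require_artifact(model_path, "train", "rank")
    .require_artifact(file.path(data_dir, "test", "truth.tsv"), "simulate",
                      "rank")
    fit <- readRDS(model_path)
    test_cases <- read_cohort(file.path(data_dir, "test"))
    ranked <- predict(fit, test_cases)
    dir.create(ranked_dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(ranked))
      write_ranked_variants(file.path(ranked_dir, paste0(pid, ".ranked.tsv")),
                            ranked[[pid]])
    result$ranked <- ranked
  }

  if ("evaluate" %in% stages) {
    .require_artifact(ranked_dir, "rank", "evaluate")
    .require_artifact(file.path(data_dir, "test", "truth.tsv"), "simulate",
                      "evaluate")
    truth_df <- utils::read.delim(file.path(data_dir, "test", "truth.tsv"),
                                  colClasses = "character")
    truth <- stats::setNames(
      lapply(truth_df$causative_keys,
             function(s) strsplit(s, ",", fixed = TRUE)[[1]]),
      truth_df$patient_id)
    files <- list.files(ranked_dir, pattern = "\\.ranked\\.tsv$",
                        full.names = TRUE)
    ranked_lists <- stats::setNames(
      lapply(files, function(f) {
        df <- read_ranked_variants(f)
        df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
        df
      }),
      sub("\\.ranked\\.tsv$", "", basename(files)))
    summaries <- lapply(c("variant", "patient", "gene"), function(m)
      topk_stats(ranked_lists, truth, mode = m))
    names(summaries) <- c("variant", "patient", "gene")
    report <- lapply(summaries, function(s)
      list(mode = s$mode, denominator = s$denominator,
           top_k = as.list(s$top_k),
           cumulative = cumulative_distribution(s)))
    jsonlite::write_json(report, file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    result$evaluation <- summaries
  }

  manifest <- list(config_hash = .config_hash(config), seed = config$seed,
                   stages = stages,
                   package_version =
                     as.character(utils::packageVersion("varranker")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  result$manifest <- file.path(out, "manifest.json")
  invisible(result)
}
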