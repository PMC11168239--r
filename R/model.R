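# Random-forest ranking model and the top-level fitting interface.
#
# A probability forest (Gini impurity splits, class-balanced weights) is
# trained on the selected features; each patient's variants are then ordered
# by predicted disease-causing probability, ties broken by ACMG score and
# variant key. Hyperparameters can be chosen by grid search with
# patient-grouped 10-fold cross-validation maximizing top-10 accuracy.

#' Hyperparameter grid for the ranking forest
#'
#' @param num_trees Numbers of trees to try.
#' @param max_depth Maximum tree depths (0 = unlimited).
#' @param mtry Variables tried per split: `"sqrt"` or `"log2"` of the
#'   feature count.
#' @return A data.frame, one row per configuration.
#' @export
prioritizer_grid <- function(num_trees = c(100, 300, 500),
                             max_depth = c(0, 10, 20),
                             mtry = c("sqrt", "log2")) {
  expand.grid(num_trees = num_trees, max_depth = max_depth, mtry = mtry,
              stringsAsFactors = FALSE)
}

.mtry_value <- function(mtry, p) {
  m <- switch(as.character(mtry),
              sqrt = floor(sqrt(p)),
              log2 = floor(log2(p)),
              as.integer(mtry))
  max(1L, min(p, m))
}

.fit_forest <- function(x, y, num_trees, max_depth, mtry, seed,
                        importance = "none") {
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  df$.label <- factor(y, levels = c(0, 1))
  tab <- table(df$.label)
  cw <- as.numeric(sum(tab) / (2 * pmax(tab, 1)))
  ranger::ranger(dependent.variable.name = ".label", data = df,
                 probability = TRUE, num.trees = num_trees,
                 mtry = .mtry_value(mtry, ncol(x)),
                 max.depth = max_depth, splitrule = "gini",
                 class.weights = cw, importance = importance,
                 seed = seed, num.threads = 1L)
}

.predict_prob <- function(forest, x) {
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  p <- stats::predict(forest, data = df, num.threads = 1L)$predictions
  as.numeric(p[, "1"])
}

# assign patients to CV folds, round-robin after a seeded shuffle
.patient_folds <- function(patient_id, n_folds, seed) {
  patients <- unique(patient_id)
  n_folds <- min(n_folds, length(patients))
  set.seed(seed)
  shuffled <- sample(patients)
  fold_of <- stats::setNames(rep(seq_len(n_folds),
                                 length.out = length(shuffled)), shuffled)
  unname(fold_of[patient_id])
}

# fraction of validation patients whose best causative variant ranks <= k
.topk_cv_metric <- function(prob, fm, rows, k = 10L) {
  ids <- fm$patient_id[rows]
  labs <- fm$labels[rows]
  acmg <- fm$acmg[rows]
  keys <- fm$key[rows]
  hits <- 0L; denom <- 0L
  for (pid in unique(ids)) {
    sel <- ids == pid
    if (!any(labs[sel] == 1L)) next
    denom <- denom + 1L
    ord <- order(-prob[sel], -acmg[sel], keys[sel])
    ranks <- integer(sum(sel))
    ranks[ord] <- seq_len(sum(sel))
    if (min(ranks[labs[sel] == 1L]) <= k) hits <- hits + 1L
  }
  if (denom == 0L) return(NA_real_)
  hits / denom
}

#' Train the random-forest ranker
#'
#' Fits a probability forest (Gini impurity criterion, class-balanced
#' weights) on the selected feature columns. When `grid` is supplied, every
#' configuration is scored by patient-grouped `cv_folds`-fold
#' cross-validated top-`top_k` accuracy and the best one (first in grid
#' order on ties) is refitted on all rows.
#'
#' @param fm A fitted `feature_matrix` (training rows).
#' @param selected Integer column indices from [select_features()].
#' @param num_trees,max_depth,mtry Forest hyperparameters used when `grid`
#'   is NULL (`max_depth = 0` grows unpruned trees).
#' @param grid Optional [prioritizer_grid()] data.frame.
#' @param cv_folds Folds for the grouped cross-validation (default 10).
#' @param top_k Rank cut-off of the model-selection metric (default 10).
#' @param seed Integer seed; fixes fold assignment and forest randomness.
#' @return A `variant_ranker`: the forest, the selected columns, grid-search
#'   results (if any) and the seed.
#' @export
train_ranker <- function(fm, selected, num_trees = 500, max_depth = 0,
                         mtry = "sqrt", grid = NULL, cv_folds = 10,
                         top_k = 10, seed = 1) {
  y <- fm$labels
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  x <- fm$x[, selected, drop = FALSE]
  cv_results <- NULL
  if (!is.null(grid)) {
    folds <- .patient_folds(fm$patient_id, cv_folds, seed)
    scores <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      fold_scores <- numeric(0)
      for (f in sort(unique(folds))) {
        tr <- which(folds != f); va <- which(folds == f)
        if (length(unique(y[tr])) < 2L || !any(y[va] == 1L)) next
        fit <- .fit_forest(x[tr, , drop = FALSE], y[tr],
                           grid$num_trees[g], grid$max_depth[g],
                           grid$mtry[g], seed = seed + f)
        prob <- .predict_prob(fit, x[va, , drop = FALSE])
        m <- .topk_cv_metric(prob, fm, va, k = top_k)
        if (!is.na(m)) fold_scores <- c(fold_scores, m)
      }
      scores[g] <- if (length(fold_scores)) mean(fold_scores) else NA_real_
    }
    cv_results <- cbind(grid, cv_topk = scores)
    best <- which.max(scores)
    num_trees <- grid$num_trees[best]
    max_depth <- grid$max_depth[best]
    mtry <- grid$mtry[best]
  }
  forest <- .fit_forest(x, y, num_trees, max_depth, mtry, seed = seed,
                        importance = "impurity")
  structure(list(forest = forest, selected = selected,
                 feature_names = colnames(fm$x)[selected],
                 num_trees = num_trees, max_depth = max_depth, mtry = mtry,
                 cv_results = cv_results, seed = seed),
            class = "variant_ranker")
}

#' @export
print.variant_ranker <- function(x, ...) {
  cat("<variant_ranker> ", x$num_trees, " trees, max depth ",
      if (x$max_depth == 0) "unlimited" else x$max_depth, ", mtry ", x$mtry,
      ", ", length(x$selected), " features\n", sep = "")
  invisible(x)
}

#' Rank one patient's variants by disease-causing probability
#'
#' Rows are sorted by predicted probability descending; ties are broken by
#' ACMG score descending, then by `(chrom,pos,ref,alt)` key. The result does
#' not depend on input row order.
#'
#' @param fm A transformed `feature_matrix` holding exactly the rows of one
#'   patient.
#' @param ranker A [train_ranker()] model.
#' @return A data.frame with `rank` (1..n), `probability`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `acmg_score`, `sim_max`, `sim_min`, `key`,
#'   `label`, plus an attribute `tie_rule_applied`.
#' @export
rank_patient <- function(fm, ranker) {
  if (!all(ranker$selected <= ncol(fm$x)) ||
      !identical(colnames(fm$x)[ranker$selected], ranker$feature_names))
    stop("feature columns do not match the trained model")
  x <- fm$x[, ranker$selected, drop = FALSE]
  prob <- .predict_prob(ranker$forest, x)
  ord <- order(-prob, -fm$acmg, fm$key)
  key_parts <- strsplit(fm$key[ord], ":", fixed = TRUE)
  out <- data.frame(
    rank = seq_along(ord),
    probability = prob[ord],
    chrom = vapply(key_parts, `[`, character(1), 1L),
    pos = as.integer(vapply(key_parts, `[`, character(1), 2L)),
    ref = vapply(key_parts, `[`, character(1), 3L),
    alt = vapply(key_parts, `[`, character(1), 4L),
    gene = fm$gene[ord],
    acmg_score = fm$acmg[ord],
    sim_max = fm$sim_max[ord],
    sim_min = fm$sim_min[ord],
    key = fm$key[ord],
    label = fm$labels[ord],
    stringsAsFactors = FALSE)
  attr(out, "tie_rule_applied") <- anyDuplicated(prob) > 0L
  out
}

#' Subset a feature matrix by rows
#'
#' @param fm A `feature_matrix`.
#' @param rows Integer or logical row index.
#' @return The row-subset `feature_matrix` (fit_state preserved).
#' @export
fm_subset <- function(fm, rows) {
  fm$x <- fm$x[rows, , drop = FALSE]
  for (f in c("labels", "patient_id", "key", "gene", "acmg",
              "sim_max", "sim_min"))
    fm[[f]] <- fm[[f]][rows]
  fm
}

# filter every case's variants; causative keys that do not survive are
# dropped with a warning (the evaluation denominators contain only retained
# causative variants)
.filter_cases <- function(cases, criteria, af_threshold = 0.01) {
  reports <- list()
  out <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    fr <- filter_variants(case$variants, criteria, af_threshold)
    keys <- variant_key(fr$variants)
    lost <- setdiff(case$causative_keys, keys)
    if (length(lost) > 0L)
      warning("patient ", case$patient_id, ": causative variant(s) removed ",
              "by filtering: ", paste(lost, collapse = ", "))
    out[[i]] <- patient_case(case$patient_id, case$sex, fr$variants,
                             case$keywords, intersect(case$causative_keys,
                                                      keys))
    reports[[case$patient_id]] <- fr$report
  }
  list(cases = out, reports = reports)
}

#' Fit the phenotype-aware variant prioritizer
#'
#' End-to-end fit on a training cohort: Table-style deleteriousness
#' filtering, BM25/RSJ gene-phenotype scoring against the corpora, feature
#' engineering into the 94-column matrix, imputation and min-max
#' normalization, mutual-information feature selection and random-forest
#' training.
#'
#' @param cases List of [patient_case()] objects (the training cohort).
#' @param corpora List of [build_corpus()] objects (1-4 sources).
#' @param params [bm25_params()].
#' @param weights [acmg_weights()].
#' @param criteria Filter definitions ([default_filter_criteria()]).
#' @param percentile Feature-selection percentile (default 60: keeps 56 of
#'   the 94 columns).
#' @param num_trees,max_depth,mtry Forest hyperparameters when `grid` is
#'   NULL.
#' @param grid Optional [prioritizer_grid()] for cross-validated grid
#'   search.
#' @param cv_folds,top_k Grid-search cross-validation settings.
#' @param seed Integer seed fixing selection, fold assignment and forest
#'   randomness.
#' @param schema Feature registry (default [feature_schema()]).
#' @return An object of class `variant_prioritizer` with `ranker`,
#'   `fit_state`, `selected`, `mi`, `filter_reports`, and the scoring
#'   configuration needed by [predict.variant_prioritizer()].
#' @seealso [predict.variant_prioritizer()], [topk_stats()]
#' @export
variant_prioritizer <- function(cases, corpora, params = bm25_params(),
                                weights = acmg_weights(),
                                criteria = default_filter_criteria(),
                                percentile = 60, num_trees = 500,
                                max_depth = 0, mtry = "sqrt", grid = NULL,
                                cv_folds = 10, top_k = 10, seed = 1,
                                schema = feature_schema()) {
  filtered <- .filter_cases(cases, criteria)
  fm <- build_feature_matrix(filtered$cases, corpora, params, weights, schema)
  fm <- fit_transform(fm, "fit")
  selected <- select_features(fm, percentile)
  mi <- mi_with_label(fm)
  ranker <- train_ranker(fm, selected, num_trees = num_trees,
                         max_depth = max_depth, mtry = mtry, grid = grid,
                         cv_folds = cv_folds, top_k = top_k, seed = seed)
  structure(list(ranker = ranker, fit_state = fm$fit_state,
                 selected = selected, mi = mi,
                 filter_reports = filtered$reports,
                 corpora = corpora, params = params, weights = weights,
                 criteria = criteria, percentile = percentile,
                 schema = schema, seed = seed,
                 n_train_rows = nrow(fm$x), n_train_pos = sum(fm$labels),
                 n_train_patients = length(cases),
                 call = match.call()),
            class = "variant_prioritizer")
}

#' Rank the variants of new patients
#'
#' Applies the fitted pipeline (filter, phenotype scoring, feature
#' engineering, the training-set preprocessing state, the trained forest)
#' to each new case and returns per-patient ranked variant lists.
#'
#' @param object A [variant_prioritizer()] fit.
#' @param newcases List of [patient_case()] objects.
#' @param ... Unused.
#' @return A named list (by patient id) of ranked data.frames as returned
#'   by [rank_patient()].
#' @export
predict.variant_prioritizer <- function(object, newcases, ...) {
  filtered <- .filter_cases(newcases, object$criteria)
  fm <- build_feature_matrix(filtered$cases, object$corpora, object$params,
                             object$weights, object$schema)
  fm <- fit_transform(fm, "transform", state = object$fit_state)
  out <- list()
  for (case in filtered$cases) {
    rows <- which(fm$patient_id == case$patient_id)
    out[[case$patient_id]] <- rank_patient(fm_subset(fm, rows), object$ranker)
  }
  out
}

#' @export
print.variant_prioritizer <- function(x, ...) {
  cat("Phenotype-aware variant prioritizer\n")
  cat("  training: ", x$n_train_rows, " variants (", x$n_train_pos,
      " causative) from ", x$n_train_patients, " patients\n", sep = "")
  cat("  features: ", length(x$selected), "/", nrow(x$schema),
      " selected by mutual information (percentile ", x$percentile, ")\n",
      sep = "")
  print(x$ranker)
  invisible(x)
}

#' @export
summary.variant_prioritizer <- function(object, ...) {
  imp <- ranger::importance(object$ranker$forest)
  names(imp) <- object$ranker$feature_names
  structure(list(fit = object,
                 importance = sort(imp, decreasing = TRUE),
                 mi = sort(object$mi, decreasing = TRUE),
                 cv_results = object$ranker$cv_results),
            class = "summary.variant_prioritizer")
}

#' @export
print.summary.variant_prioritizer <- function(x, ...) {
  print(x$fit)
  cat("\nTop 10 features by impurity importance:\n")
  top <- utils::head(x$importance, 10)
  for (i in seq_along(top))
    cat(sprintf("  %-28s %.4f\n", names(top)[i], top[i]))
  if (!is.null(x$cv_results)) {
    cat("\nGrid-search results (top-k CV accuracy):\n")
    print(x$cv_results)
  }
  invisible(x)
}

#' Plot feature importances of a fitted prioritizer
#'
#' Horizontal barplot of the top `n` features by impurity importance.
#'
#' @param x A [variant_prioritizer()] fit.
#' @param n Number of features shown (default 20).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.variant_prioritizer <- function(x, n = 20, ...) {
  imp <- ranger::importance(x$ranker$forest)
  names(imp) <- x$ranker$feature_names
  top <- rev(utils::head(sort(imp, decreasing = TRUE), n))
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(top, horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "Impurity importance",
                    main = "Variant prioritizer feature importance", ...)
  invisible(x)
}
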