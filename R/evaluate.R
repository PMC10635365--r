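# Feature assembly, cross-validation with augmented-train /
# original-validate discipline, classifiers, and the metric panel.

#' Baseline 300-dimensional drug embedding
#'
#' Folds a binary fingerprint into `dim` dimensions by fixed index
#' hashing: component k collects the count of on-bits at fingerprint
#' positions p with ((p - 1) mod dim) + 1 = k. Deterministic and
#' structure-preserving (similar fingerprints give similar embeddings);
#' any pretrained molecular embedder with the same output length can be
#' plugged in instead.
#'
#' @param fingerprint Logical or 0/1 numeric fingerprint vector.
#' @param dim Embedding dimension (default 300).
#' @param embedder Optional function `fingerprint -> numeric(dim)`
#'   replacing the baseline; its output length is checked.
#' @return Numeric vector of length `dim`.
#' @export
embed_drug <- function(fingerprint, dim = 300L, embedder = NULL) {
  if (!is.null(embedder)) {
    v <- embedder(fingerprint)
    if (!is.numeric(v) || length(v) != dim || anyNA(v))
      dacs_abort("embedder must return %d finite numbers", dim)
    return(as.numeric(v))
  }
  fp <- as.numeric(fingerprint)
  if (anyNA(fp)) dacs_abort("fingerprint contains missing values")
  idx <- ((seq_along(fp) - 1L) %% dim) + 1L
  out <- numeric(dim)
  agg <- rowsum(fp, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# Seeded random-projection matrix, dim x n_genes, entries
# N(0, 1/n_genes) so projected scales are comparable across gene counts.
projection_matrix <- function(n_genes, dim = 300L, seed = 1L) {
  with_seed(seed, matrix(stats::rnorm(dim * n_genes, sd = 1 / sqrt(n_genes)),
                         nrow = dim, ncol = n_genes))
}

#' Baseline 300-dimensional cell-line embedding
#'
#' Projects a gene-expression profile with a fixed seeded Gaussian
#' random projection; the projection matrix is fully determined by
#' `(length(expression), dim, seed)`, so embeddings are reproducible
#' across runs. A learned expression encoder with the same output
#' length can be plugged in via `embedder`.
#'
#' @param expression Numeric vector of gene-expression values for one
#'   cell line.
#' @param dim Embedding dimension (default 300).
#' @param seed Seed fixing the projection matrix.
#' @param embedder Optional replacement function, checked as in
#'   [embed_drug()].
#' @return Numeric vector of length `dim`.
#' @export
embed_cell <- function(expression, dim = 300L, seed = 1L, embedder = NULL) {
  if (!is.null(embedder)) {
    v <- embedder(expression)
    if (!is.numeric(v) || length(v) != dim || anyNA(v))
      dacs_abort("embedder must return %d finite numbers", dim)
    return(as.numeric(v))
  }
  x <- as.numeric(expression)
  if (anyNA(x)) dacs_abort("expression profile contains missing values")
  as.numeric(projection_matrix(length(x), dim, seed) %*% x)
}

#' Assemble instance feature vectors
#'
#' One row per instance: drug A embedding, then drug B embedding (in
#' the stored canonical pair order), then the cell-line embedding —
#' 3 * `dim` columns (900 by default).
#'
#' @param instances Data frame with `drug_a`, `drug_b`, `cell_line`.
#' @param library [drug_library()] covering every drug referenced.
#' @param expression Genes x cell-lines numeric matrix with column
#'   names covering every referenced cell line.
#' @param dim Per-block embedding dimension.
#' @param cell_seed Seed for the cell-embedding projection.
#' @return Numeric matrix `nrow(instances)` x `3 * dim`.
#' @export
build_features <- function(instances, library, expression, dim = 300L,
                           cell_seed = 1L) {
  drugs <- unique(c(instances$drug_a, instances$drug_b))
  missing_d <- setdiff(drugs, library$drug_id)
  if (length(missing_d))
    dacs_abort("instances reference drugs missing from the library: %s",
               paste(utils::head(missing_d, 5L), collapse = ", "))
  cells <- unique(instances$cell_line)
  missing_c <- setdiff(cells, colnames(expression))
  if (length(missing_c))
    dacs_abort("instances reference cell lines missing from the expression matrix: %s",
               paste(utils::head(missing_c, 5L), collapse = ", "))
  emb_drug <- t(vapply(drugs, function(d)
    embed_drug(library$fingerprints[d, ], dim), numeric(dim)))
  P <- projection_matrix(nrow(expression), dim, cell_seed)
  emb_cell <- t(P %*% expression[, cells, drop = FALSE])
  rownames(emb_cell) <- cells
  out <- cbind(emb_drug[instances$drug_a, , drop = FALSE],
               emb_drug[instances$drug_b, , drop = FALSE],
               emb_cell[instances$cell_line, , drop = FALSE])
  dimnames(out) <- list(NULL, c(sprintf("drugA_%03d", seq_len(dim)),
                                sprintf("drugB_%03d", seq_len(dim)),
                                sprintf("cell_%03d", seq_len(dim))))
  out
}

#' Assign cross-validation folds
#'
#' Random scheme: a seeded stratified split into `k` folds preserving
#' the class proportion within one instance per fold. Tissue scheme:
#' folds are exactly the tissue groups of the instances' cell lines, so
#' no tissue appears in both training and validation.
#'
#' @param labeled [label_instances()] output (needs `instance_id`,
#'   `label`, `cell_line`).
#' @param scheme `"random_stratified"` or `"tissue"`.
#' @param cell_meta Data frame `CELL_LINE`, `TISSUE`; required for the
#'   tissue scheme, which errors on unmapped cell lines.
#' @param k Number of folds for the random scheme (default 5).
#' @param seed Seed for the random scheme.
#' @return Data frame `instance_id`, `fold` of class `fold_assignment`;
#'   attributes `scheme` and (tissue scheme) `groups` naming the folds.
#' @export
make_folds <- function(labeled, scheme = c("random_stratified", "tissue"),
                       cell_meta = NULL, k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  labeled <- ensure_instance_ids(labeled)
  n <- nrow(labeled)
  fold <- integer(n)
  groups <- NULL
  if (scheme == "random_stratified") {
    for (cl in unique(labeled$label)) {
      idx <- which(labeled$label == cl)
      idx <- with_seed(seed + match(cl, sort(unique(labeled$label))),
                       sample(idx))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    if (is.null(cell_meta))
      dacs_abort("tissue scheme needs `cell_meta` (CELL_LINE, TISSUE)")
    tissue <- cell_meta$TISSUE[match(labeled$cell_line, cell_meta$CELL_LINE)]
    if (anyNA(tissue))
      dacs_abort("cell line(s) without a tissue mapping: %s",
                 paste(utils::head(unique(labeled$cell_line[is.na(tissue)]), 5L),
                       collapse = ", "))
    groups <- sort(unique(cell_meta$TISSUE))
    fold <- match(tissue, groups)
  }
  out <- data.frame(instance_id = labeled$instance_id, fold = fold,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  attr(out, "groups") <- groups
  class(out) <- c("fold_assignment", "data.frame")
  out
}

#' Classifier configuration
#'
#' Returns the tree-ensemble settings used for full-scale runs — RF:
#' 300 trees, minimum 85 samples per leaf, sqrt-of-features per split,
#' balanced class weights; GBT: 650 boosting stages, minimum 120
#' samples per leaf, sqrt-of-features per split, learning rate 0.28,
#' maximum depth 5 — with every value overridable (small cohorts need
#' far smaller leaf minima). Overrides are recorded in the
#' configuration and surfaced in evaluation reports.
#'
#' @param name `"RF"` or `"GBT"`.
#' @param ... Named overrides of the listed settings.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(name = c("RF", "GBT"), ...) {
  name <- match.arg(name)
  cfg <- switch(name,
    RF = list(name = "RF", n_trees = 300L, min_leaf = 85L,
              max_features = "sqrt", class_weight = "balanced"),
    GBT = list(name = "GBT", n_stages = 650L, min_leaf = 120L,
               max_features = "sqrt", learning_rate = 0.28, max_depth = 5L))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    dacs_abort("unknown %s setting(s): %s", name, paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$overridden <- names(dots)
  class(cfg) <- "classifier_config"
  cfg
}

# Train on (X, y) and return P(synergistic) for newX. y is a character
# vector with values "synergistic"/"antagonistic".
fit_predict <- function(X, y, newX, config, seed = 1L) {
  y <- factor(y, levels = c("antagonistic", "synergistic"))
  p <- ncol(X)
  mtry <- max(1L, floor(sqrt(p)))
  if (config$name == "RF") {
    cw <- if (identical(config$class_weight, "balanced")) {
      tab <- table(y)
      as.numeric(length(y) / (length(tab) * tab))
    } else NULL
    fit <- ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = config$n_trees,
      min.node.size = config$min_leaf,
      mtry = mtry,
      class.weights = cw,
      seed = seed, num.threads = 1L, verbose = FALSE)
    predict(fit, data = newX, num.threads = 1L)$predictions[, "synergistic"]
  } else if (config$name == "GBT") {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "synergistic"))
    params <- list(objective = "binary:logistic",
                   eta = config$learning_rate,
                   max_depth = config$max_depth,
                   min_child_weight = config$min_leaf,
                   colsample_bynode = mtry / p,
                   nthread = 1L,
                   seed = seed)
    bst <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = config$n_stages, verbose = 0)
    predict(bst, xgboost::xgb.DMatrix(newX))
  } else dacs_abort("unknown classifier '%s'", config$name)
}

#' Classification metrics from a confusion table
#'
#' @param tp,fn,fp,tn Confusion counts with synergistic as the positive
#'   class.
#' @return Named list: `acc`, `tpr`, `fpr`, `ppv`, `mcc`, `f1`
#'   (undefined ratios are `NA`).
#' @export
metrics_from_confusion <- function(tp, fn, fp, tn) {
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  ppv <- div(tp, tp + fp)
  tpr <- div(tp, tp + fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    acc = div(tp + tn, tp + tn + fp + fn),
    tpr = tpr,
    fpr = div(fp, fp + tn),
    ppv = ppv,
    mcc = if (denom == 0) NA_real_ else (tp * tn - fp * fn) / denom,
    f1  = if (is.na(ppv) || is.na(tpr) || ppv + tpr == 0) NA_real_
          else 2 * ppv * tpr / (ppv + tpr))
}

binary_metrics <- function(truth, prob, threshold = 0.5) {
  pos <- truth == "synergistic"
  pred <- prob >= threshold
  m <- metrics_from_confusion(tp = sum(pred & pos), fn = sum(!pred & pos),
                              fp = sum(pred & !pos), tn = sum(!pred & !pos))
  m$auc <- if (length(unique(truth)) < 2L) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = prob,
      levels = c("antagonistic", "synergistic"), direction = "<",
      quiet = TRUE)))
  m
}

#' Cross-validated evaluation with augmented-train / original-validate
#'
#' Runs k rounds of cross-validation under the leakage discipline the
#' augmentation method requires: in each round the model is trained on
#' the original instances of the training folds — plus, under
#' `condition = "augmented"`, ratio-preserving augmented instances
#' derived *only* from those training-fold parents — and validated on
#' the untouched original instances of the held-out fold. Augmented
#' copies of validation instances can therefore never leak into
#' training; the constraint is asserted per fold.
#'
#' @param labeled Labeled original instances.
#' @param folds A [make_folds()] assignment for `labeled`.
#' @param pool Labeled augmented instances (with `parent_id`); may be
#'   `NULL` under `condition = "original"`.
#' @param library,expression,dim,cell_seed Feature inputs, see
#'   [build_features()].
#' @param config A [classifier_config()].
#' @param condition `"original"` (plain CV) or `"augmented"`.
#' @param seed Seed for classifier fitting and pool selection.
#' @return Data frame of class `eval_report`: one row per fold plus a
#'   `"mean"` row averaging the folds, columns `ACC`, `TPR`, `FPR`,
#'   `PPV`, `AUC`, `MCC`, `F1`, `n_train`, `n_validate`.
#' @export
run_cv <- function(labeled, folds, pool = NULL, library, expression,
                   config = classifier_config("RF"),
                   condition = c("original", "augmented"),
                   dim = 300L, cell_seed = 1L, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "classifier_config"))
  labeled <- ensure_instance_ids(labeled)
  if (!setequal(folds$instance_id, labeled$instance_id))
    dacs_abort("fold assignment does not match the labeled instances")
  if (condition == "augmented" && is.null(pool))
    dacs_abort("`condition = \"augmented\"` needs an augmented `pool`")
  fold_of <- folds$fold[match(labeled$instance_id, folds$instance_id)]

  all_inst <- if (!is.null(pool) && nrow(pool)) {
    keep <- intersect(names(labeled), names(pool))
    rbind(as.data.frame(labeled)[, keep, drop = FALSE],
          as.data.frame(pool)[, keep, drop = FALSE])
  } else as.data.frame(labeled)
  feats <- build_features(all_inst, library, expression, dim, cell_seed)
  n_orig <- nrow(labeled)

  rows <- list()
  for (f in sort(unique(fold_of))) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    train_ids <- labeled$instance_id[tr]
    if (condition == "augmented") {
      pidx <- which(pool$parent_id %in% train_ids)
      # leakage guard: no selected augmented instance may descend from a
      # validation-fold parent
      if (any(pool$parent_id[pidx] %in% labeled$instance_id[va]))
        dacs_abort("leakage: augmented training instance with a validation-fold parent")
      sub_pool <- pool[pidx, , drop = FALSE]
      aug_train <- ratio_preserving_augment(labeled[tr, , drop = FALSE],
                                            sub_pool, seed = seed + f)
      train_rows <- c(tr, n_orig + pidx[match(aug_train$instance_id[-seq_along(tr)],
                                              pool$instance_id[pidx])])
      y_train <- aug_train$label
    } else {
      train_rows <- tr
      y_train <- labeled$label[tr]
    }
    prob <- fit_predict(feats[train_rows, , drop = FALSE], y_train,
                        feats[va, , drop = FALSE], config, seed = seed + f)
    m <- binary_metrics(labeled$label[va], prob)
    rows[[as.character(f)]] <- data.frame(
      fold = as.character(f), ACC = m$acc, TPR = m$tpr, FPR = m$fpr,
      PPV = m$ppv, AUC = m$auc, MCC = m$mcc, F1 = m$f1,
      n_train = length(train_rows), n_validate = length(va),
      stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("ACC", "TPR", "FPR", "PPV", "AUC", "MCC", "F1")
  mean_row <- per_fold[1, , drop = FALSE]
  mean_row$fold <- "mean"
  mean_row[metric_cols] <- lapply(per_fold[metric_cols],
                                  function(v) mean(v, na.rm = TRUE))
  mean_row$n_train <- mean(per_fold$n_train)
  mean_row$n_validate <- sum(per_fold$n_validate)
  out <- rbind(per_fold, mean_row)
  rownames(out) <- NULL
  attr(out, "classifier") <- config$name
  attr(out, "condition") <- condition
  attr(out, "config") <- config
  attr(out, "scheme") <- attr(folds, "scheme")
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("eval_report: %s, %s data, %s CV\n",
              attr(x, "classifier"), attr(x, "condition"),
              attr(x, "scheme") %||% "unknown"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
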