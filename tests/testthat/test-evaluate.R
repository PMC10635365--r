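small_cohort <- function(seed = 17L) {
  generate_cohort(cohort_spec(
    n_clusters = 4L, drugs_per_cluster = 3L, n_candidates = 8L,
    n_cell_lines = 10L, n_genes = 60L, n_instances = 120L,
    universe_size = 40L, targets_per_cluster = 6L, seed = seed))
}

test_that("drug embeddings fold fingerprints by fixed index hashing", {
  fp <- rep(0, 1024); fp[c(1, 301, 601, 901, 2, 5)] <- 1
  e <- embed_drug(fp)
  expect_length(e, 300)
  # bits 1, 301, 601, 901 all fold into component 1
  expect_equal(e[1], 4)
  expect_equal(e[2], 1)
  expect_equal(e[5], 1)
  expect_equal(sum(e), sum(fp))
  # determinism and identity on identical fingerprints
  expect_identical(embed_drug(fp), embed_drug(fp))
  # hand-folded counts on a full random pattern
  set.seed(9)
  fp2 <- rbinom(1024, 1, 0.1)
  hand <- vapply(1:300, function(k)
    sum(fp2[seq_along(fp2)[((seq_along(fp2) - 1) %% 300) + 1 == k]]), 0)
  expect_equal(embed_drug(fp2), hand)
  # pluggable embedder contract is enforced
  expect_error(embed_drug(fp, embedder = function(x) 1:10), "300")
})

test_that("cell embeddings are reproducible seeded projections", {
  x <- rnorm(60)
  expect_identical(embed_cell(x, seed = 4L), embed_cell(x, seed = 4L))
  expect_false(isTRUE(all.equal(embed_cell(x, seed = 4L),
                                embed_cell(x, seed = 5L))))
  # a unit basis vector picks out one projection-matrix column
  e7 <- embed_cell(replace(rep(0, 60), 7, 1), seed = 4L)
  P <- dacsaug:::projection_matrix(60, 300L, 4L)
  expect_equal(e7, unname(P[, 7]))
})

test_that("feature vectors concatenate drug A, drug B and cell blocks", {
  co <- small_cohort()
  X <- build_features(co$instances[1:5, ], co$drugs, co$expression, dim = 300L)
  expect_equal(dim(X), c(5L, 900L))
  expect_true(all(is.finite(X)))
  i1 <- co$instances[1, ]
  expect_equal(unname(X[1, 1:300]),
               embed_drug(co$drugs$fingerprints[i1$drug_a, ]))
  expect_equal(unname(X[1, 301:600]),
               embed_drug(co$drugs$fingerprints[i1$drug_b, ]))
  expect_equal(unname(X[1, 601:900]),
               embed_cell(co$expression[, i1$cell_line], seed = 1L))
  expect_error(build_features(data.frame(drug_a = "zz", drug_b = "yy",
                                         cell_line = "CL01"),
                              co$drugs, co$expression), "missing from")
})

test_that("stratified folds preserve class counts within one instance", {
  lab <- data.frame(instance_id = sprintf("I%03d", 1:100),
                    cell_line = "CL01",
                    label = rep(c("synergistic", "antagonistic"), c(76, 24)),
                    stringsAsFactors = FALSE)
  f <- make_folds(lab, "random_stratified", k = 5L, seed = 2L)
  per <- table(lab$label[match(f$instance_id, lab$instance_id)], f$fold)
  expect_true(all(per["synergistic", ] %in% 15:16))
  expect_true(all(per["antagonistic", ] %in% 4:5))
  # partition: every instance exactly once
  expect_setequal(f$instance_id, lab$instance_id)
  # seed reproducibility
  expect_identical(f, make_folds(lab, "random_stratified", k = 5L, seed = 2L))
  expect_false(identical(f$fold, make_folds(lab, "random_stratified",
                                            k = 5L, seed = 3L)$fold))
})

test_that("tissue folds are exactly the tissue groups", {
  co <- small_cohort()
  lab <- label_instances(co$instances)
  f <- make_folds(lab, "tissue", cell_meta = co$cells)
  groups <- attr(f, "groups")
  expect_setequal(groups, unique(co$cells$TISSUE))
  tis <- co$cells$TISSUE[match(lab$cell_line, co$cells$CELL_LINE)]
  expect_equal(groups[f$fold], tis)
  # unmapped cell line is an error
  meta2 <- co$cells[-1, ]
  lab_bad <- lab[lab$cell_line == co$cells$CELL_LINE[1], ]
  expect_error(make_folds(lab_bad, "tissue", cell_meta = meta2), "tissue mapping")
})

test_that("classifier configurations carry the full-scale settings with overrides", {
  rf <- classifier_config("RF")
  expect_equal(rf[c("n_trees", "min_leaf", "max_features", "class_weight")],
               list(n_trees = 300L, min_leaf = 85L, max_features = "sqrt",
                    class_weight = "balanced"))
  gbt <- classifier_config("GBT")
  expect_equal(gbt[c("n_stages", "min_leaf", "max_features", "learning_rate",
                     "max_depth")],
               list(n_stages = 650L, min_leaf = 120L, max_features = "sqrt",
                    learning_rate = 0.28, max_depth = 5L))
  ov <- classifier_config("RF", min_leaf = 5L)
  expect_equal(ov$min_leaf, 5L)
  expect_equal(ov$overridden, "min_leaf")
  expect_error(classifier_config("SVM"))
  expect_error(classifier_config("RF", gamma = 1), "unknown")
})

test_that("classification metrics match direct formula evaluation", {
  m <- metrics_from_confusion(tp = 8, fn = 2, fp = 3, tn = 7)
  expect_equal(m$acc, 0.75)
  expect_equal(m$tpr, 0.8)
  expect_equal(m$fpr, 0.3)
  expect_equal(m$ppv, 8 / 11)
  expect_equal(m$mcc, (8 * 7 - 3 * 2) / sqrt(11 * 10 * 10 * 9), tolerance = 1e-6)
  expect_equal(m$f1, 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8), tolerance = 1e-12)
  expect_equal(round(m$mcc, 4), 0.5025)
  expect_equal(round(m$f1, 3), 0.762)
  # consistency identities
  expect_equal(m$acc, (8 + 7) / 20)
  # MCC flips sign under class swap
  m2 <- metrics_from_confusion(tp = 7, fn = 3, fp = 2, tn = 8)
  expect_equal(m2$mcc, m$mcc)   # symmetric swap of both classes
  m3 <- metrics_from_confusion(tp = 3, fn = 7, fp = 8, tn = 2)
  expect_equal(m3$mcc, -m$mcc)
  # degenerate margins give NA, not an error
  expect_true(is.na(metrics_from_confusion(0, 0, 0, 10)$tpr))
})

test_that("AUC from continuous scores matches a rank-based oracle", {
  set.seed(31)
  truth <- rep(c("synergistic", "antagonistic"), c(30, 20))
  prob <- ifelse(truth == "synergistic", rnorm(50, 0.6, 0.2), rnorm(50, 0.4, 0.2))
  got <- dacsaug:::binary_metrics(truth, prob)$auc
  # Mann-Whitney oracle
  pos <- prob[truth == "synergistic"]; neg <- prob[truth != "synergistic"]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  expect_equal(got, mean(cmp), tolerance = 1e-12)
})

test_that("cross-validation enforces the augmented-train / original-validate discipline", {
  co <- small_cohort()
  lab <- label_instances(co$instances)
  subs <- build_substitute_map(co$drugs, co$candidates, co$universe, 0.4)
  aug <- suppressWarnings(augment_dataset(co$instances, subs))
  pool <- label_instances(aug[aug$provenance == "augmented", ])
  liball <- drug_library(
    c(co$drugs$drug_id, co$candidates$drug_id),
    fingerprints = rbind(co$drugs$fingerprints, co$candidates$fingerprints),
    targets = c(co$drugs$targets, co$candidates$targets))
  folds <- make_folds(lab, "tissue", cell_meta = co$cells)
  cfg <- classifier_config("RF", n_trees = 60L, min_leaf = 5L)
  rep0 <- run_cv(lab, folds, NULL, liball, co$expression, cfg,
                 condition = "original", seed = 5L)
  expect_s3_class(rep0, "eval_report")
  expect_equal(rep0$fold[nrow(rep0)], "mean")
  # validation sets partition the labeled originals
  expect_equal(sum(rep0$n_validate[rep0$fold != "mean"]), nrow(lab))
  metric_cols <- c("ACC", "TPR", "FPR", "PPV", "AUC")
  expect_true(all(as.matrix(rep0[metric_cols]) >= 0 &
                  as.matrix(rep0[metric_cols]) <= 1, na.rm = TRUE))
  rep1 <- run_cv(lab, folds, pool, liball, co$expression, cfg,
                 condition = "augmented", seed = 5L)
  # augmented training enlarges every fold's training set
  expect_true(all(rep1$n_train >= rep0$n_train))
  # determinism: identical seeds give identical reports
  rep1b <- run_cv(lab, folds, pool, liball, co$expression, cfg,
                  condition = "augmented", seed = 5L)
  expect_identical(as.data.frame(rep1), as.data.frame(rep1b))
  # condition=augmented without a pool is refused
  expect_error(run_cv(lab, folds, NULL, liball, co$expression, cfg,
                      condition = "augmented"), "pool")
})

test_that("no augmented training instance descends from a validation parent in any fold or scheme", {
  co <- small_cohort(23L)
  lab <- label_instances(co$instances)
  subs <- build_substitute_map(co$drugs, co$candidates, co$universe, 0.4)
  aug <- suppressWarnings(augment_dataset(co$instances, subs))
  pool <- label_instances(aug[aug$provenance == "augmented", ])
  for (scheme in c("random_stratified", "tissue")) {
    folds <- make_folds(lab, scheme, cell_meta = co$cells, seed = 7L)
    fold_of <- folds$fold[match(lab$instance_id, folds$instance_id)]
    for (f in sort(unique(fold_of))) {
      train_ids <- lab$instance_id[fold_of != f]
      val_ids <- lab$instance_id[fold_of == f]
      selected <- ratio_preserving_augment(lab[fold_of != f, ],
                                           pool[pool$parent_id %in% train_ids, ],
                                           seed = f)
      parents <- selected$parent_id[!is.na(selected$parent_id)]
      expect_length(intersect(parents, val_ids), 0)
    }
  }
})
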