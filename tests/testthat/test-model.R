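test_that("negative sampling honours the 1:8 ratio and the seed", {
  pool <- generate_fragments(synthetic_config(n = 3, n_pos = 0, n_neg = 1000,
                                              seed = 1))
  idx <- sample_negatives(112, pool, ratio = 8, seed = 5)
  expect_length(idx, 896L)
  expect_identical(idx, sample_negatives(112, pool, ratio = 8, seed = 5))
  expect_false(identical(idx, sample_negatives(112, pool, ratio = 8, seed = 6)))
  expect_warning(out <- sample_negatives(50, pool[1:100, ], ratio = 8, seed = 1),
                 "whole pool")
  expect_length(out, 100L)
  expect_error(sample_negatives(5, pool[0, ], seed = 1), "empty")
})

test_that("a separable subgroup model fits its training data", {
  # a motif subgroup holds ONE substrate class: a single rule-set world
  one_motif <- synthetic_config(n = 10, n_pos = 120, n_neg = 400, seed = 21,
                                rules = list(list(rules = lapply(
                                  c(4, 7, 10), motif_rule, group = "basic",
                                  prob = 0.95), weight = 1)))
  ds <- generate_fragments(one_motif)
  pos <- positives_of(ds)
  ctx <- build_feature_context(pos, c("aac", "pssm"))
  feat <- encode_features(ds, c("aac", "pssm"), ctx)
  y <- ds$label == "positive"
  m <- train_subgroup_model(feat[y, , drop = FALSE], feat[!y, , drop = FALSE],
                            id = "PalmT")
  p <- mddpalm:::subgroup_probability(m, feat)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(y, p)$auc, 0.95)   # training-set separability
  expect_error(train_subgroup_model(feat[y, , drop = FALSE],
                                    feat[0, , drop = FALSE]),
               "both classes")
})

test_that("first-layer probability matrix preserves order and shape", {
  ds <- generate_fragments(three_rule_config(22, n_pos = 60, n_neg = 200))
  pos <- positives_of(ds)
  ctx <- build_feature_context(pos, "aac")
  feat <- encode_features(ds, "aac", ctx)
  y <- ds$label == "positive"
  mk <- function(id, seed) {
    neg <- which(!y)[sample_negatives(30, ds[!y, ], ratio = 2, seed = seed)]
    train_subgroup_model(feat[which(y)[1:30], , drop = FALSE],
                         feat[neg, , drop = FALSE], id = id)
  }
  models <- list(mk("Palm1", 1), mk("Palm2", 2), mk("Palm3", 3))
  P <- first_layer_probabilities(feat, models)
  expect_equal(dim(P), c(nrow(ds), 3L))
  expect_equal(colnames(P), c("Palm1", "Palm2", "Palm3"))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(first_layer_probabilities(feat, models[1])[, 1],
               mddpalm:::subgroup_probability(models[[1]], feat))
  # row order follows fragment order
  P2 <- first_layer_probabilities(feat[nrow(ds):1, , drop = FALSE], models)
  expect_equal(P2[nrow(ds), ], P[1, ])
})

test_that("the two-layer model learns a planted multi-position world", {
  tr <- generate_fragments(three_rule_config(11))
  te <- generate_fragments(three_rule_config(99, n_pos = 150, n_neg = 1200))
  model <- train_two_layer(tr, mdd_cfg = mdd_config(max_cluster_size = 120),
                           seed = 5)
  expect_s3_class(model, "two_layer_model")
  expect_gt(length(model$subgroup_models), 1L)
  expect_equal(names(model$subgroup_models), names(mdd_leaves(model$tree)))

  p <- predict_two_layer(model, te$fragment)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(te$label, p)$auc, 0.85)

  # prediction is stateless: order permutation permutes the output
  perm <- sample(nrow(te))
  expect_equal(predict_two_layer(model, te$fragment[perm]), p[perm],
               tolerance = 1e-12)

  # stacking sanity: the stacked AUC is within 0.05 of the best subgroup
  feat <- encode_features(te, model$recipe, model$context)
  fl <- first_layer_probabilities(feat, model$subgroup_models)
  best_single <- max(apply(fl, 2, function(col) roc_auc(te$label, col)$auc))
  expect_gte(roc_auc(te$label, p)$auc, best_single - 0.05)
})

test_that("training is reproducible given the seed", {
  tr <- generate_fragments(three_rule_config(31, n_pos = 120, n_neg = 960))
  probe <- random_fragments(30, seed = 1)
  m1 <- train_two_layer(tr, mdd_cfg = mdd_config(max_cluster_size = 80),
                        seed = 9, crossfit_folds = 3)
  m2 <- train_two_layer(tr, mdd_cfg = mdd_config(max_cluster_size = 80),
                        seed = 9, crossfit_folds = 3)
  expect_identical(predict_two_layer(m1, probe), predict_two_layer(m2, probe))
})

test_that("model archives round-trip through text serialization", {
  tr <- generate_fragments(three_rule_config(41, n_pos = 120, n_neg = 960))
  model <- train_two_layer(tr, mdd_cfg = mdd_config(max_cluster_size = 80),
                           seed = 3, crossfit_folds = 3)
  dir <- tempfile("archive")
  save_model(model, dir)
  back <- load_model(dir)
  probe <- random_fragments(40, seed = 2)
  expect_equal(predict_two_layer(back, probe),
               predict_two_layer(model, probe), tolerance = 1e-8)
  expect_equal(names(back$subgroup_models), names(model$subgroup_models))
  expect_error(load_model(tempfile()), "manifest")
})

test_that("predict_sites scores every cysteine exactly once", {
  tr <- generate_fragments(three_rule_config(51, n_pos = 120, n_neg = 960))
  model <- train_two_layer(tr, mdd_cfg = mdd_config(max_cluster_size = 200),
                           seed = 3, crossfit_folds = 3)
  prot <- c(noC = "MAGLLV", twoC = "MACGGGGGGGGGGCK")
  res <- predict_sites(prot, model)
  expect_equal(nrow(res), 2L)
  expect_equal(res$protein_id, c("twoC", "twoC"))
  expect_setequal(res$position, c(3L, 14L))
  expect_true(all(res$residue == "C"))
  expect_true(all(res$motif_subgroup %in% names(model$subgroup_models)))
  # threshold 0 calls everything
  expect_true(all(predict_sites(prot, model, threshold = 0)$call))
  # no cysteines anywhere -> empty frame with the full column set
  res0 <- predict_sites(c(x = "MAGL"), model)
  expect_equal(nrow(res0), 0L)
  expect_true(all(c("protein_id", "position", "probability", "call",
                    "motif_subgroup") %in% names(res0)))
  expect_error(predict_sites(character(0), model), "no protein")
})

test_that("grid search returns a grid member, ties to the cheaper model", {
  ds <- generate_fragments(three_rule_config(61, n_pos = 60, n_neg = 240))
  one <- grid_search(ds, gammas = 0.01, costs = 2, recipe = "aac",
                     folds = 2, seed = 1)
  expect_equal(one$gamma, 0.01)
  expect_equal(one$cost, 2)

  res <- grid_search(ds, gammas = c(0.005, 0.05), costs = c(1, 4),
                     recipe = "aac", folds = 2, seed = 1)
  grid <- attr(res, "results")
  expect_equal(nrow(grid), 4L)
  expect_true(res$gamma %in% c(0.005, 0.05) && res$cost %in% c(1, 4))
  # reproducible under the same seed
  res2 <- grid_search(ds, gammas = c(0.005, 0.05), costs = c(1, 4),
                      recipe = "aac", folds = 2, seed = 1)
  expect_identical(attr(res2, "results"), grid)
})
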