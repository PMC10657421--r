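test_that("leave-sgRNA-out folds never share guides and partition the data", {
  d <- tiny_labeled_dataset(n_guides = 10, per_guide = 30)
  plan <- split_dataset(d, "lso", k = 5, seed = 3)
  all_test <- integer(0)
  for (f in plan$folds) {
    expect_length(intersect(unique(d$group[f$train]),
                            unique(d$group[f$test])), 0)
    all_test <- c(all_test, f$test)
  }
  expect_setequal(all_test, seq_len(nrow(d)))
  expect_equal(anyDuplicated(all_test), 0L)
})

test_that("stratified leave-group-out folds balance each label stratum", {
  d <- tiny_labeled_dataset(n_guides = 8, per_guide = 50)
  k <- 5
  plan <- split_dataset(d, "lgo", k = k, seed = 9)
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(all_test, seq_len(nrow(d)))
  # counting oracle: per label stratum, fold sizes differ by at most 1
  for (lv in c(0, 1)) {
    sizes <- vapply(plan$folds,
                    function(f) sum(d$label[f$test] == lv), numeric(1))
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("split plans are reproducible and guard their preconditions", {
  d <- tiny_labeled_dataset(n_guides = 6, per_guide = 20)
  p1 <- split_dataset(d, "lso", k = 3, seed = 7)
  p2 <- split_dataset(d, "lso", k = 3, seed = 7)
  expect_identical(p1$folds, p2$folds)
  expect_error(split_dataset(d, "lso", k = 7, seed = 1), "distinct guides")
})

test_that("fold models fit a separable toy exactly and ensemble size is k", {
  # labels are a deterministic function of one fingerprint slot: a
  # mismatch at position 20 marks the (rare) positive class, mirroring
  # the imbalance direction of real candidate sets
  set.seed(15)
  pairs <- lapply(1:200, function(i) random_pair(sample(0:4, 1)))
  d <- data.frame(guide = vapply(pairs, `[[`, "", "guide"),
                  target = vapply(pairs, `[[`, "", "target"),
                  stringsAsFactors = FALSE)
  d$label <- as.integer(substr(d$guide, 20, 20) != substr(d$target, 20, 20))
  d$group <- d$guide
  plan <- split_dataset(d, "lgo", k = 4, seed = 2)
  ens <- train_ensemble(d, plan, encoder = "onehot", nrounds = 30, seed = 2)
  expect_length(ens$models, 4)
  for (f in seq_along(plan$folds)) {
    tr <- plan$folds[[f]]$train
    p <- predict_ensemble(ens, d$guide[tr], d$target[tr])
    # the ensemble mean includes models that saw these rows in training;
    # on separable data every fold model individually is perfect, so the
    # mean classifies the training rows perfectly too
    expect_equal(as.integer(p > 0.5), d$label[tr])
  }
})

test_that("single-class training folds are rejected with advice", {
  d <- tiny_labeled_dataset(n_guides = 6, per_guide = 20)
  d$label <- 0
  d$label[1] <- 1
  plan <- split_dataset(d, "lso", k = 3, seed = 1)
  expect_error(train_ensemble(d, plan, encoder = "onehot", nrounds = 5),
               "single class")
})

test_that("ensemble prediction is the mean of fold-model probabilities", {
  d <- tiny_labeled_dataset(n_guides = 8, per_guide = 30)
  plan <- split_dataset(d, "lgo", k = 3, seed = 5)
  ens <- train_ensemble(d, plan, encoder = "onehot", nrounds = 20, seed = 5)
  idx <- 1:25
  p <- predict_ensemble(ens, d$guide[idx], d$target[idx])
  X <- t(mapply(encode_onehot, d$guide[idx], d$target[idx]))
  rownames(X) <- NULL
  per_model <- sapply(ens$models, function(m) predict(m, X))
  expect_equal(p, rowMeans(per_model), tolerance = 1e-7)
  expect_true(all(p >= 0 & p <= 1))
  # single-model ensemble predicts that model's probability
  solo <- ens
  solo$models <- ens$models[1]
  expect_equal(predict_ensemble(solo, d$guide[idx], d$target[idx]),
               predict(ens$models[[1]], X), tolerance = 1e-7)
})

test_that("AUC evaluation matches exhaustive oracles, including ties", {
  set.seed(23)
  for (rep in 1:4) {
    n <- 50
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0 || sum(labels) == n) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    got <- evaluate_scores(scores, labels)
    expect_equal(got$roc_auc, pairwise_roc_auc(scores, labels))
    expect_equal(got$pr_auc, stepwise_pr_auc(scores, labels))
  }
})

test_that("AUC degenerate cases behave analytically", {
  labels <- c(1, 1, 0, 0, 0)
  perfect <- evaluate_scores(c(0.9, 0.8, 0.3, 0.2, 0.1), labels)
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$pr_auc, 1)
  flat <- evaluate_scores(rep(0.5, 5), labels)
  expect_equal(flat$roc_auc, 0.5)
  expect_equal(flat$pr_auc, 0.4)  # prevalence
  expect_error(evaluate_scores(1:5, rep(1, 5)), "both classes")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  labels <- rbinom(80, 1, 0.4)
  scores <- runif(80) + labels * 0.3
  got <- evaluate_scores(scores, labels)$roc_auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("SHAP attributions are additive and concentrate correctly", {
  d <- tiny_labeled_dataset(n_guides = 8, per_guide = 40, seed = 5)
  # make the label depend only on position 20 match so importance must
  # concentrate in that position block
  d$label <- as.integer(substr(d$guide, 20, 20) != substr(d$target, 20, 20))
  if (mean(d$label) %in% c(0, 1)) skip("degenerate fixture")
  plan <- split_dataset(d, "lgo", k = 3, seed = 8)
  ens <- train_ensemble(d, plan, encoder = "onehot", nrounds = 25, seed = 8)
  sm <- shap_summary(ens, d)
  expect_true(all(sm$importance >= 0))
  pos_importance <- colSums(sm$importance)
  expect_equal(unname(which.max(pos_importance)), 20)
  expect_gt(pos_importance[20] / sum(pos_importance), 0.9)
  # per-cell sample counts partition the dataset at every position
  expect_equal(unname(rowSums(sm$counts)), rep(nrow(d), 20))

  # additivity: mean fold contributions + bias == mean fold margin
  X <- t(mapply(encode_onehot, d$guide, d$target)); rownames(X) <- NULL
  margins <- rowMeans(sapply(ens$models,
                             function(m) predict(m, X, outputmargin = TRUE)))
  contrib <- Reduce(`+`, lapply(ens$models, function(m)
    predict(m, X, predcontrib = TRUE))) / length(ens$models)
  expect_equal(rowSums(contrib), margins, tolerance = 1e-4)
})

test_that("a mismatched feature table is refused at prediction time", {
  d <- tiny_labeled_dataset(n_guides = 6, per_guide = 25)
  tab <- simulate_feature_table(seed = 3)
  plan <- split_dataset(d, "lgo", k = 3, seed = 4)
  ens <- train_ensemble(d, plan, encoder = "fp", table = tab, nrounds = 10,
                        seed = 4)
  other <- simulate_feature_table(seed = 99)
  expect_error(predict_ensemble(ens, d$guide[1], d$target[1], other),
               "differs")
})
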