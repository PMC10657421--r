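#' Build a cross-validation split plan
#'
#' Two modes mirror the two generalization questions for off-target
#' models. `"lgo"` (leave-group-out) holds out 1/k of the individual
#' sites, stratified on the label, so train and test share guides but not
#' sites. `"lso"` (leave-sgRNA-out) holds out 1/k of the guides with all
#' their sites, so no guide appears on both sides of any fold -- the
#' stricter test of generalization to unseen guides.
#'
#' @param data Labeled dataset (data frame with `label` and `group`; see
#'   [read_dataset()]), or anything with those columns.
#' @param mode `"lgo"` or `"lso"`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the plan is reproducible given the seed.
#' @return An object of class `split_plan`: list with `folds` (list of
#'   `list(train, test)` index vectors), `mode`, `k`, `seed`. Test sets
#'   partition `seq_len(nrow(data))`.
#' @export
split_dataset <- function(data, mode = c("lgo", "lso"), k = 5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(k >= 2)
  label <- data$label
  group <- if (is.null(data$group)) data$guide else data$group
  n <- length(label)
  fold_of <- integer(n)
  if (mode == "lgo") {
    fold_of <- with_seed(seed, "split_lgo", {
      f <- integer(n)
      for (lv in unique(label)) {
        idx <- which(label == lv)
        idx <- idx[sample.int(length(idx))]
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
  } else {
    gs <- unique(group)
    if (length(gs) < k) {
      stop("leave-sgRNA-out needs at least k = ", k, " distinct guides, got ",
           length(gs), call. = FALSE)
    }
    fold_of <- with_seed(seed, "split_lso", {
      gs <- gs[sample.int(length(gs))]
      gfold <- rep_len(seq_len(k), length(gs))
      gfold[match(group, gs)]
    })
  }
  folds <- lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
  structure(list(folds = folds, mode = mode, k = k, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> mode=", x$mode, " k=", x$k, " seed=", x$seed, "\n",
      sep = "")
  invisible(x)
}

default_xgb_params <- function() {
  list(objective = "binary:logistic", booster = "gbtree",
       tree_method = "hist", max_depth = 6, eta = 0.3,
       min_child_weight = 1, subsample = 1, colsample_bytree = 1,
       nthread = 1)
}

#' Train a cross-validated gradient-boosted off-target classifier ensemble
#'
#' Fits one XGBoost classifier (gbtree booster, logistic objective) per
#' fold of the plan on the encoded pairs; the ensemble's prediction is the
#' mean of the fold-model probabilities. Off-target datasets are highly
#' imbalanced (active sites are typically well under 1% of candidates), so
#' by default each fold weights the positive class by its
#' negatives/positives ratio (`scale_pos_weight`); pass an explicit
#' `scale_pos_weight` in `params` to override.
#'
#' @param data Labeled dataset (columns `guide`, `target`, `label`,
#'   `group`).
#' @param plan A `split_plan` for the same dataset.
#' @param encoder `"fp"`, `"onehot"` or `"twohot"`.
#' @param table `feature_table` (required for the `"fp"` encoder).
#' @param params Named list of XGBoost parameters; merged over the
#'   package defaults (depth 6, eta 0.3, hist, single thread).
#' @param nrounds Boosting rounds per fold model.
#' @param seed Integer seed passed to XGBoost for reproducible training.
#' @return An object of class `ot_ensemble`: fold models plus the encoder
#'   id, feature ordering, hyperparameters and the split plan.
#' @export
train_ensemble <- function(data, plan, encoder = "fp", table = NULL,
                           params = list(), nrounds = 100, seed = 1) {
  stopifnot(inherits(plan, "split_plan"))
  X <- encode_dataset(data, encoder, table)
  y <- as.numeric(data$label)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  base <- modifyList(default_xgb_params(), params)
  auto_spw <- is.null(params$scale_pos_weight)
  models <- vector("list", length(plan$folds))
  for (f in seq_along(plan$folds)) {
    tr <- plan$folds[[f]]$train
    ytr <- y[tr]
    if (length(unique(ytr)) < 2) {
      stop("training fold ", f, " contains a single class; ",
           "re-split with label stratification (mode = 'lgo') or larger folds",
           call. = FALSE)
    }
    p <- base
    if (auto_spw) p$scale_pos_weight <- sum(ytr == 0) / sum(ytr == 1)
    p$seed <- seed + f
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = ytr)
    models[[f]] <- xgboost::xgb.train(params = p, data = dtr,
                                      nrounds = nrounds, verbose = 0)
  }
  structure(list(models = models, encoder = encoder,
                 feature_names = colnames(X),
                 table_hash = if (!is.null(table))
                   feature_table_hash(table) else NA_character_,
                 params = base, nrounds = nrounds, seed = seed, plan = plan),
            class = "ot_ensemble")
}

# cheap content hash so a model bundle can refuse a mismatched table
feature_table_hash <- function(table) {
  v <- c(as.numeric(table$values))
  sprintf("%.10e", sum(v * seq_along(v)) + sum(v^2))
}

#' @export
print.ot_ensemble <- function(x, ...) {
  cat("<ot_ensemble> ", length(x$models), " fold models, encoder=",
      x$encoder, ", ", length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Predict off-target activity probabilities
#'
#' Mean of the fold-model probabilities for each guide/target pair.
#'
#' @param ensemble An `ot_ensemble`.
#' @param guides,targets Pairs to score (one guide may be recycled).
#' @param table `feature_table` used at training time (for the `"fp"`
#'   encoder); its content is checked against the ensemble's record.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_ensemble <- function(ensemble, guides, targets, table = NULL) {
  stopifnot(inherits(ensemble, "ot_ensemble"))
  X <- encode_dataset(data.frame(guide = guides, target = targets,
                                 stringsAsFactors = FALSE),
                      ensemble$encoder, table)
  check_feature_order(ensemble, X, table)
  preds <- vapply(ensemble$models, function(m) predict(m, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

check_feature_order <- function(ensemble, X, table) {
  if (!identical(colnames(X), ensemble$feature_names)) {
    stop("feature ordering of the input does not match the ensemble",
         call. = FALSE)
  }
  if (ensemble$encoder == "fp" && !is.na(ensemble$table_hash) &&
      !identical(feature_table_hash(table), ensemble$table_hash)) {
    stop("feature_table content differs from the one used in training",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Pooled held-out predictions from the ensemble's own split plan
#'
#' Each site is predicted by the one fold model that did not see it in
#' training, giving an honest held-out score vector over the full dataset.
#'
#' @inheritParams train_ensemble
#' @param ensemble An `ot_ensemble` trained with `plan` on `data`.
#' @return Numeric vector aligned with `data` rows.
#' @export
predict_heldout <- function(ensemble, data, table = NULL) {
  stopifnot(inherits(ensemble, "ot_ensemble"))
  X <- encode_dataset(data, ensemble$encoder, table)
  check_feature_order(ensemble, X, table)
  out <- rep(NA_real_, nrow(X))
  for (f in seq_along(ensemble$plan$folds)) {
    te <- ensemble$plan$folds[[f]]$test
    out[te] <- predict(ensemble$models[[f]], X[te, , drop = FALSE])
  }
  out
}

#' ROC and precision-recall areas under the curve
#'
#' ROC-AUC is computed from the rank statistic (Mann-Whitney form, average
#' ranks for ties). PR-AUC is computed by step integration: thresholds
#' sweep the unique score values from high to low and the area is
#' `sum((recall_i - recall_{i-1}) * precision_i)`, which gives exactly the
#' prevalence for constant scores and 1 for perfect ranking.
#'
#' @param scores Numeric score vector (higher = more likely active).
#' @param labels 0/1 labels, both classes present.
#' @return List with `roc_auc` and `pr_auc`.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUCs", call. = FALSE)
  }
  r <- rank(scores)
  roc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # collapse tied scores into single threshold blocks
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[block_end]
  fp <- cumsum(1 - y)[block_end]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  pr <- sum(diff(c(0, recall)) * precision)
  list(roc_auc = roc, pr_auc = pr)
}

#' Shapley attribution summary of a trained ensemble
#'
#' Runs the tree-SHAP algorithm of the underlying XGBoost models over the
#' encoded dataset, averages the per-sample attributions across fold
#' models, and aggregates them two ways: `importance`, the mean absolute
#' attribution per fingerprint slot reshaped to features x positions (its
#' column sums are the per-position importances); and `per_type_mean`, the
#' mean signed attribution of each (position, base-pair type, feature)
#' cell taken over the samples that actually carry that base-pair type at
#' that position. The latter is the quantity the per-position score map is
#' built from.
#'
#' @inheritParams predict_heldout
#' @return An object of class `shap_summary`: list with `importance`
#'   (F x 20 matrix, feature rownames, `p1..p20` colnames),
#'   `per_type_mean` (array 20 x 16 x F; `NA` where a cell has no
#'   samples), `counts` (20 x 16 sample counts per cell), `base_value`
#'   (mean model bias), `n` (dataset size) and `feature_names`.
#' @export
shap_summary <- function(ensemble, data, table = NULL) {
  stopifnot(inherits(ensemble, "ot_ensemble"))
  X <- encode_dataset(data, ensemble$encoder, table)
  check_feature_order(ensemble, X, table)
  n <- nrow(X)
  ncols <- ncol(X)
  contrib <- matrix(0, n, ncols)
  bias <- 0
  for (m in ensemble$models) {
    ctr <- predict(m, X, predcontrib = TRUE)
    contrib <- contrib + ctr[, seq_len(ncols), drop = FALSE]
    bias <- bias + mean(ctr[, ncols + 1L])
  }
  contrib <- contrib / length(ensemble$models)
  bias <- bias / length(ensemble$models)

  blocks <- infer_position_blocks(ensemble$encoder, ncols)
  FF <- blocks$block_size
  importance <- matrix(colMeans(abs(contrib)), nrow = FF, ncol = 20)
  rownames(importance) <- sub("^p1\\.", "", ensemble$feature_names[1:FF])
  colnames(importance) <- paste0("p", 1:20)

  idx <- matrix(0L, n, 20)
  for (i in seq_len(n)) {
    idx[i, ] <- pair_bp_indices(normalize_seq(data$guide[i], 20),
                                normalize_seq(data$target[i], 20))
  }
  per_type <- array(NA_real_, dim = c(20, 16, FF))
  counts <- matrix(0L, 20, 16, dimnames = list(paste0("p", 1:20), bp_types()))
  for (p in 1:20) {
    cols <- ((p - 1L) * FF + 1L):(p * FF)
    grp <- factor(idx[, p], levels = 1:16)
    cnt <- as.integer(table(grp))
    counts[p, ] <- cnt
    sums <- rowsum(contrib[, cols, drop = FALSE], group = grp)
    present <- which(cnt > 0)
    per_type[p, present, ] <- sums[as.character(present), , drop = FALSE] /
      cnt[present]
  }
  structure(list(importance = importance, per_type_mean = per_type,
                 counts = counts, base_value = bias, n = n,
                 feature_names = rownames(importance)),
            class = "shap_summary")
}

# fingerprint encoders are position-major with a fixed per-position block
infer_position_blocks <- function(encoder, ncols) {
  stopifnot(ncols %% 20 == 0)
  list(block_size = as.integer(ncols / 20))
}

#' @export
print.shap_summary <- function(x, ...) {
  cat("<shap_summary> ", nrow(x$importance), " features x 20 positions, n=",
      x$n, "\n", sep = "")
  invisible(x)
}
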