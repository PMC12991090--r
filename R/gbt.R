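# Gradient-boosted decision-tree baseline on fixed per-read features.

#' Fixed per-read feature vector for the gradient-boosted baseline
#'
#' Concatenates three blocks: the 19 percentiles (5%..95%) of the read's own
#' methylation probabilities; the Pearson correlation between the read's
#' methylation and each cell type's atlas values over shared sites (NA when
#' fewer than two shared sites or zero variance); and the 19 percentiles of
#' per-CpG sample-rank values, where a CpG's rank is the fraction of its
#' site's 19 sample percentiles strictly below its methylation probability.
#'
#' @param fs A `feature_set`.
#' @param rank_method "strict" (strictly-below count / 19, default) or
#'   "midrank".
#' @return Numeric vector of length 38 + K.
#' @export
extract_gbt_features <- function(fs, rank_method = c("strict", "midrank")) {
  rank_method <- match.arg(rank_method)
  meth_sorted <- sort(fs$meth)
  own_pct <- .quantile_sorted(meth_sorted)
  cors <- vapply(seq_len(ncol(fs$atlas)), function(k) {
    v <- fs$atlas[, k]
    ok <- !is.na(v)
    if (sum(ok) < 2) return(NA_real_)
    if (stats::sd(fs$meth[ok]) == 0 || stats::sd(v[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(fs$meth[ok], v[ok])
  }, 0)
  ranks <- vapply(seq_len(fs$n_cpg), function(i) {
    q <- fs$pct[i, ]
    if (anyNA(q)) return(NA_real_)
    if (rank_method == "strict") {
      sum(q < fs$meth[i]) / 19
    } else {
      (sum(q < fs$meth[i]) + 0.5 * sum(q == fs$meth[i])) / 19
    }
  }, 0)
  ranks <- ranks[!is.na(ranks)]
  rank_pct <- if (length(ranks)) .quantile_sorted(sort(ranks)) else
    rep(NA_real_, 19)
  out <- c(own_pct, cors, rank_pct)
  names(out) <- c(paste0("own_q", seq(5, 95, 5)),
                  paste0("cor_", colnames(fs$atlas)),
                  paste0("rank_q", seq(5, 95, 5)))
  out
}

#' Hyperparameter grid for the gradient-boosted baseline
#'
#' The full sweep: max depth \{5, 7, 9, 11\}, learning rate 0.01, 15,000
#' boosting rounds with early stopping on a 10% holdout of the training
#' split, subsample ratio \{0.25, 0.5, 0.6, 0.8, 1.0\}, min child weight
#' \{3, 5, 10, 25\}, column subsample \{0.25, 0.5, 0.75, 1.0\},
#' binary-logistic objective, AUC metric. `n_configs` draws a seeded random
#' subset for desk-scale runs.
#'
#' @param n_configs Number of grid points to keep (NULL = exhaustive 320).
#' @param seed Seed for the subsample draw.
#' @param nrounds Maximum boosting rounds.
#' @param early_stopping_rounds Early-stopping patience in rounds.
#' @return `data.frame` of configurations.
#' @export
gbt_grid <- function(n_configs = NULL, seed = 1L, nrounds = 15000L,
                     early_stopping_rounds = 100L) {
  g <- expand.grid(max_depth = c(5L, 7L, 9L, 11L),
                   eta = 0.01,
                   subsample = c(0.25, 0.5, 0.6, 0.8, 1.0),
                   min_child_weight = c(3, 5, 10, 25),
                   colsample_bytree = c(0.25, 0.5, 0.75, 1.0))
  if (!is.null(n_configs) && n_configs < nrow(g)) {
    set.seed(seed)
    g <- g[sort(sample.int(nrow(g), n_configs)), , drop = FALSE]
  }
  attr(g, "nrounds") <- as.integer(nrounds)
  attr(g, "early_stopping_rounds") <- as.integer(early_stopping_rounds)
  g
}

# xgboost engine behind fit_read_classifier(engine = "xgboost").
.fit_gbt <- function(features, y, grp, split, train_cfg, grid, verbose) {
  if (is.null(grid)) grid <- gbt_grid(n_configs = 8L, seed = train_cfg$seed)
  Xall <- t(vapply(features, extract_gbt_features,
                   numeric(38 + ncol(features[[1]]$atlas))))
  tr <- which(grp == "train")
  va <- which(grp == "validation")
  if (!length(tr) || length(unique(y[tr])) < 2) {
    stop("training split needs both classes")
  }
  set.seed(train_cfg$seed)
  hold <- sample(tr, max(1L, round(0.1 * length(tr))))
  core <- setdiff(tr, hold)
  dtrain <- xgboost::xgb.DMatrix(Xall[core, , drop = FALSE],
                                 label = y[core])
  dhold <- xgboost::xgb.DMatrix(Xall[hold, , drop = FALSE],
                                label = y[hold])
  pw <- positive_weight(sum(y[tr] == 0), sum(y[tr] == 1))
  results <- NULL
  best <- NULL; best_auc <- -Inf
  for (i in seq_len(nrow(grid))) {
    params <- list(objective = "binary:logistic", eval_metric = "auc",
                   eta = grid$eta[i], max_depth = grid$max_depth[i],
                   subsample = grid$subsample[i],
                   min_child_weight = grid$min_child_weight[i],
                   colsample_bytree = grid$colsample_bytree[i],
                   scale_pos_weight = pw, nthread = 1L,
                   tree_method = "hist")
    set.seed(train_cfg$seed + i)
    bst <- xgboost::xgb.train(
      params = params, data = dtrain, nrounds = attr(grid, "nrounds"),
      evals = list(holdout = dhold),
      early_stopping_rounds = attr(grid, "early_stopping_rounds"),
      verbose = 0)
    vp <- predict(bst, Xall[va, , drop = FALSE])
    vauc <- evaluate_auc(y[va], vp)
    results <- rbind(results, cbind(grid[i, , drop = FALSE],
                                    val_auc = vauc))
    if (verbose) message(sprintf("gbt config %d/%d: val AUC %.4f", i,
                                 nrow(grid), vauc))
    if (vauc > best_auc) {
      best_auc <- vauc
      best <- bst
    }
  }
  structure(list(engine = "xgboost", booster = best,
                 model_cfg = NULL, train_cfg = train_cfg, split = split,
                 feature_subset = "all", pos_weight = pw,
                 history = results, best_epoch = NA_integer_,
                 best_val_auc = best_auc, n_train = length(tr),
                 n_validation = length(va), n_test = sum(grp == "test"),
                 sweep = results),
            class = "read_classifier")
}

.gbt_predict <- function(object, features) {
  X <- t(vapply(features, extract_gbt_features,
                numeric(38 + ncol(features[[1]]$atlas))))
  predict(object$booster, X)
}

#' Hyperparameter sweep for the gradient-boosted baseline
#'
#' Convenience wrapper over [fit_read_classifier()] with the xgboost engine:
#' runs the grid, keeps the model with the highest validation-split AUC and
#' returns it with the per-configuration AUC table attached (`$sweep`).
#'
#' @param features Labeled feature sets.
#' @param grid A [gbt_grid()] (default: 8 seeded random configurations).
#' @param ... Passed to [fit_read_classifier()].
#' @return A `read_classifier` with engine "xgboost".
#' @export
sweep_and_train <- function(features, grid = NULL, ...) {
  fit_read_classifier(features, engine = "xgboost", gbt_grid = grid, ...)
}
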