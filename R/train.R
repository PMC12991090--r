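# Model fitting: chromosome-based splits, the training loop with input
# noise, learning-rate warmup, early stopping on validation AUC and
# best-weight restoration; prediction and evaluation.

#' Training configuration
#'
#' @param lr AdamW learning rate (default 1e-4).
#' @param warmup_steps Linear learning-rate warmup steps (default 100).
#' @param noise_sd SD of Gaussian noise added to methylation, percentile and
#'   atlas inputs during training (default 0.01).
#' @param patience Early-stopping patience in epochs on validation AUC
#'   (default 5); best-epoch weights are restored.
#' @param max_epochs Upper bound on epochs.
#' @param batch_size Reads per training batch (default 256).
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed RNG seed controlling initialization, shuffling, noise,
#'   dropout and CpG subsampling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, warmup_steps = 100L, noise_sd = 0.01,
                         patience = 5L, max_epochs = 50L,
                         batch_size = 256L, weight_decay = 0.01,
                         seed = 1L) {
  structure(list(lr = lr, warmup_steps = as.integer(warmup_steps),
                 noise_sd = noise_sd, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Chromosome-based train/validation/test split
#'
#' Validation chromosomes are held out for tuning/early stopping and test
#' chromosomes for final evaluation; everything else trains the model.
#'
#' @param validation,test Character vectors of chromosome names.
#' @return A `chromosome_split` list.
#' @export
chromosome_split <- function(validation = c("chr4", "chr21"),
                             test = c("chr5", "chr22")) {
  structure(list(validation = validation, test = test),
            class = "chromosome_split")
}

#' Partition feature sets by chromosome split
#'
#' @param features List of `feature_set`.
#' @param split A [chromosome_split()].
#' @return Factor of "train"/"validation"/"test" per feature set.
#' @export
split_assign <- function(features, split) {
  ch <- vapply(features, `[[`, "", "chrom")
  out <- rep("train", length(ch))
  out[ch %in% split$validation] <- "validation"
  out[ch %in% split$test] <- "test"
  factor(out, levels = c("train", "validation", "test"))
}

.labels01 <- function(features, labels = NULL) {
  lab <- if (is.null(labels)) {
    vapply(features, `[[`, NA_character_, "label")
  } else labels
  y <- ifelse(lab == "tumor", 1L, ifelse(lab == "non_tumor", 0L,
                                         NA_integer_))
  as.integer(y)
}

# Order-invariant seeded inference-time CpG cap: the subsample for an
# over-long read depends only on its read id and the model seed.
.cap_inference <- function(fs, max_n, seed) {
  if (fs$n_cpg <= max_n) return(fs)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((sum(utf8ToInt(fs$read_id)) + seed) %% 2147483647L)
  cap_cpgs(fs, max_n)
}

#' Fit a read-origin classifier
#'
#' Trains the encoder-only transformer (or the gradient-boosted tree
#' baseline, see [sweep_and_train()]) on labeled per-read feature sets with
#' a chromosome-based split. Training uses weighted binary cross-entropy
#' with the non-tumor/tumor [positive_weight()], Gaussian input noise,
#' per-epoch resampling of reads above the CpG cap, linear learning-rate
#' warmup and early stopping on validation AUC with best-weight restoration.
#'
#' @param features List of `feature_set` (see [build_feature_sets()]).
#' @param labels Optional label vector ("tumor"/"non_tumor"); defaults to
#'   the labels attached to the feature sets. Unlabeled sets are dropped.
#' @param engine "transformer" or "xgboost".
#' @param model_cfg A [model_config()] (transformer engine).
#' @param train_cfg A [train_config()].
#' @param split A [chromosome_split()].
#' @param feature_subset Feature ablation: "all", "meth_only",
#'   "meth_atlas" or "meth_percentiles".
#' @param gbt_grid Hyperparameter grid for the xgboost engine, see
#'   [gbt_grid()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `read_classifier` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @export
fit_read_classifier <- function(features, labels = NULL,
                                engine = c("transformer", "xgboost"),
                                model_cfg = model_config(),
                                train_cfg = train_config(),
                                split = chromosome_split(),
                                feature_subset = c("all", "meth_only",
                                                   "meth_atlas",
                                                   "meth_percentiles"),
                                gbt_grid = NULL, verbose = FALSE) {
  engine <- match.arg(engine)
  feature_subset <- match.arg(feature_subset)
  y <- .labels01(features, labels)
  keep <- !is.na(y)
  features <- features[keep]
  y <- y[keep]
  grp <- split_assign(features, split)
  if (engine == "xgboost") {
    return(.fit_gbt(features, y, grp, split, train_cfg, gbt_grid, verbose))
  }
  tr <- which(grp == "train")
  va <- which(grp == "validation")
  if (!length(tr) || length(unique(y[tr])) < 2) {
    stop("training split needs both classes")
  }
  if (!length(va) || length(unique(y[va])) < 2) {
    stop("validation split needs both classes")
  }
  pw <- positive_weight(sum(y[tr] == 0), sum(y[tr] == 1))
  set.seed(train_cfg$seed)
  state <- list(params = .init_params(model_cfg), t = 0L)
  state$m <- .zero_like(state$params)
  state$v <- .zero_like(state$params)
  step <- 0L
  best_auc <- -Inf; best_params <- NULL; best_epoch <- 0L
  since_best <- 0L
  history <- NULL
  for (epoch in seq_len(train_cfg$max_epochs)) {
    perm <- sample(tr)
    losses <- numeric(0)
    for (b0 in seq(1L, length(perm), by = train_cfg$batch_size)) {
      bi <- perm[b0:min(b0 + train_cfg$batch_size - 1L, length(perm))]
      fb <- lapply(features[bi], cap_cpgs, max_n = model_cfg$max_cpgs)
      X <- .prep_batch(fb, model_cfg, noise_sd = train_cfg$noise_sd,
                       feature_subset = feature_subset)
      fw <- .tf_forward(state$params, X, model_cfg, training = TRUE,
                        keep_cache = TRUE)
      lo <- .wbce(fw$logits, y[bi], pos_weight = pw)
      bw <- .tf_backward(state$params, X, model_cfg, fw, lo$dlogits)
      step <- step + 1L
      lr_t <- train_cfg$lr * min(1, step / max(train_cfg$warmup_steps, 1L))
      state <- .adamw_step(state, bw$grads, lr = lr_t,
                           weight_decay = train_cfg$weight_decay)
      losses <- c(losses, lo$loss)
      rm(fw, bw, X)
      # large per-batch temporaries (attention caches) would otherwise let
      # the R heap grow far beyond the live set before a full collection
      if (step %% 4L == 0L) gc(verbose = FALSE, full = FALSE)
    }
    val_probs <- .tf_predict(state$params, features[va], model_cfg,
                             train_cfg$seed, feature_subset)
    val_auc <- evaluate_auc(y[va], val_probs)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = mean(losses),
                                val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val AUC %.4f", epoch,
                      mean(losses), val_auc))
    }
    if (val_auc > best_auc + 1e-12) {
      best_auc <- val_auc
      best_params <- state$params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }
  structure(list(engine = "transformer", params = best_params,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 split = split, feature_subset = feature_subset,
                 pos_weight = pw, history = history,
                 best_epoch = best_epoch, best_val_auc = best_auc,
                 n_train = length(tr), n_validation = length(va),
                 n_test = sum(grp == "test")),
            class = "read_classifier")
}

# Batched inference on a params list.
.tf_predict <- function(params, features, model_cfg, seed,
                        feature_subset = "all", batch_size = 512L) {
  if (!length(features)) return(numeric(0))
  probs <- numeric(length(features))
  for (b0 in seq(1L, length(features), by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, length(features))
    fb <- lapply(features[bi], .cap_inference,
                 max_n = model_cfg$max_cpgs, seed = seed)
    X <- .prep_batch(fb, model_cfg, noise_sd = 0,
                     feature_subset = feature_subset)
    fw <- .tf_forward(params, X, model_cfg, training = FALSE)
    probs[bi] <- 1 / (1 + exp(-fw$logits))
  }
  probs
}

#' @rdname fit_read_classifier
#' @param object,x A fitted `read_classifier`.
#' @param newdata List of `feature_set` to score.
#' @param type "prob" for tumor-origin probabilities, "class" for hard
#'   calls (tumor iff p >= 0.5).
#' @param ... Unused.
#' @export
predict.read_classifier <- function(object, newdata, type = c("prob",
                                                              "class"),
                                    ...) {
  type <- match.arg(type)
  probs <- if (object$engine == "transformer") {
    .tf_predict(object$params, newdata, object$model_cfg,
                object$train_cfg$seed, object$feature_subset)
  } else {
    .gbt_predict(object, newdata)
  }
  if (type == "prob") return(probs)
  ifelse(probs >= 0.5, "tumor", "non_tumor")
}

#' @rdname fit_read_classifier
#' @export
print.read_classifier <- function(x, ...) {
  cat(sprintf("Read-origin classifier (%s engine)\n", x$engine))
  if (x$engine == "transformer") {
    cat(sprintf("  embed %d, %d heads, %d blocks, ff %d\n",
                x$model_cfg$embed_dim, x$model_cfg$n_heads,
                x$model_cfg$n_blocks, x$model_cfg$ff_dim))
    cat(sprintf("  best epoch %d, validation AUC %.4f\n", x$best_epoch,
                x$best_val_auc))
  } else {
    cat(sprintf("  best validation AUC %.4f\n", x$best_val_auc))
  }
  cat(sprintf("  train/validation/test reads: %d/%d/%d, positive weight %.3f\n",
              x$n_train, x$n_validation, x$n_test, x$pos_weight))
  invisible(x)
}

#' @rdname fit_read_classifier
#' @export
summary.read_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @rdname fit_read_classifier
#' @export
plot.read_classifier <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history recorded")
  graphics::plot(h$epoch, h$val_auc, type = "b", xlab = "epoch",
                 ylab = "validation AUC",
                 main = "Read-origin classifier training", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Train with supplemental matched-normal reads
#'
#' Randomly samples a fraction of reads from a matched adjacent-normal
#' sample, labels them non-tumor, merges them with the biopsy's labeled
#' feature sets (the chromosome split applies to them identically) and
#' refits; the positive weight is recomputed.
#'
#' @param features Labeled biopsy feature sets.
#' @param normal_features Feature sets from the adjacent-normal sample.
#' @param frac Fraction of normal reads to sample (default 0.05).
#' @param seed Sampling seed.
#' @param ... Passed to [fit_read_classifier()].
#' @return A `read_classifier`.
#' @export
train_with_normal <- function(features, normal_features, frac = 0.05,
                              seed = 1L, ...) {
  set.seed(seed)
  n <- length(normal_features)
  take <- sort(sample.int(n, round(frac * n)))
  extra <- lapply(normal_features[take], function(fs) {
    fs$label <- "non_tumor"
    fs
  })
  fit_read_classifier(c(features, extra), ...)
}

#' Feature-ablation experiment
#'
#' Trains one model per feature subset and evaluates each on the test
#' split.
#'
#' @param features Labeled feature sets.
#' @param subsets Character vector of feature subsets.
#' @param ... Passed to [fit_read_classifier()].
#' @return `data.frame(subset, test_auc, best_epoch)`.
#' @export
ablation_train <- function(features, subsets = c("all", "meth_only"), ...) {
  y <- .labels01(features)
  rows <- lapply(subsets, function(ss) {
    fit <- fit_read_classifier(features, feature_subset = ss, ...)
    grp <- split_assign(features, fit$split)
    te <- which(grp == "test" & !is.na(y))
    auc <- evaluate_auc(y[te], predict(fit, features[te]))
    data.frame(subset = ss, test_auc = auc, best_epoch = fit$best_epoch)
  })
  do.call(rbind, rows)
}

#' Read-length (cropping) experiment
#'
#' Restricts to reads of at least `min_length_bp`, crops them to each target
#' length ([crop_reads()]), rebuilds features against the sample's site
#' distribution and atlas, trains one model per length and reports test-set
#' AUC.
#'
#' @param reads List of [methyl_read()].
#' @param labels `data.frame(read_id, label)`.
#' @param site_dist,atlas Sample site distribution and cell-type atlas.
#' @param lengths Crop lengths in bp.
#' @param min_length_bp Minimum original read length (default 15000).
#' @param seed Cropping seed.
#' @param ... Passed to [fit_read_classifier()].
#' @return `data.frame(length_bp, test_auc, n_reads)`.
#' @export
crop_experiment <- function(reads, labels, site_dist, atlas, lengths,
                            min_length_bp = 15000, seed = 1L, ...) {
  long <- Filter(function(r) r$end - r$start >= min_length_bp, reads)
  rows <- lapply(seq_along(lengths), function(i) {
    cropped <- crop_reads(long, lengths[i], seed = seed + i)
    feats <- suppressMessages(
      build_feature_sets(cropped, site_dist, atlas, labels = labels))
    feats <- Filter(function(f) !is.na(f$label), feats)
    fit <- fit_read_classifier(feats, ...)
    grp <- split_assign(feats, fit$split)
    y <- .labels01(feats)
    te <- which(grp == "test")
    data.frame(length_bp = lengths[i],
               test_auc = evaluate_auc(y[te], predict(fit, feats[te])),
               n_reads = length(feats))
  })
  do.call(rbind, rows)
}
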