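# Sparse counterfactual perturbation: optimize a per-CpG methylation delta
# that flips a read's predicted origin, under a clipping penalty and a
# scheduled smooth-L0 sparsity penalty, with the model frozen.

#' Perturbation optimization configuration
#'
#' Defaults: clip strength gamma = 50, smoothness schedule eps 0.5 -> 0.01,
#' sparsity strength lambda 0 -> lambda_max, t0 = 25 steps without the L0
#' penalty, T_W = 975 warmup steps (1000 optimization steps total), Adam
#' learning rate 0.01, batches of 1024 reads, |delta| > 0.1 counts as
#' perturbed, and reads are analyzed only when the unperturbed tumor
#' probability is <= 0.2 or >= 0.8.
#'
#' @param gamma Clip-penalty strength.
#' @param eps_max,eps_min Smooth-L0 smoothness schedule endpoints.
#' @param lambda_min,lambda_max Smooth-L0 strength schedule endpoints.
#' @param t0 Steps before the L0 penalty switches on.
#' @param t_warm Warmup steps T_W; total steps = t0 + t_warm.
#' @param lr Adam learning rate on delta.
#' @param batch_size Reads per optimization batch.
#' @param delta_threshold Post-hoc threshold below which deltas are zeroed.
#' @param conf_low,conf_high Confidence bounds on the unperturbed
#'   probability.
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(gamma = 50, eps_max = 0.5, eps_min = 0.01,
                                lambda_min = 0, lambda_max = 5,
                                t0 = 25L, t_warm = 975L, lr = 0.01,
                                batch_size = 1024L, delta_threshold = 0.1,
                                conf_low = 0.2, conf_high = 0.8) {
  stopifnot(t_warm > t0, lr > 0, batch_size >= 1,
            eps_max >= eps_min, eps_min > 0, lambda_max >= lambda_min,
            conf_low < conf_high)
  structure(list(gamma = gamma, eps_max = eps_max, eps_min = eps_min,
                 lambda_min = lambda_min, lambda_max = lambda_max,
                 t0 = as.integer(t0), t_warm = as.integer(t_warm),
                 lr = lr, batch_size = as.integer(batch_size),
                 delta_threshold = delta_threshold,
                 conf_low = conf_low, conf_high = conf_high),
            class = "perturbation_config")
}

#' Smooth-L0 penalty schedule
#'
#' Piecewise-linear schedules for the smoothness parameter epsilon(t) and
#' strength parameter lambda(t): both stay at their starting values
#' (eps_max, lambda_min) for the first t0 steps, then ramp linearly to
#' (eps_min, lambda_max), fully reached at step T_W.
#'
#' @param t Optimization step (0-based).
#' @param cfg A [perturbation_config()].
#' @return `list(epsilon, lambda)`.
#' @export
perturb_schedule <- function(t, cfg = perturbation_config()) {
  ramp <- min(max(t - cfg$t0, 0), cfg$t_warm - cfg$t0) /
    (cfg$t_warm - cfg$t0)
  # convex combination so both endpoints are reproduced exactly
  list(epsilon = (1 - ramp) * cfg$eps_max + ramp * cfg$eps_min,
       lambda = (1 - ramp) * cfg$lambda_min + ramp * cfg$lambda_max)
}

#' Perturbation loss for one read
#'
#' The three-part objective: binary cross-entropy of the perturbed logit
#' toward the inverted target label, the gamma-weighted mean clipping
#' penalty ReLU(-x) + ReLU(x - 1) on the perturbed methylation, and the
#' scheduled smooth-L0 penalty lambda(t)/N * sum delta^2/(delta^2 +
#' epsilon(t)^2). All penalties average over the read's N attended CpGs.
#'
#' @param logit Model logit on the perturbed read.
#' @param x_tilde Perturbed methylation vector (pre-threshold, unclipped).
#' @param delta Current perturbation vector.
#' @param y Target label (the inverse of the unperturbed hard call).
#' @param t Optimization step.
#' @param cfg A [perturbation_config()].
#' @return `list(total, class_loss, clip_loss, l0_loss)`.
#' @export
perturbation_loss <- function(logit, x_tilde, delta, y, t,
                              cfg = perturbation_config()) {
  n <- length(x_tilde)
  sched <- perturb_schedule(t, cfg)
  sp <- if (logit > 30) logit else log1p(exp(min(logit, 30)))
  class_loss <- sp - y * logit
  clip_loss <- cfg$gamma / n * sum(pmax(-x_tilde, 0) + pmax(x_tilde - 1, 0))
  l0_loss <- sched$lambda / n *
    sum(delta^2 / (delta^2 + sched$epsilon^2))
  list(total = class_loss + clip_loss + l0_loss, class_loss = class_loss,
       clip_loss = clip_loss, l0_loss = l0_loss)
}

#' Optimize counterfactual methylation perturbations for a read batch
#'
#' Keeps the reads whose unperturbed tumor probability is confidently low or
#' high, then runs Adam on the batch-mean perturbation loss for t0 + T_W
#' steps with the model frozen, optimizing one delta per CpG per read
#' toward the inverted classification. The final delta is thresholded
#' (|delta| < 0.1 zeroed) and the perturbed methylation clipped to [0, 1]
#' before the post-perturbation probability is computed. A read counts as
#' successfully converted when it crosses from one confidence region to the
#' other.
#'
#' @param model A fitted transformer `read_classifier`.
#' @param features List of `feature_set` to perturb.
#' @param cfg A [perturbation_config()].
#' @param seed RNG seed (inference CpG capping only; optimization is
#'   deterministic).
#' @param confident_only Drop non-confident reads before optimizing
#'   (default TRUE).
#' @return Object of class `perturbation_result`: a list with `table`
#'   (per-read data.frame: read_id, p_before, p_after, n_cpg, n_perturbed,
#'   frac_perturbed, n_increased, success, direction), `delta` (list of
#'   per-CpG vectors, post-threshold), `features` (the capped feature sets
#'   analyzed) and `cfg`.
#' @export
perturb_batch <- function(model, features, cfg = perturbation_config(),
                          seed = 1L, confident_only = TRUE) {
  stopifnot(model$engine == "transformer")
  mcfg <- model$model_cfg
  feats <- lapply(features, .cap_inference, max_n = mcfg$max_cpgs,
                  seed = model$train_cfg$seed)
  p0 <- .tf_predict(model$params, feats, mcfg, model$train_cfg$seed,
                    model$feature_subset)
  if (confident_only) {
    keep <- p0 <= cfg$conf_low | p0 >= cfg$conf_high
    feats <- feats[keep]
    p0 <- p0[keep]
  }
  if (!length(feats)) {
    return(structure(list(table = NULL, delta = list(),
                          features = list(), cfg = cfg),
                     class = "perturbation_result"))
  }
  out_tab <- NULL
  out_delta <- list()
  for (b0 in seq(1L, length(feats), by = cfg$batch_size)) {
    bi <- b0:min(b0 + cfg$batch_size - 1L, length(feats))
    res <- .perturb_one_batch(model, feats[bi], p0[bi], cfg)
    out_tab <- rbind(out_tab, res$table)
    out_delta <- c(out_delta, res$delta)
  }
  structure(list(table = out_tab, delta = out_delta, features = feats,
                 cfg = cfg),
            class = "perturbation_result")
}

.perturb_one_batch <- function(model, feats, p0, cfg) {
  mcfg <- model$model_cfg
  B <- length(feats)
  lens <- vapply(feats, `[[`, 0L, "n_cpg")
  M <- sum(lens)
  read_of <- rep(seq_len(B), lens)
  inv_n <- 1 / lens[read_of]             # per-token 1/N of its read
  y <- as.numeric(p0 < 0.5)              # inverted hard prediction
  X <- .prep_batch(feats, mcfg, noise_sd = 0,
                   feature_subset = model$feature_subset)
  x0 <- X$Xa[, 1L]
  delta <- numeric(M)
  m <- numeric(M); v <- numeric(M)
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  n_steps <- cfg$t0 + cfg$t_warm
  for (t in seq_len(n_steps) - 1L) {
    sched <- perturb_schedule(t, cfg)
    xt <- x0 + delta
    X$Xa[, 1L] <- xt
    fw <- .tf_forward(model$params, X, mcfg, training = FALSE,
                      keep_cache = TRUE)
    p <- 1 / (1 + exp(-fw$logits))
    dlogits <- (p - y) / B
    bw <- .tf_backward(model$params, X, mcfg, fw, dlogits,
                       want_input_grad = TRUE, want_param_grads = FALSE)
    g_clip <- cfg$gamma * inv_n / B * ((xt > 1) - (xt < 0))
    g_l0 <- sched$lambda * inv_n / B *
      2 * delta * sched$epsilon^2 / (delta^2 + sched$epsilon^2)^2
    g <- bw$dmeth + g_clip + g_l0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^(t + 1))
    vh <- v / (1 - beta2^(t + 1))
    delta <- delta - cfg$lr * mh / (sqrt(vh) + eps_adam)
    if (t %% 25L == 0L) gc(verbose = FALSE, full = FALSE)
  }
  ## post-hoc threshold and clip, then re-score
  delta[abs(delta) < cfg$delta_threshold] <- 0
  xt <- pmin(1, pmax(0, x0 + delta))
  X$Xa[, 1L] <- xt
  fw <- .tf_forward(model$params, X, mcfg, training = FALSE)
  p1 <- 1 / (1 + exp(-fw$logits))
  dsplit <- split(delta, read_of)
  n_pert <- vapply(dsplit, function(d) sum(d != 0), 0L)
  n_up <- vapply(dsplit, function(d) sum(d > 0), 0L)
  success <- (p0 >= cfg$conf_high & p1 <= cfg$conf_low) |
    (p0 <= cfg$conf_low & p1 >= cfg$conf_high)
  tab <- data.frame(
    read_id = vapply(feats, `[[`, "", "read_id"),
    p_before = p0, p_after = p1, n_cpg = lens,
    n_perturbed = n_pert, frac_perturbed = n_pert / lens,
    n_increased = n_up, success = success,
    direction = ifelse(p0 >= 0.5, "tumor_to_non_tumor",
                       "non_tumor_to_tumor"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, delta = unname(dsplit))
}

#' @export
print.perturbation_result <- function(x, ...) {
  n <- if (is.null(x$table)) 0L else nrow(x$table)
  conv <- if (n) sum(x$table$success) else 0L
  cat(sprintf("<perturbation_result  %d reads, %d converted (%.1f%%)>\n",
              n, conv, if (n) 100 * conv / n else 0))
  invisible(x)
}

#' Combine perturbation runs across sparsity strengths
#'
#' When the same reads are perturbed under several lambda_max values, a read
#' converted in more than one run is reported from the run perturbing the
#' fewest CpGs.
#'
#' @param runs List of `perturbation_result` over the same reads.
#' @return A merged `perturbation_result`.
#' @export
combine_perturbation_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  base <- runs[[1]]
  if (is.null(base$table)) return(base)
  for (r in runs[-1]) {
    better <- r$table$success &
      (!base$table$success | r$table$n_perturbed < base$table$n_perturbed)
    base$table[better, ] <- r$table[better, ]
    base$delta[better] <- r$delta[better]
  }
  base
}
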