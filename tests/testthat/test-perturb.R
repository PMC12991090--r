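# Counterfactual perturbation: schedule, loss arithmetic and gradients.

test_that("schedule endpoints and plateau are exact", {
  cfg <- perturbation_config(eps_max = 0.5, eps_min = 0.01,
                             lambda_min = 0, lambda_max = 5,
                             t0 = 25L, t_warm = 975L)
  s0 <- perturb_schedule(0, cfg)
  expect_identical(s0$epsilon, 0.5)
  expect_identical(s0$lambda, 0)
  # the L0 penalty stays off through step t0
  st0 <- perturb_schedule(25, cfg)
  expect_identical(st0$epsilon, 0.5)
  expect_identical(st0$lambda, 0)
  # endpoint reached exactly at t_warm and held beyond it
  send <- perturb_schedule(975, cfg)
  expect_identical(send$epsilon, 0.01)
  expect_identical(send$lambda, 5)
  expect_identical(perturb_schedule(2000, cfg), send)
  # midpoint of the ramp
  tmid <- (25 + 975) / 2
  smid <- perturb_schedule(tmid, cfg)
  expect_equal(smid$epsilon, (0.5 + 0.01) / 2, tolerance = 1e-15)
  expect_equal(smid$lambda, 2.5, tolerance = 1e-15)
})

test_that("the three-part loss matches hand arithmetic", {
  cfg <- perturbation_config(gamma = 50, lambda_max = 5, t0 = 25L,
                             t_warm = 975L)
  x <- c(-0.2, 0.3, 1.4, 0.9)     # one below 0, one above 1
  delta <- c(-0.5, 0.1, 0.6, 0)
  logit <- 0.7
  y <- 1
  t <- 975                         # lambda = 5, epsilon = 0.01
  got <- perturbation_loss(logit, x, delta, y, t, cfg)
  class_expected <- log(1 + exp(logit)) - y * logit
  clip_expected <- 50 / 4 * (0.2 + 0.4)
  l0_expected <- 5 / 4 * sum(delta^2 / (delta^2 + 0.01^2))
  expect_equal(got$class_loss, class_expected, tolerance = 1e-12)
  expect_equal(got$clip_loss, clip_expected, tolerance = 1e-12)
  expect_equal(got$l0_loss, l0_expected, tolerance = 1e-12)
  expect_equal(got$total, class_expected + clip_expected + l0_expected,
               tolerance = 1e-12)
  # before the ramp the L0 term is exactly zero
  expect_identical(perturbation_loss(logit, x, delta, y, 0, cfg)$l0_loss, 0)
})

test_that("penalty gradients match finite differences of the loss", {
  cfg <- perturbation_config(gamma = 50, lambda_max = 5)
  t <- 700
  sched <- perturb_schedule(t, cfg)
  x0 <- c(0.1, 0.8, 0.05)
  delta <- c(-0.35, 0.6, 0.25)
  n <- 3
  # analytic penalty gradient as used in the optimizer (per-read, B = 1)
  xt <- x0 + delta
  g_ana <- cfg$gamma / n * ((xt > 1) - (xt < 0)) +
    sched$lambda / n * 2 * delta * sched$epsilon^2 /
      (delta^2 + sched$epsilon^2)^2
  eps <- 1e-7
  g_num <- vapply(1:n, function(i) {
    up <- delta; up[i] <- up[i] + eps
    dn <- delta; dn[i] <- dn[i] - eps
    fu <- perturbation_loss(0, x0 + up, up, 1, t, cfg)
    fd <- perturbation_loss(0, x0 + dn, dn, 1, t, cfg)
    ((fu$clip_loss + fu$l0_loss) - (fd$clip_loss + fd$l0_loss)) / (2 * eps)
  }, 0)
  expect_lt(max(abs(g_ana - g_num)), 1e-5)
})

test_that("a trained tiny model converts toy reads", {
  # linearly separable toy problem: tumor reads hypermethylated
  ns <- asNamespace("readorigin")
  set.seed(9)
  mk <- function(id, hot, chrom) {
    fs <- toy_feature_set(id, n = 12L, K = 2L, chrom = chrom,
                          label = if (hot) "tumor" else "non_tumor",
                          seed = sample.int(1e6, 1))
    fs$meth <- if (hot) runif(12, 0.7, 1) else runif(12, 0, 0.3)
    fs
  }
  chroms <- rep(c("chr1", "chr4", "chr5"), times = c(40, 10, 10))
  fl <- lapply(seq_along(chroms), function(i) mk(paste0("r", i),
                                                 i %% 2 == 0, chroms[i]))
  cfg <- model_config(embed_dim = 8L, n_heads = 2L, n_blocks = 1L,
                      ff_dim = 16L, dropout = 0, max_cpgs = 16L,
                      n_cell_types = 2L)
  fit <- fit_read_classifier(fl, model_cfg = cfg,
                             train_cfg = train_config(seed = 3L,
                                                      max_epochs = 30L,
                                                      batch_size = 20L,
                                                      lr = 3e-3,
                                                      warmup_steps = 5L))
  pcfg <- perturbation_config(t0 = 10L, t_warm = 190L, lr = 0.05,
                              lambda_max = 0.5)
  res <- perturb_batch(fit, fl[1:20], pcfg, seed = 2L,
                       confident_only = FALSE)
  expect_s3_class(res, "perturbation_result")
  tab <- res$table
  expect_equal(nrow(tab), 20L)
  # optimization moves the predictions toward the inverted label
  moved <- ifelse(tab$p_before >= 0.5, tab$p_before - tab$p_after,
                  tab$p_after - tab$p_before)
  expect_gt(mean(moved > 0), 0.5)
  expect_true(all(tab$n_perturbed <= tab$n_cpg))
  expect_equal(tab$frac_perturbed, tab$n_perturbed / tab$n_cpg)
  # directions follow the unperturbed call
  expect_true(all(tab$direction[tab$p_before >= 0.5] == "tumor_to_non_tumor"))
  # successful conversions cross both confidence bounds
  conv <- tab[tab$success, ]
  if (nrow(conv)) {
    expect_true(all((conv$p_before >= 0.8 & conv$p_after <= 0.2) |
                      (conv$p_before <= 0.2 & conv$p_after >= 0.8)))
  }
  # every nonzero delta exceeds the reporting threshold in magnitude
  dmin <- vapply(res$delta, function(d) {
    if (any(d != 0)) min(abs(d[d != 0])) else Inf
  }, 0)
  expect_true(all(dmin >= pcfg$delta_threshold))
})

test_that("runs at several strengths combine to the sparsest success", {
  tab1 <- data.frame(read_id = c("a", "b"), p_before = c(0.9, 0.9),
                     p_after = c(0.1, 0.5), n_cpg = c(10L, 10L),
                     n_perturbed = c(6L, 4L), frac_perturbed = c(0.6, 0.4),
                     n_increased = c(0L, 0L), success = c(TRUE, FALSE),
                     direction = "tumor_to_non_tumor",
                     stringsAsFactors = FALSE)
  tab2 <- tab1
  tab2$n_perturbed <- c(3L, 5L)
  tab2$success <- c(TRUE, TRUE)
  r1 <- structure(list(table = tab1, delta = list(rep(1, 10), rep(0, 10)),
                       features = list(), cfg = perturbation_config()),
                  class = "perturbation_result")
  r2 <- structure(list(table = tab2, delta = list(rep(2, 10), rep(3, 10)),
                       features = list(), cfg = perturbation_config()),
                  class = "perturbation_result")
  merged <- combine_perturbation_runs(list(r1, r2))
  expect_equal(merged$table$n_perturbed, c(3L, 5L))
  expect_true(all(merged$table$success))
  expect_equal(merged$delta[[1]][1], 2)
})
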