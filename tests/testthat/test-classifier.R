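# Transformer internals: analytic gradients vs finite differences, batch
# assembly and ablation masking, loss oracle, prediction determinism.

ns <- asNamespace("readorigin")

tiny_cfg <- model_config(embed_dim = 8L, n_heads = 2L, n_blocks = 2L,
                         ff_dim = 12L, dropout = 0, max_cpgs = 16L,
                         n_cell_types = 3L)

tiny_batch <- function() {
  fl <- list(toy_feature_set("r1", n = 4L, seed = 31L),
             toy_feature_set("r2", n = 6L, seed = 32L))
  for (i in seq_along(fl)) {
    a <- fl[[i]]$atlas
    a[sample(length(a), 2)] <- NA
    fl[[i]]$atlas <- a
    fl[[i]]$atlas_missing <- is.na(a)
  }
  fl
}

test_that("weighted binary cross-entropy matches direct arithmetic", {
  logits <- c(-2.5, 0, 3.1)
  y <- c(0, 1, 1)
  w <- 1.7
  p <- 1 / (1 + exp(-logits))
  manual <- mean(ifelse(y == 1, -w * log(p), -log(1 - p)))
  got <- ns$.wbce(logits, y, pos_weight = w)
  expect_equal(got$loss, manual, tolerance = 1e-12)
  # gradient of the mean loss wrt logits
  expect_equal(got$dlogits,
               ifelse(y == 1, w, 1) * (p - y) / length(y),
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  fl <- tiny_batch()
  cfg <- tiny_cfg
  set.seed(11)
  P <- ns$.init_params(cfg)
  X <- ns$.prep_batch(fl, cfg, noise_sd = 0)
  y <- c(1, 0)
  lossfn <- function(P) {
    ns$.wbce(ns$.tf_forward(P, X, cfg, training = FALSE)$logits, y, 1.3)$loss
  }
  fw <- ns$.tf_forward(P, X, cfg, training = FALSE, keep_cache = TRUE)
  bw <- ns$.tf_backward(P, X, cfg, fw,
                        ns$.wbce(fw$logits, y, 1.3)$dlogits,
                        want_input_grad = TRUE)
  eps <- 1e-6
  num_grad <- function(get, set) {
    v <- get(P)
    vapply(seq_along(v), function(i) {
      up <- v; up[i] <- up[i] + eps
      dn <- v; dn[i] <- dn[i] - eps
      (lossfn(set(P, up)) - lossfn(set(P, dn))) / (2 * eps)
    }, 0)
  }
  cases <- list(
    A1   = list(function(P) as.numeric(P$A1),
                function(P, v) { P$A1[] <- v; P },
                function() as.numeric(bw$grads$A1)),
    Wq1  = list(function(P) as.numeric(P$blocks[[1]]$Wq),
                function(P, v) { P$blocks[[1]]$Wq[] <- v; P },
                function() as.numeric(bw$grads$blocks[[1]]$Wq)),
    F1b2 = list(function(P) as.numeric(P$blocks[[2]]$F1),
                function(P, v) { P$blocks[[2]]$F1[] <- v; P },
                function() as.numeric(bw$grads$blocks[[2]]$F1)),
    ln1  = list(function(P) P$blocks[[1]]$ln1,
                function(P, v) { P$blocks[[1]]$ln1 <- v; P },
                function() bw$grads$blocks[[1]]$ln1),
    miss = list(function(P) P$miss,
                function(P, v) { P$miss <- v; P },
                function() bw$grads$miss),
    cls  = list(function(P) P$cls,
                function(P, v) { P$cls <- v; P },
                function() bw$grads$cls),
    pos  = list(function(P) as.numeric(P$pos),
                function(P, v) { P$pos[] <- v; P },
                function() as.numeric(bw$grads$pos)),
    head = list(function(P) P$head,
                function(P, v) { P$head <- v; P },
                function() bw$grads$head),
    lnf  = list(function(P) P$lnf,
                function(P, v) { P$lnf <- v; P },
                function() bw$grads$lnf))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    g_num <- num_grad(cs[[1]], cs[[2]])
    g_ana <- cs[[3]]()
    expect_lt(max(abs(g_ana - g_num)) / (max(abs(g_num)) + 1e-12), 1e-5)
  }
  # gradient on the methylation input (used by the perturbation module)
  g_meth <- vapply(seq_len(nrow(X$Xa)), function(i) {
    X1 <- X; X1$Xa[i, 1] <- X1$Xa[i, 1] + eps
    X2 <- X; X2$Xa[i, 1] <- X2$Xa[i, 1] - eps
    (ns$.wbce(ns$.tf_forward(P, X1, cfg)$logits, y, 1.3)$loss -
       ns$.wbce(ns$.tf_forward(P, X2, cfg)$logits, y, 1.3)$loss) / (2 * eps)
  }, 0)
  expect_lt(max(abs(bw$dmeth - g_meth)) / (max(abs(g_meth)) + 1e-12), 1e-5)
})

test_that("batch assembly masks feature blocks for ablations", {
  fl <- tiny_batch()
  cfg <- tiny_cfg
  full <- ns$.prep_batch(fl, cfg, noise_sd = 0, feature_subset = "all")
  # methylation and position are always present
  expect_equal(full$Xa[, 1], unlist(lapply(fl, `[[`, "meth")))
  expect_equal(full$Xa[, 2], unlist(lapply(fl, `[[`, "pos_norm")))
  # meth_only zeroes percentiles and marks all atlas entries missing
  mo <- ns$.prep_batch(fl, cfg, noise_sd = 0, feature_subset = "meth_only")
  expect_true(all(mo$Xa[, -(1:2)] == 0))
  expect_true(all(mo$missm))
  # meth_atlas keeps atlas values but zeroes percentiles
  ma <- ns$.prep_batch(fl, cfg, noise_sd = 0, feature_subset = "meth_atlas")
  expect_true(all(ma$Xa[, -(1:2)] == 0))
  expect_identical(ma$missm, full$missm)
  expect_identical(ma$Xb, full$Xb)
  # meth_percentiles keeps percentiles but masks the atlas
  mp <- ns$.prep_batch(fl, cfg, noise_sd = 0,
                       feature_subset = "meth_percentiles")
  expect_identical(mp$Xa, full$Xa)
  expect_true(all(mp$missm))
  # token layout: one CLS row in front of each read's tokens
  expect_equal(full$Mtot, sum(full$lens) + 2L)
  expect_equal(full$cls_rows, c(1L, full$lens[1] + 2L))
})

test_that("held-out-chromosome split is disjoint and exhaustive", {
  fl <- c(lapply(1:3, function(i) toy_feature_set(paste0("a", i),
                                                  chrom = "chr1", seed = i)),
          lapply(1:2, function(i) toy_feature_set(paste0("v", i),
                                                  chrom = "chr4", seed = i)),
          lapply(1:2, function(i) toy_feature_set(paste0("t", i),
                                                  chrom = "chr22", seed = i)))
  grp <- split_assign(fl, chromosome_split())
  expect_equal(as.character(grp), c(rep("train", 3), rep("validation", 2),
                                    rep("test", 2)))
})

test_that("forward pass and prediction are deterministic", {
  set.seed(3)
  fl <- tiny_batch()
  set.seed(11)
  P <- ns$.init_params(tiny_cfg)
  p1 <- ns$.tf_predict(P, fl, tiny_cfg, seed = 5L, feature_subset = "all")
  p2 <- ns$.tf_predict(P, fl, tiny_cfg, seed = 5L, feature_subset = "all")
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})
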