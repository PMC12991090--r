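# Encoder-only transformer for per-read tumor-origin classification,
# implemented natively: explicit forward and backward passes over flattened
# token matrices, with per-read attention (reads keep their true lengths, so
# no padding enters the attention — equivalent to a key-padding mask).
#
# Architecture: two embedding MLPs (21-dim per-CpG vector; K-dim atlas
# vector with a learned missing-value embedding), summed with a scaled
# learned absolute position embedding; a learned CLS vector prepended; N
# pre-layer-norm encoder blocks (multi-head self-attention + GELU
# feed-forward, no bias terms, gain-only layer norm); final layer norm and a
# linear head on the CLS state.

#' Transformer model configuration
#'
#' Defaults follow the full-scale architecture (embedding 384, 6 heads of
#' dimension 64, 3 blocks, feed-forward 1536, pre-layer-norm, GELU, no bias
#' terms, dropout 0.1, position-embedding scale 0.05, at most 511 CpGs per
#' read); every field can be overridden for desk-scale runs.
#'
#' @param embed_dim Embedding dimension.
#' @param n_heads Attention heads; `embed_dim` must be divisible by it.
#' @param n_blocks Encoder blocks.
#' @param ff_dim Feed-forward hidden dimension.
#' @param dropout Dropout rate during training.
#' @param pos_embed_scale Multiplier on the position-embedding output.
#' @param max_cpgs Maximum CpGs per read (excess subsampled).
#' @param n_cell_types Atlas width K.
#' @param input_dim Per-CpG concatenated vector size (1 methylation +
#'   1 position + 19 percentiles).
#' @return A `model_config` list.
#' @export
model_config <- function(embed_dim = 384L, n_heads = 6L, n_blocks = 3L,
                         ff_dim = 1536L, dropout = 0.1,
                         pos_embed_scale = 0.05, max_cpgs = 511L,
                         n_cell_types = 84L, input_dim = 21L) {
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be a multiple of n_heads")
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 head_dim = as.integer(embed_dim / n_heads),
                 n_blocks = as.integer(n_blocks),
                 ff_dim = as.integer(ff_dim), dropout = dropout,
                 pos_embed_scale = pos_embed_scale,
                 max_cpgs = as.integer(max_cpgs),
                 n_cell_types = as.integer(n_cell_types),
                 input_dim = as.integer(input_dim)),
            class = "model_config")
}

# Uniform(-1/sqrt(fan_in), +) linear init, stored input x output.
.lin_init <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

.init_params <- function(cfg) {
  E <- cfg$embed_dim; FF <- cfg$ff_dim; K <- cfg$n_cell_types
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) list(
    ln1 = rep(1, E),
    Wq = .lin_init(E, E), Wk = .lin_init(E, E), Wv = .lin_init(E, E),
    Wo = .lin_init(E, E),
    ln2 = rep(1, E),
    F1 = .lin_init(E, FF), F2 = .lin_init(FF, E)))
  list(
    A1 = .lin_init(cfg$input_dim, E), A2 = .lin_init(E, E),
    B1 = .lin_init(K, E), B2 = .lin_init(E, E),
    miss = stats::rnorm(K),
    cls = stats::rnorm(E),
    pos = matrix(stats::rnorm((cfg$max_cpgs + 1L) * E), cfg$max_cpgs + 1L, E),
    blocks = blocks,
    lnf = rep(1, E),
    head = .lin_init(E, 1L)[, 1]
  )
}

# GELU with cached Phi/phi for the backward pass.
.gelu_fwd <- function(x) {
  Phi <- stats::pnorm(x)
  list(y = x * Phi, x = x, Phi = Phi)
}
.gelu_bwd <- function(cache, dy) {
  dy * (cache$Phi + cache$x * stats::dnorm(cache$x))
}

# Fast row maximum (max.col runs in C; apply() would dominate the profile).
.row_max <- function(S) {
  S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
}

.ln_eps <- 1e-5

.ln_fwd <- function(X, g) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .ln_eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`), xhat = xhat, inv = inv)
}
.ln_bwd <- function(cache, g, dY) {
  d <- sweep(dY, 2L, g, `*`)
  dg <- colSums(dY * cache$xhat)
  dX <- cache$inv * (d - rowMeans(d) - cache$xhat * rowMeans(d * cache$xhat))
  list(dX = dX, dg = dg)
}

.dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# Assemble flattened batch inputs from a list of feature_sets.
# noise_sd > 0 adds Gaussian noise to methylation, percentile and atlas
# values (training only). feature_subset masks feature blocks for ablation.
.prep_batch <- function(features, cfg, noise_sd = 0,
                        feature_subset = "all") {
  B <- length(features)
  lens <- vapply(features, `[[`, 0L, "n_cpg")
  M <- sum(lens)
  Xa <- matrix(0, M, cfg$input_dim)
  Xb <- matrix(0, M, cfg$n_cell_types)
  missm <- matrix(TRUE, M, cfg$n_cell_types)
  posidx <- integer(M)
  off <- 0L
  for (i in seq_len(B)) {
    fs <- features[[i]]
    n <- fs$n_cpg
    rows <- off + seq_len(n)
    meth <- fs$meth
    pct <- fs$pct
    pct[is.na(pct)] <- 0.5
    atl <- fs$atlas
    amiss <- fs$atlas_missing
    if (feature_subset %in% c("meth_only", "meth_percentiles")) {
      amiss[] <- TRUE
    }
    if (feature_subset %in% c("meth_only", "meth_atlas")) {
      pct[] <- 0
    }
    if (noise_sd > 0) {
      meth <- meth + stats::rnorm(n, 0, noise_sd)
      if (feature_subset %in% c("all", "meth_percentiles")) {
        pct <- pct + stats::rnorm(length(pct), 0, noise_sd)
      }
      if (feature_subset %in% c("all", "meth_atlas")) {
        atl <- atl + stats::rnorm(length(atl), 0, noise_sd)
      }
    }
    atl[amiss] <- 0  # replaced by the learned missing embedding downstream
    Xa[rows, 1] <- meth
    Xa[rows, 2] <- fs$pos_norm
    Xa[rows, 3:cfg$input_dim] <- pct
    Xb[rows, ] <- atl
    missm[rows, ] <- amiss
    posidx[rows] <- seq_len(n)
    off <- off + n
  }
  # token layout: [cls_1, toks_1, cls_2, toks_2, ...]
  Mtot <- M + B
  starts <- cumsum(c(1L, lens + 1L))[seq_len(B)]
  cls_rows <- starts
  tok_rows <- setdiff(seq_len(Mtot), cls_rows)
  slices <- lapply(seq_len(B), function(i) starts[i] + 0:lens[i])
  list(Xa = Xa, Xb = Xb, missm = missm, posidx = posidx, lens = lens,
       B = B, M = M, Mtot = Mtot, cls_rows = cls_rows,
       tok_rows = tok_rows, slices = slices)
}

# Forward pass. Returns logits (length B) and, if keep_cache, everything the
# backward pass needs.
.tf_forward <- function(P, X, cfg, training = FALSE, keep_cache = FALSE) {
  E <- cfg$embed_dim; H <- cfg$n_heads; dh <- cfg$head_dim
  drop <- if (training) cfg$dropout else 0
  # atlas missing-value embedding substitution
  Xb <- X$Xb
  if (any(X$missm)) {
    mi <- which(X$missm)
    Xb[mi] <- P$miss[((mi - 1L) %/% nrow(Xb)) + 1L]
  }
  ga <- .gelu_fwd(X$Xa %*% P$A1)
  Ha <- ga$y %*% P$A2
  gb <- .gelu_fwd(Xb %*% P$B1)
  Hb <- gb$y %*% P$B2
  tok <- Ha + Hb +
    cfg$pos_embed_scale * P$pos[X$posidx + 1L, , drop = FALSE]
  T_ <- matrix(0, X$Mtot, E)
  T_[X$tok_rows, ] <- tok
  T_[X$cls_rows, ] <- rep(P$cls + cfg$pos_embed_scale * P$pos[1L, ],
                          each = X$B)
  caches <- if (keep_cache) vector("list", cfg$n_blocks) else NULL
  hs_list <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  scale <- 1 / sqrt(dh)
  for (b in seq_len(cfg$n_blocks)) {
    Pb <- P$blocks[[b]]
    T_in <- T_
    l1 <- .ln_fwd(T_, Pb$ln1)
    Q <- l1$y %*% Pb$Wq
    Km <- l1$y %*% Pb$Wk
    V <- l1$y %*% Pb$Wv
    O <- matrix(0, X$Mtot, E)
    Alist <- if (keep_cache) vector("list", length(X$slices)) else NULL
    for (ri in seq_along(X$slices)) {
      idx <- X$slices[[ri]]
      Qr <- Q[idx, , drop = FALSE]
      Kr <- Km[idx, , drop = FALSE]
      Vr <- V[idx, , drop = FALSE]
      Or <- matrix(0, length(idx), E)
      Ar <- if (keep_cache) vector("list", H) else NULL
      for (h in seq_len(H)) {
        hs <- hs_list[[h]]
        S <- tcrossprod(Qr[, hs, drop = FALSE],
                        Kr[, hs, drop = FALSE]) * scale
        S <- S - .row_max(S)
        A <- exp(S)
        A <- A / rowSums(A)
        Or[, hs] <- A %*% Vr[, hs, drop = FALSE]
        if (keep_cache) Ar[[h]] <- A
      }
      O[idx, ] <- Or
      if (keep_cache) Alist[[ri]] <- Ar
    }
    AO <- O %*% Pb$Wo
    m1 <- .dropout_mask(X$Mtot, E, drop)
    if (!is.null(m1)) AO <- AO * m1
    T_ <- T_ + AO
    T_mid <- T_
    l2 <- .ln_fwd(T_, Pb$ln2)
    gf <- .gelu_fwd(l2$y %*% Pb$F1)
    Hf <- gf$y
    m2 <- .dropout_mask(X$Mtot, cfg$ff_dim, drop)
    if (!is.null(m2)) Hf <- Hf * m2
    FO <- Hf %*% Pb$F2
    m3 <- .dropout_mask(X$Mtot, E, drop)
    if (!is.null(m3)) FO <- FO * m3
    T_ <- T_ + FO
    if (keep_cache) {
      caches[[b]] <- list(T_in = T_in, l1 = l1, Q = Q, K = Km, V = V,
                          O = O, A = Alist, m1 = m1, T_mid = T_mid,
                          l2 = l2, gf = gf, m2 = m2, m3 = m3)
    }
  }
  lf <- .ln_fwd(T_[X$cls_rows, , drop = FALSE], P$lnf)
  logits <- as.numeric(lf$y %*% P$head)
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits,
       cache = list(ga = ga, gb = gb, Xb = Xb, caches = caches, lf = lf,
                    T_final_cls = T_[X$cls_rows, , drop = FALSE]))
}

# Backward pass from per-read logit gradients. Returns parameter gradients
# (same nesting as P) and, if want_input_grad, the gradient w.r.t. the raw
# methylation entries (column 1 of Xa), per token.
.tf_backward <- function(P, X, cfg, fw, dlogits, want_input_grad = FALSE,
                         want_param_grads = TRUE) {
  E <- cfg$embed_dim; H <- cfg$n_heads; dh <- cfg$head_dim
  cache <- fw$cache
  G <- if (want_param_grads) .zero_like(P) else NULL
  hs_list <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  scale <- 1 / sqrt(dh)

  dCn <- outer(dlogits, P$head)            # B x E
  if (want_param_grads) G$head <- as.numeric(crossprod(cache$lf$y, dlogits))
  lb <- .ln_bwd(cache$lf, P$lnf, dCn)
  if (want_param_grads) G$lnf <- lb$dg
  dT <- matrix(0, X$Mtot, E)
  dT[X$cls_rows, ] <- lb$dX

  for (b in rev(seq_len(cfg$n_blocks))) {
    Pb <- P$blocks[[b]]
    Cb <- cache$caches[[b]]
    ## feed-forward sublayer
    dFO <- dT
    if (!is.null(Cb$m3)) dFO <- dFO * Cb$m3
    dHf <- dFO %*% t(Pb$F2)
    if (want_param_grads) {
      Hf_used <- Cb$gf$y
      if (!is.null(Cb$m2)) Hf_used <- Hf_used * Cb$m2
      G$blocks[[b]]$F2 <- crossprod(Hf_used, dFO)
    }
    if (!is.null(Cb$m2)) dHf <- dHf * Cb$m2
    dPre <- .gelu_bwd(Cb$gf, dHf)
    dZ2 <- dPre %*% t(Pb$F1)
    if (want_param_grads) G$blocks[[b]]$F1 <- crossprod(Cb$l2$y, dPre)
    lb2 <- .ln_bwd(Cb$l2, Pb$ln2, dZ2)
    if (want_param_grads) G$blocks[[b]]$ln2 <- lb2$dg
    dT <- dT + lb2$dX
    ## attention sublayer
    dAO <- dT
    if (!is.null(Cb$m1)) dAO <- dAO * Cb$m1
    dO <- dAO %*% t(Pb$Wo)
    if (want_param_grads) G$blocks[[b]]$Wo <- crossprod(Cb$O, dAO)
    dQ <- matrix(0, X$Mtot, E)
    dK <- matrix(0, X$Mtot, E)
    dV <- matrix(0, X$Mtot, E)
    for (ri in seq_along(X$slices)) {
      idx <- X$slices[[ri]]
      Qr <- Cb$Q[idx, , drop = FALSE]
      Kr <- Cb$K[idx, , drop = FALSE]
      Vr <- Cb$V[idx, , drop = FALSE]
      dOr <- dO[idx, , drop = FALSE]
      dQr <- matrix(0, length(idx), E)
      dKr <- matrix(0, length(idx), E)
      dVr <- matrix(0, length(idx), E)
      for (h in seq_len(H)) {
        hs <- hs_list[[h]]
        Qh <- Qr[, hs, drop = FALSE]
        Kh <- Kr[, hs, drop = FALSE]
        A <- Cb$A[[ri]][[h]]               # cached attention probabilities
        dOh <- dOr[, hs, drop = FALSE]
        dA <- tcrossprod(dOh, Vr[, hs, drop = FALSE])
        dS <- A * (dA - rowSums(dA * A))
        dQr[, hs] <- dS %*% Kh * scale
        dKr[, hs] <- crossprod(dS, Qh) * scale
        dVr[, hs] <- crossprod(A, dOh)
      }
      dQ[idx, ] <- dQr
      dK[idx, ] <- dKr
      dV[idx, ] <- dVr
    }
    dZ1 <- dQ %*% t(Pb$Wq) + dK %*% t(Pb$Wk) + dV %*% t(Pb$Wv)
    if (want_param_grads) {
      G$blocks[[b]]$Wq <- crossprod(Cb$l1$y, dQ)
      G$blocks[[b]]$Wk <- crossprod(Cb$l1$y, dK)
      G$blocks[[b]]$Wv <- crossprod(Cb$l1$y, dV)
    }
    lb1 <- .ln_bwd(Cb$l1, Pb$ln1, dZ1)
    if (want_param_grads) G$blocks[[b]]$ln1 <- lb1$dg
    dT <- dT + lb1$dX
  }

  dtok <- dT[X$tok_rows, , drop = FALSE]
  dcls_rows <- dT[X$cls_rows, , drop = FALSE]
  if (want_param_grads) {
    G$cls <- colSums(dcls_rows)
    G$pos <- matrix(0, cfg$max_cpgs + 1L, E)
    G$pos[1L, ] <- cfg$pos_embed_scale * colSums(dcls_rows)
    ptab <- rowsum(dtok, X$posidx, reorder = TRUE)
    rows <- as.integer(rownames(ptab)) + 1L
    G$pos[rows, ] <- G$pos[rows, , drop = FALSE] +
      cfg$pos_embed_scale * ptab
    ## embedding MLPs
    G$A2 <- crossprod(cache$ga$y, dtok)
    dGa <- .gelu_bwd(cache$ga, dtok %*% t(P$A2))
    G$A1 <- crossprod(X$Xa, dGa)
    G$B2 <- crossprod(cache$gb$y, dtok)
    dGb <- .gelu_bwd(cache$gb, dtok %*% t(P$B2))
    G$B1 <- crossprod(cache$Xb, dGb)
    dXb <- dGb %*% t(P$B1)
    G$miss <- rep(0, cfg$n_cell_types)
    if (any(X$missm)) {
      cm <- colSums(dXb * X$missm)
      G$miss <- as.numeric(cm)
    }
  }
  dmeth <- NULL
  if (want_input_grad) {
    dGa <- .gelu_bwd(cache$ga, dtok %*% t(P$A2))
    dXa <- dGa %*% t(P$A1)
    dmeth <- dXa[, 1L]
  }
  list(grads = G, dmeth = dmeth)
}

# Structural zero copy of a parameter list.
.zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, .zero_like))
  p * 0
}

# Elementwise walk over two parallel nested lists.
.param_map <- function(f, a, b) {
  if (is.list(a)) {
    return(Map(function(x, y) .param_map(f, x, y), a, b))
  }
  f(a, b)
}

# One AdamW step (decoupled weight decay), in place on a state list holding
# params, m, v, t.
.adamw_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  state$m <- .param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .param_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  upd <- .param_map(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  state$params <- .param_map(function(p, u) p - lr * u, state$params, upd)
  if (weight_decay > 0) {
    state$params <- .param_map(function(p, u) p - lr * weight_decay * p,
                               state$params, state$params)
  }
  state
}

# Weighted binary cross-entropy with logits; returns loss and dlogits.
.wbce <- function(logits, y, pos_weight = 1) {
  w <- ifelse(y == 1, pos_weight, 1)
  # softplus(z) - y*z, numerically stable
  sp <- ifelse(logits > 30, logits, log1p(exp(pmin(logits, 30))))
  loss <- mean(w * (sp - y * logits))
  p <- 1 / (1 + exp(-logits))
  dlog <- w * (p - y) / length(logits)
  list(loss = loss, dlogits = dlog)
}
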