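# Transformer internals: parameter initialization, forward pass (exact and
# kernel-approximate attention), backpropagation, and Adam. Written in base
# R matrix algebra; gradients are verified against finite differences in the
# test suite.

LN_EPS <- 1e-5

#' Encoder model configuration
#'
#' @param h Embedding width (must be divisible by `n_heads`).
#' @param n_layers,n_heads Transformer depth and heads per layer.
#' @param ff_mult Feed-forward expansion factor.
#' @param attention_kind `"exact"` or `"kernel-approximate"` (Performer-style
#'   positive random features; inference only). The kernel path cannot carry
#'   the additive relative-position bias and ignores it.
#' @param kernel_features Number of random features for the kernel path.
#' @param dropout Dropout fraction (training only; inference is always
#'   deterministic).
#' @param max_transcript_length Longest input the model accepts directly.
#' @param chunk_overlong If `TRUE`, longer inputs are scored in overlapping
#'   chunks; otherwise they are an error (never silent truncation).
#' @param chunk_overlap Overlap (nt) between chunks.
#' @param use_positional Add learned absolute positional encodings.
#' @param rel_window Half-width (nt) of the learned relative-position
#'   attention bias; offsets beyond it share the edge bins. 0 disables.
#' @param seed Seed for weight init and kernel feature draws.
#' @return A `ModelConfig` list.
#' @export
model_config <- function(h = 32L, n_layers = 4L, n_heads = 4L, ff_mult = 2L,
                         attention_kind = c("exact", "kernel-approximate"),
                         kernel_features = 256L, dropout = 0,
                         max_transcript_length = 2048L,
                         chunk_overlong = TRUE, chunk_overlap = 64L,
                         use_positional = TRUE, rel_window = 32L, seed = 1L) {
  attention_kind <- match.arg(attention_kind)
  stopifnot(h %% n_heads == 0L, dropout >= 0, dropout < 1)
  structure(list(h = as.integer(h), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), ff_mult = as.integer(ff_mult),
                 attention_kind = attention_kind,
                 kernel_features = as.integer(kernel_features),
                 dropout = dropout,
                 max_transcript_length = as.integer(max_transcript_length),
                 chunk_overlong = chunk_overlong,
                 chunk_overlap = as.integer(chunk_overlap),
                 use_positional = use_positional,
                 rel_window = as.integer(rel_window), seed = as.integer(seed)),
            class = "ModelConfig")
}

init_params <- function(config, head_width = 1L) {
  h <- config$h; f <- config$h * config$ff_mult
  set.seed(derive_seed(config$seed, "init"))
  rn <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  p <- list(
    # phi's first layer starts as a spread of tanh ramps over c in [0,1]
    # (soft binning), so count differences are strongly directional from the
    # first step rather than a near-rank-1 signal
    phi_W1 = rnorm(h, 4, 1), phi_b1 = -seq(0, 4, length.out = h),
    phi_W2 = rn(h, h, 1 / sqrt(h)), phi_b2 = numeric(h),
    e = rnorm(h, 0, 0.5),
    E = rn(N_RL, h, 0.1),
    P = rn(config$max_transcript_length, h, 0.02),
    mask_tok = rnorm(h, 0, 0.1)
  )
  for (k in seq_len(config$n_layers)) {
    pre <- sprintf("L%d_", k)
    sdw <- 1 / sqrt(h)
    lay <- list(ln1_g = rep(1, h), ln1_b = numeric(h),
                Wq = rn(h, h, sdw), bq = numeric(h),
                Wk = rn(h, h, sdw), bk = numeric(h),
                Wv = rn(h, h, sdw), bv = numeric(h),
                Wo = rn(h, h, sdw), bo = numeric(h),
                ln2_g = rep(1, h), ln2_b = numeric(h),
                Wf1 = rn(h, f, sdw), bf1 = numeric(f),
                Wf2 = rn(f, h, 1 / sqrt(f)), bf2 = numeric(h),
                rb = {
                  # heads start attending to local windows, alternating
                  # upstream/downstream across heads and layers: boundary
                  # comparisons are expressible at initialization and are
                  # refined (or undone) by training
                  w <- max(0L, config$rel_window)
                  off <- seq.int(-w, w)
                  m <- matrix(0, config$n_heads, 2L * w + 1L)
                  if (w > 0L) for (j in seq_len(config$n_heads)) {
                    near <- abs(off) <= 15L & off != 0L
                    if ((j + k) %% 2L == 0L)
                      m[j, ] <- 1.5 * (near & off < 0) - 1.5 * (off > 0)
                    else
                      m[j, ] <- 1.5 * (near & off > 0) - 1.5 * (off < 0)
                  }
                  m
                })
    names(lay) <- paste0(pre, names(lay))
    p <- c(p, lay)
  }
  p$lnf_g <- rep(1, h); p$lnf_b <- numeric(h)
  p$head_W <- rn(h, head_width, 1 / sqrt(h)); p$head_b <- numeric(head_width)
  p
}

# swap the output head (e.g. 21-wide pretraining head -> 1-wide TIS head)
swap_head <- function(params, config, head_width) {
  set.seed(derive_seed(config$seed, "head_swap"))
  params$head_W <- matrix(rnorm(config$h * head_width, 0, 1 / sqrt(config$h)),
                          config$h, head_width)
  params$head_b <- numeric(head_width)
  params
}

ln_fwd <- function(x, g, b) {
  n <- ncol(x)
  mu <- .rowMeans(x, nrow(x), n); xc <- x - mu
  v <- .rowMeans(xc * xc, nrow(x), n); inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- .rowMeans(dxhat, nrow(dy), ncol(dy)); m2 <- .rowMeans(dxhat * xhat, nrow(dy), ncol(dy))
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / .rowSums(e, nrow(e), ncol(e))
}

# orthogonal gaussian random features (Performer / FAVOR+)
orf_matrix <- function(d, m, seed) {
  set.seed(seed)
  blocks <- ceiling(m / d)
  W <- matrix(0, d, blocks * d)
  for (b in seq_len(blocks)) {
    G <- matrix(rnorm(d * d), d, d)
    Q <- qr.Q(qr(G))
    norms <- sqrt(rowSums(matrix(rnorm(d * d), d, d)^2))
    W[, ((b - 1L) * d + 1L):(b * d)] <- t(Q * norms)
  }
  W[, seq_len(m), drop = FALSE]
}

kernel_attention <- function(Qh, Kh, Vh, W) {
  d <- ncol(Qh)
  sc <- d^(-0.25)
  Qs <- Qh * sc; Ks <- Kh * sc
  lq <- Qs %*% W - rowSums(Qs * Qs) / 2
  lk <- Ks %*% W - rowSums(Ks * Ks) / 2
  stab <- max(lk)
  phq <- exp(lq - stab); phk <- exp(lk - stab)
  num <- phq %*% (t(phk) %*% Vh)
  den <- as.numeric(phq %*% colSums(phk))
  num / pmax(den, 1e-12)
}

# relative-offset bin index matrix (L x L), cached per (L, window)
.rel_idx_cache <- new.env(parent = emptyenv())
rel_idx <- function(L, w) {
  key <- paste0(L, "_", w)
  if (!is.null(.rel_idx_cache[[key]])) return(.rel_idx_cache[[key]])
  off <- outer(seq_len(L), seq_len(L), function(i, j) pmin(pmax(j - i, -w), w))
  idx <- off + w + 1L
  .rel_idx_cache[[key]] <- idx
  idx
}

# Forward pass over one transcript. c: length-L vector in [0,1]; lmat: L x 21
# read-length fractions; mask_idx: positions (1-based) replaced by the mask
# token. Returns logits (L x head_width) and, if want_cache, every
# intermediate needed for the backward pass.
nn_forward <- function(params, config, c_vec, lmat, mask_idx = integer(),
                       want_cache = FALSE, dropout_seed = NULL) {
  L <- length(c_vec); h <- config$h
  stopifnot(L <= config$max_transcript_length)
  Z1 <- outer(c_vec, params$phi_W1) + rep(params$phi_b1, each = L)
  H1 <- tanh(Z1)
  Z2 <- H1 %*% params$phi_W2 + rep(params$phi_b2, each = L)
  T2 <- tanh(Z2)
  ec <- sweep(T2, 2, params$e, "*")
  el <- lmat %*% params$E
  X0 <- ec + el
  if (length(mask_idx)) X0[mask_idx, ] <- rep(params$mask_tok, each = length(mask_idx))
  X <- if (config$use_positional) X0 + params$P[seq_len(L), , drop = FALSE] else X0

  use_drop <- config$dropout > 0 && !is.null(dropout_seed)
  if (use_drop) set.seed(dropout_seed)
  nh <- config$n_heads; d <- h %/% nh
  cache <- list(Z1 = Z1, H1 = H1, T2 = T2, el = el, X0 = X0,
                c_vec = c_vec, lmat = lmat, mask_idx = mask_idx, layers = list())
  for (k in seq_len(config$n_layers)) {
    pre <- sprintf("L%d_", k)
    g <- function(nm) params[[paste0(pre, nm)]]
    lnc1 <- ln_fwd(X, g("ln1_g"), g("ln1_b"))
    A <- lnc1$y
    Q <- A %*% g("Wq") + rep(g("bq"), each = L)
    K <- A %*% g("Wk") + rep(g("bk"), each = L)
    V <- A %*% g("Wv") + rep(g("bv"), each = L)
    O <- matrix(0, L, h); Plist <- vector("list", nh)
    for (j in seq_len(nh)) {
      cols <- ((j - 1L) * d + 1L):(j * d)
      if (config$attention_kind == "exact") {
        S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(d)
        if (config$rel_window > 0L) {
          ridx <- rel_idx(L, config$rel_window)
          S <- S + matrix(g("rb")[j, ][ridx], L, L)
        }
        Pj <- softmax_rows(S)
        O[, cols] <- Pj %*% V[, cols, drop = FALSE]
        Plist[[j]] <- Pj
      } else {
        Wrf <- orf_matrix(d, config$kernel_features,
                          derive_seed(config$seed, sprintf("favor_%d_%d", k, j)))
        O[, cols] <- kernel_attention(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE],
                                      V[, cols, drop = FALSE], Wrf)
      }
    }
    att <- O %*% g("Wo") + rep(g("bo"), each = L)
    if (use_drop) {
      dm <- matrix(runif(L * h) >= config$dropout, L, h) / (1 - config$dropout)
      att <- att * dm
    } else dm <- NULL
    X1 <- X + att
    lnc2 <- ln_fwd(X1, g("ln2_g"), g("ln2_b"))
    B <- lnc2$y
    F1 <- B %*% g("Wf1") + rep(g("bf1"), each = L)
    Rl <- pmax(F1, 0)
    F2 <- Rl %*% g("Wf2") + rep(g("bf2"), each = L)
    if (use_drop) {
      dm2 <- matrix(runif(L * h) >= config$dropout, L, h) / (1 - config$dropout)
      F2 <- F2 * dm2
    } else dm2 <- NULL
    Xout <- X1 + F2
    if (want_cache)
      cache$layers[[k]] <- list(Xin = X, lnc1 = lnc1, A = A, Q = Q, K = K, V = V,
                                O = O, Plist = Plist, X1 = X1, lnc2 = lnc2,
                                B = B, F1 = F1, Rl = Rl, dm = dm, dm2 = dm2)
    X <- Xout
  }
  lncf <- ln_fwd(X, params$lnf_g, params$lnf_b)
  logits <- lncf$y %*% params$head_W + rep(params$head_b, each = L)
  if (want_cache) { cache$Xfinal <- X; cache$lncf <- lncf }
  list(logits = logits, cache = if (want_cache) cache else NULL)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

acc_grad <- function(g, nm, val) { g[[nm]] <- g[[nm]] + val; g }

# Backward pass; dlogits is L x head_width. Returns gradient list with the
# same names/shapes as params.
nn_backward <- function(params, config, cache, dlogits) {
  L <- nrow(dlogits); h <- config$h
  nh <- config$n_heads; d <- h %/% nh
  grads <- zero_like(params)
  Xf <- cache$lncf$y
  grads$head_W <- crossprod(Xf, dlogits)
  grads$head_b <- colSums(dlogits)
  dXf <- tcrossprod(dlogits, params$head_W)
  bb <- ln_bwd(dXf, cache$lncf, params$lnf_g)
  grads$lnf_g <- bb$dg; grads$lnf_b <- bb$db
  dX <- bb$dx

  for (k in rev(seq_len(config$n_layers))) {
    pre <- sprintf("L%d_", k)
    g <- function(nm) params[[paste0(pre, nm)]]
    la <- cache$layers[[k]]
    dF2 <- dX
    if (!is.null(la$dm2)) dF2 <- dF2 * la$dm2
    grads[[paste0(pre, "Wf2")]] <- crossprod(la$Rl, dF2)
    grads[[paste0(pre, "bf2")]] <- colSums(dF2)
    dRl <- tcrossprod(dF2, g("Wf2"))
    dF1 <- dRl * (la$F1 > 0)
    grads[[paste0(pre, "Wf1")]] <- crossprod(la$B, dF1)
    grads[[paste0(pre, "bf1")]] <- colSums(dF1)
    dB <- tcrossprod(dF1, g("Wf1"))
    bb <- ln_bwd(dB, la$lnc2, g("ln2_g"))
    grads[[paste0(pre, "ln2_g")]] <- bb$dg
    grads[[paste0(pre, "ln2_b")]] <- bb$db
    dX1 <- dX + bb$dx

    datt <- dX1
    if (!is.null(la$dm)) datt <- datt * la$dm
    grads[[paste0(pre, "Wo")]] <- crossprod(la$O, datt)
    grads[[paste0(pre, "bo")]] <- colSums(datt)
    dO <- tcrossprod(datt, g("Wo"))
    dQ <- matrix(0, L, h); dK <- matrix(0, L, h); dV <- matrix(0, L, h)
    for (j in seq_len(nh)) {
      cols <- ((j - 1L) * d + 1L):(j * d)
      Pj <- la$Plist[[j]]
      dOh <- dO[, cols, drop = FALSE]
      dPj <- tcrossprod(dOh, la$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(Pj, dOh)
      dS <- Pj * (dPj - .rowSums(dPj * Pj, nrow(Pj), ncol(Pj)))
      if (config$rel_window > 0L) {
        ridx <- rel_idx(L, config$rel_window)
        acc <- rowsum(as.vector(dS), as.vector(ridx))
        grads[[paste0(pre, "rb")]][j, as.integer(rownames(acc))] <-
          grads[[paste0(pre, "rb")]][j, as.integer(rownames(acc))] + acc[, 1]
      }
      dQ[, cols] <- (dS %*% la$K[, cols, drop = FALSE]) / sqrt(d)
      dK[, cols] <- crossprod(dS, la$Q[, cols, drop = FALSE]) / sqrt(d)
    }
    grads[[paste0(pre, "Wq")]] <- crossprod(la$A, dQ)
    grads[[paste0(pre, "bq")]] <- colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(la$A, dK)
    grads[[paste0(pre, "bk")]] <- colSums(dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(la$A, dV)
    grads[[paste0(pre, "bv")]] <- colSums(dV)
    dA <- tcrossprod(dQ, g("Wq")) + tcrossprod(dK, g("Wk")) + tcrossprod(dV, g("Wv"))
    bb <- ln_bwd(dA, la$lnc1, g("ln1_g"))
    grads[[paste0(pre, "ln1_g")]] <- bb$dg
    grads[[paste0(pre, "ln1_b")]] <- bb$db
    dX <- dX1 + bb$dx
  }

  if (config$use_positional)
    grads$P[seq_len(L), ] <- dX
  dX0 <- dX
  if (length(cache$mask_idx)) {
    grads$mask_tok <- colSums(dX0[cache$mask_idx, , drop = FALSE])
    dX0[cache$mask_idx, ] <- 0
  }
  # e_l branch
  grads$E <- crossprod(cache$lmat, dX0)
  # e_c branch
  dT2 <- sweep(dX0, 2, params$e, "*")
  grads$e <- colSums(dX0 * cache$T2)
  dZ2 <- dT2 * (1 - cache$T2^2)
  grads$phi_W2 <- crossprod(cache$H1, dZ2)
  grads$phi_b2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, params$phi_W2)
  dZ1 <- dH1 * (1 - cache$H1^2)
  grads$phi_W1 <- colSums(dZ1 * cache$c_vec)
  grads$phi_b1 <- colSums(dZ1)
  grads
}

# weighted binary cross-entropy on logits; labels/weights same shape as
# logits. Returns mean loss and d(loss)/d(logits).
bce_loss <- function(logits, labels, weights = NULL) {
  if (is.null(weights)) weights <- array(1, dim(as.matrix(logits)))
  z <- as.matrix(logits); y <- as.matrix(labels); w <- as.matrix(weights)
  sp <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  wsum <- sum(w)
  loss <- sum(w * (sp - y * z)) / wsum
  dz <- w * (1 / (1 + exp(-z)) - y) / wsum
  list(loss = loss, dlogits = dz)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
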