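# Transformer internals: weight initialization, forward pass with cache,
# and hand-written backpropagation. Batches are processed with the sequence
# dimension stacked, i.e. a batch of n examples of shape (L, d) lives in an
# (n*L) x d matrix whose rows (i-1)*L + 1 ... i*L belong to example i.

LN_EPS <- 1e-5
BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

block_has_ffn <- function(cfg, b) {
  b < cfg$n_encoder_blocks || cfg$symmetric_blocks
}

# Flat named weight list; *_rm / *_rv are batch-norm running statistics and
# are not trained.
init_weights <- function(cfg, seed) {
  with_seed(seed, {
    d <- cfg$embed_dim; hh <- cfg$n_heads * cfg$head_size
    w <- list()
    for (b in seq_len(cfg$n_encoder_blocks)) {
      p <- sprintf("b%d_", b)
      for (m in c("Wq", "Wk", "Wv")) w[[paste0(p, "mha_", m)]] <- glorot(d, hh)
      for (m in c("bq", "bk", "bv")) w[[paste0(p, "mha_", m)]] <- numeric(hh)
      w[[paste0(p, "mha_Wo")]] <- glorot(hh, d)
      w[[paste0(p, "mha_bo")]] <- numeric(d)
      if (block_has_ffn(cfg, b)) {
        w[[paste0(p, "lna_g")]] <- rep(1, d)
        w[[paste0(p, "lna_b")]] <- numeric(d)
        w[[paste0(p, "ffn1_W")]] <- glorot(d, cfg$ffn_units)
        w[[paste0(p, "ffn1_b")]] <- numeric(cfg$ffn_units)
        w[[paste0(p, "ffn2_W")]] <- glorot(cfg$ffn_units, d)
        w[[paste0(p, "ffn2_b")]] <- numeric(d)
        w[[paste0(p, "lnb_g")]] <- rep(1, d)
        w[[paste0(p, "lnb_b")]] <- numeric(d)
      }
    }
    prev <- d
    for (j in seq_along(cfg$head_units)) {
      u <- cfg$head_units[j]
      w[[sprintf("head%d_W", j)]] <- glorot(prev, u)
      w[[sprintf("head%d_b", j)]] <- numeric(u)
      w[[sprintf("bn%d_g", j)]] <- rep(1, u)
      w[[sprintf("bn%d_b", j)]] <- numeric(u)
      w[[sprintf("bn%d_rm", j)]] <- numeric(u)
      w[[sprintf("bn%d_rv", j)]] <- rep(1, u)
      w[[sprintf("lnh%d_g", j)]] <- rep(1, u)
      w[[sprintf("lnh%d_b", j)]] <- numeric(u)
      prev <- u
    }
    w$out_W <- glorot(prev, cfg$n_classes)
    w$out_b <- numeric(cfg$n_classes)
    w
  })
}

trainable_names <- function(w) names(w)[!grepl("_(rm|rv)$", names(w))]

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

drop_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((stats::runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(Y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"), xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, g, "*")
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

bn_fwd <- function(X, g, b, rm, rv, train) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, inv, "*")
    list(Y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"), xhat = xhat,
         inv = inv,
         new_rm = BN_MOMENTUM * rm + (1 - BN_MOMENTUM) * mu,
         new_rv = BN_MOMENTUM * rv + (1 - BN_MOMENTUM) * v)
  } else {
    xhat <- sweep(sweep(X, 2, rm), 2, 1 / sqrt(rv + BN_EPS), "*")
    list(Y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"))
  }
}

bn_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  m <- nrow(dY); f <- ncol(dY)
  dxhat <- sweep(dY, 2, g, "*")
  cm1 <- matrix(colMeans(dxhat), m, f, byrow = TRUE)
  cm2 <- matrix(colMeans(dxhat * xhat), m, f, byrow = TRUE)
  dX <- sweep(dxhat - cm1 - xhat * cm2, 2, cache$inv, "*")
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

mha_fwd <- function(E, w, p, n, L, h, hs) {
  Q <- add_bias(E %*% w[[paste0(p, "mha_Wq")]], w[[paste0(p, "mha_bq")]])
  K <- add_bias(E %*% w[[paste0(p, "mha_Wk")]], w[[paste0(p, "mha_bk")]])
  V <- add_bias(E %*% w[[paste0(p, "mha_Wv")]], w[[paste0(p, "mha_bv")]])
  scale <- 1 / sqrt(hs)
  A <- vector("list", n)
  Hcat <- matrix(0, n * L, h * hs)
  for (i in seq_len(n)) {
    ri <- ((i - 1L) * L + 1L):(i * L)
    Ai <- array(0, c(L, L, h))
    for (hd in seq_len(h)) {
      cols <- ((hd - 1L) * hs + 1L):(hd * hs)
      S <- (Q[ri, cols, drop = FALSE] %*%
              t(K[ri, cols, drop = FALSE])) * scale
      S <- S - apply(S, 1, max)
      Ae <- exp(S)
      Ae <- Ae / rowSums(Ae)
      Ai[, , hd] <- Ae
      Hcat[ri, cols] <- Ae %*% V[ri, cols, drop = FALSE]
    }
    A[[i]] <- Ai
  }
  O <- add_bias(Hcat %*% w[[paste0(p, "mha_Wo")]], w[[paste0(p, "mha_bo")]])
  list(O = O, Q = Q, K = K, V = V, A = A, Hcat = Hcat, E = E)
}

mha_bwd <- function(dO, cache, w, p, n, L, h, hs) {
  g <- list()
  g[[paste0(p, "mha_Wo")]] <- t(cache$Hcat) %*% dO
  g[[paste0(p, "mha_bo")]] <- colSums(dO)
  dH <- dO %*% t(w[[paste0(p, "mha_Wo")]])
  scale <- 1 / sqrt(hs)
  dQ <- matrix(0, n * L, h * hs)
  dK <- dQ; dV <- dQ
  for (i in seq_len(n)) {
    ri <- ((i - 1L) * L + 1L):(i * L)
    for (hd in seq_len(h)) {
      cols <- ((hd - 1L) * hs + 1L):(hd * hs)
      Ae <- cache$A[[i]][, , hd]
      dHh <- dH[ri, cols, drop = FALSE]
      Vh <- cache$V[ri, cols, drop = FALSE]
      dA <- dHh %*% t(Vh)
      dV[ri, cols] <- t(Ae) %*% dHh
      dS <- Ae * (dA - rowSums(Ae * dA))
      dQ[ri, cols] <- (dS %*% cache$K[ri, cols, drop = FALSE]) * scale
      dK[ri, cols] <- (t(dS) %*% cache$Q[ri, cols, drop = FALSE]) * scale
    }
  }
  E <- cache$E
  g[[paste0(p, "mha_Wq")]] <- t(E) %*% dQ
  g[[paste0(p, "mha_bq")]] <- colSums(dQ)
  g[[paste0(p, "mha_Wk")]] <- t(E) %*% dK
  g[[paste0(p, "mha_bk")]] <- colSums(dK)
  g[[paste0(p, "mha_Wv")]] <- t(E) %*% dV
  g[[paste0(p, "mha_bv")]] <- colSums(dV)
  dE <- dQ %*% t(w[[paste0(p, "mha_Wq")]]) +
    dK %*% t(w[[paste0(p, "mha_Wk")]]) +
    dV %*% t(w[[paste0(p, "mha_Wv")]])
  list(dE = dE, grads = g)
}

# Forward pass over a feature batch X (n x L x d array). Returns class
# probabilities, plus the full activation cache when `collect = TRUE` and
# updated batch-norm running stats when `train = TRUE`. Dropout draws come
# from the current RNG stream.
model_forward <- function(w, cfg, X, train = FALSE, collect = FALSE) {
  n <- dim(X)[1]; L <- cfg$seq_len; d <- cfg$embed_dim
  stopifnot(dim(X)[2] == L, dim(X)[3] == d)
  pe <- positional_encoding(L, d)
  E <- matrix(aperm(X, c(2, 1, 3)), n * L, d) + pe[rep(seq_len(L), n), ]
  cache <- list(blocks = vector("list", cfg$n_encoder_blocks))
  bn_updates <- list()
  for (b in seq_len(cfg$n_encoder_blocks)) {
    p <- sprintf("b%d_", b)
    bc <- list(E_in = E)
    mha <- mha_fwd(E, w, p, n, L, cfg$n_heads, cfg$head_size)
    Ad <- mha$O
    bc$mask_att <- if (train) drop_mask(dim(Ad), cfg$dropout_attention)
    if (!is.null(bc$mask_att)) Ad <- Ad * bc$mask_att
    R <- E + Ad
    if (block_has_ffn(cfg, b)) {
      lna <- ln_fwd(R, w[[paste0(p, "lna_g")]], w[[paste0(p, "lna_b")]])
      N1 <- lna$Y
      H1pre <- add_bias(N1 %*% w[[paste0(p, "ffn1_W")]],
                        w[[paste0(p, "ffn1_b")]])
      H1 <- pmax(H1pre, 0)
      bc$mask_ffn <- if (train) drop_mask(dim(H1), cfg$dropout_attention)
      H1d <- if (!is.null(bc$mask_ffn)) H1 * bc$mask_ffn else H1
      F2 <- add_bias(H1d %*% w[[paste0(p, "ffn2_W")]],
                     w[[paste0(p, "ffn2_b")]])
      R2 <- N1 + F2
      lnb <- ln_fwd(R2, w[[paste0(p, "lnb_g")]], w[[paste0(p, "lnb_b")]])
      E <- lnb$Y
      bc <- c(bc, list(mha = mha, lna = lna, N1 = N1, H1pre = H1pre,
                       H1d = H1d, lnb = lnb))
    } else {
      E <- R
      bc$mha <- mha
    }
    cache$blocks[[b]] <- bc
  }
  # global average pooling over the L sequence positions
  grp <- rep(seq_len(n), each = L)
  P <- rowsum(E, grp) / L
  rownames(P) <- NULL
  cache$gap_in_rows <- n * L
  H <- P
  for (j in seq_along(cfg$head_units)) {
    hc <- list(X_in = H)
    Zpre <- add_bias(H %*% w[[sprintf("head%d_W", j)]],
                     w[[sprintf("head%d_b", j)]])
    Z <- pmax(Zpre, 0)
    bn <- bn_fwd(Z, w[[sprintf("bn%d_g", j)]], w[[sprintf("bn%d_b", j)]],
                 w[[sprintf("bn%d_rm", j)]], w[[sprintf("bn%d_rv", j)]],
                 train)
    if (train) {
      bn_updates[[sprintf("bn%d_rm", j)]] <- bn$new_rm
      bn_updates[[sprintf("bn%d_rv", j)]] <- bn$new_rv
    }
    B <- bn$Y
    hc$mask <- if (train) drop_mask(dim(B), cfg$dropout_ffn)
    Bd <- if (!is.null(hc$mask)) B * hc$mask else B
    ln <- ln_fwd(Bd, w[[sprintf("lnh%d_g", j)]], w[[sprintf("lnh%d_b", j)]])
    H <- ln$Y
    cache[[sprintf("head%d", j)]] <- c(hc, list(Zpre = Zpre, Z = Z, bn = bn,
                                                ln = ln))
  }
  logits <- add_bias(H %*% w$out_W, w$out_b)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  cache$H_final <- H
  out <- list(probs = probs, logits = logits)
  if (collect) out$cache <- cache
  if (train) out$bn_updates <- bn_updates
  out
}

# Backpropagation from d(loss)/d(logits); returns gradients for every
# trainable weight.
model_backward <- function(w, cfg, cache, dlogits, n) {
  L <- cfg$seq_len
  g <- list()
  g$out_W <- t(cache$H_final) %*% dlogits
  g$out_b <- colSums(dlogits)
  dH <- dlogits %*% t(w$out_W)
  for (j in rev(seq_along(cfg$head_units))) {
    hc <- cache[[sprintf("head%d", j)]]
    ln <- ln_bwd(dH, hc$ln, w[[sprintf("lnh%d_g", j)]])
    g[[sprintf("lnh%d_g", j)]] <- ln$dg
    g[[sprintf("lnh%d_b", j)]] <- ln$db
    dBd <- ln$dX
    dB <- if (!is.null(hc$mask)) dBd * hc$mask else dBd
    bn <- bn_bwd(dB, hc$bn, w[[sprintf("bn%d_g", j)]])
    g[[sprintf("bn%d_g", j)]] <- bn$dg
    g[[sprintf("bn%d_b", j)]] <- bn$db
    dZ <- bn$dX * (hc$Zpre > 0)
    g[[sprintf("head%d_W", j)]] <- t(hc$X_in) %*% dZ
    g[[sprintf("head%d_b", j)]] <- colSums(dZ)
    dH <- dZ %*% t(w[[sprintf("head%d_W", j)]])
  }
  # undo global average pooling
  dE <- dH[rep(seq_len(n), each = L), , drop = FALSE] / L
  for (b in rev(seq_len(cfg$n_encoder_blocks))) {
    p <- sprintf("b%d_", b)
    bc <- cache$blocks[[b]]
    if (block_has_ffn(cfg, b)) {
      lnb <- ln_bwd(dE, bc$lnb, w[[paste0(p, "lnb_g")]])
      g[[paste0(p, "lnb_g")]] <- lnb$dg
      g[[paste0(p, "lnb_b")]] <- lnb$db
      dR2 <- lnb$dX
      dF2 <- dR2
      g[[paste0(p, "ffn2_W")]] <- t(bc$H1d) %*% dF2
      g[[paste0(p, "ffn2_b")]] <- colSums(dF2)
      dH1d <- dF2 %*% t(w[[paste0(p, "ffn2_W")]])
      dH1 <- if (!is.null(bc$mask_ffn)) dH1d * bc$mask_ffn else dH1d
      dH1pre <- dH1 * (bc$H1pre > 0)
      g[[paste0(p, "ffn1_W")]] <- t(bc$N1) %*% dH1pre
      g[[paste0(p, "ffn1_b")]] <- colSums(dH1pre)
      dN1 <- dR2 + dH1pre %*% t(w[[paste0(p, "ffn1_W")]])
      lna <- ln_bwd(dN1, bc$lna, w[[paste0(p, "lna_g")]])
      g[[paste0(p, "lna_g")]] <- lna$dg
      g[[paste0(p, "lna_b")]] <- lna$db
      dR <- lna$dX
    } else {
      dR <- dE
    }
    dAd <- if (!is.null(bc$mask_att)) dR * bc$mask_att else dR
    mb <- mha_bwd(dAd, bc$mha, w, p, n, L, cfg$n_heads, cfg$head_size)
    g <- c(g, mb$grads)
    dE <- dR + mb$dE
  }
  g
}

# Gradient of the batch-mean focal loss with respect to the logits.
focal_loss_grad_logits <- function(probs, true_class, gamma, alpha) {
  n <- nrow(probs)
  pc <- pmin(pmax(probs[cbind(seq_len(n), true_class)], 1e-12), 1 - 1e-12)
  # dL/dp_c for each example
  focus <- if (gamma > 0) gamma * (1 - pc)^(gamma - 1) * log(pc) else 0
  dLdp <- -alpha[true_class] * ((1 - pc)^gamma / pc - focus)
  dZ <- -probs * (dLdp * pc)           # j != c part via softmax jacobian
  dZ[cbind(seq_len(n), true_class)] <-
    dZ[cbind(seq_len(n), true_class)] + dLdp * pc
  dZ / n
}
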