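#' Masked-language-model encoder configuration
#'
#' A bidirectional transformer encoder (token + learned absolute position
#' embeddings, pre-LayerNorm multi-head self-attention and feed-forward
#' blocks) trained to predict masked tokens with cross-entropy. No
#' next-sentence objective and no CLS/SEP tokens: pooling is mean-based.
#' The full-scale configuration (768 dims, vocab 8192) is expressible;
#' the desk-scale default (2 layers, 4 heads, 64 dims) trains on one CPU
#' in minutes.
#'
#' @param embed_dim embedding width (default 64; 768 at full scale)
#' @param n_layers encoder blocks (default 2)
#' @param n_heads attention heads; must divide `embed_dim`
#' @param mask_rate fraction of tokens masked per sequence per step
#'   (default 0.15)
#' @param max_tokens maximum sequence length (default 512)
#' @param epochs passes over the corpus (default 20)
#' @param batch_size sequences per Adam update (gradient accumulation;
#'   default 8)
#' @param learning_rate Adam step size
#' @param mask_scheme `"mask_all"` replaces every selected position with
#'   the MASK token (the default reading); `"bert"` uses the 80/10/10
#'   mask/random/keep convention
#' @param seed training seed (masking and initialization)
#' @return list of class `mlm_config`
#' @export
mlm_config <- function(embed_dim = 64L, n_layers = 2L, n_heads = 4L,
                       mask_rate = 0.15, max_tokens = 512L, epochs = 20L,
                       batch_size = 8L, learning_rate = 1e-3,
                       mask_scheme = c("mask_all", "bert"), seed = 1L) {
  mask_scheme <- match.arg(mask_scheme)
  if (embed_dim %% n_heads != 0L)
    config_error("embed_dim must be divisible by n_heads")
  if (!(mask_rate > 0 && mask_rate < 1))
    config_error("mask_rate must be in (0,1)")
  if (batch_size < 1L) config_error("batch_size must be >= 1")
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), mask_rate = mask_rate,
                 max_tokens = as.integer(max_tokens),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 mask_scheme = mask_scheme, seed = as.integer(seed)),
            class = "mlm_config")
}

# recursive gradient accumulation; token/position embeddings are kept
# sparse (row lists / variable-length matrices) until the Adam step
add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  acc$W_out <- acc$W_out + g$W_out
  acc$b_out <- acc$b_out + g$b_out
  acc$lnf_g <- acc$lnf_g + g$lnf_g
  acc$lnf_b <- acc$lnf_b + g$lnf_b
  for (li in seq_along(acc$layers))
    for (nm in names(acc$layers[[li]]))
      acc$layers[[li]][[nm]] <- acc$layers[[li]][[nm]] + g$layers[[li]][[nm]]
  acc$tok_emb$rows <- c(acc$tok_emb$rows, g$tok_emb$rows)
  acc$tok_emb$grad <- rbind(acc$tok_emb$grad, g$tok_emb$grad)
  pa <- acc$pos_emb; pb <- g$pos_emb
  if (nrow(pa) < nrow(pb)) { tmp <- pa; pa <- pb; pb <- tmp }
  pa[seq_len(nrow(pb)), ] <- pa[seq_len(nrow(pb)), ] + pb
  acc$pos_emb <- pa
  acc
}

scale_grads <- function(g, s) {
  rapply(g, function(x) x * s, how = "replace",
         classes = c("numeric", "matrix", "integer", "array"))
}

# parameter initialization (BERT-style truncated-ish normal, sd 0.02)
init_mlm_params <- function(vocab_size, cfg) {
  d <- cfg$embed_dim; h <- 4L * d
  rn <- function(r, c) matrix(rnorm(r * c, 0, 0.02), r, c)
  layer <- function() list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = rn(d, d), Wk = rn(d, d), Wv = rn(d, d), Wo = rn(d, d),
    bq = rep(0, d), bk = rep(0, d), bv = rep(0, d), bo = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = rn(d, h), b1 = rep(0, h), W2 = rn(h, d), b2 = rep(0, d))
  list(tok_emb = rn(vocab_size + 1L, d),   # last row is [MASK]
       pos_emb = rn(cfg$max_tokens, d),
       layers = lapply(seq_len(cfg$n_layers), function(i) layer()),
       lnf_g = rep(1, d), lnf_b = rep(0, d),
       W_out = rn(d, vocab_size), b_out = rep(0, vocab_size))
}

ln_fwd <- function(x, g, b, eps = 1e-5) {
  n <- nrow(x); d <- ncol(x)
  mu <- .rowMeans(x, n, d)
  xc <- x - mu
  inv <- 1 / sqrt(.rowMeans(xc * xc, n, d) + eps)
  xhat <- xc * inv
  ix <- col(xhat)
  list(y = xhat * g[ix] + b[ix], xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  n <- nrow(dy); d <- ncol(dy)
  dxhat <- dy * g[col(dy)]
  dx <- cache$inv * (dxhat - .rowMeans(dxhat, n, d) -
                       cache$xhat * .rowMeans(dxhat * cache$xhat, n, d))
  list(dx = dx, dg = .colSums(dy * cache$xhat, n, d),
       db = .colSums(dy, n, d))
}

softmax_rows <- function(s) {
  n <- nrow(s); d <- ncol(s)
  rm <- s[cbind(seq_len(n), max.col(s, ties.method = "first"))]
  e <- exp(s - rm[row(s)])
  e / .rowSums(e, n, d)
}

# forward + (optionally) backward through the encoder for one sequence.
# Returns final hidden states; when targets are given, also the masked-
# token loss and gradients for every parameter.
mlm_seq_pass <- function(params, cfg, ids, mpos = NULL, targets = NULL) {
  d <- cfg$embed_dim; nh <- cfg$n_heads; dh <- d %/% nh
  L <- length(ids)
  X <- params$tok_emb[ids, , drop = FALSE] +
    params$pos_emb[seq_len(L), , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  h_idx <- lapply(seq_len(nh), function(k) ((k - 1L) * dh + 1L):(k * dh))
  for (li in seq_len(cfg$n_layers)) {
    P <- params$layers[[li]]
    c1 <- ln_fwd(X, P$ln1_g, P$ln1_b)
    Q <- c1$y %*% P$Wq + P$bq[col(X)]
    K <- c1$y %*% P$Wk + P$bk[col(X)]
    V <- c1$y %*% P$Wv + P$bv[col(X)]
    O <- matrix(0, L, d); A_list <- vector("list", nh)
    for (k in seq_len(nh)) {
      ix <- h_idx[[k]]
      S <- Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      A_list[[k]] <- A
      O[, ix] <- A %*% V[, ix, drop = FALSE]
    }
    attn <- O %*% P$Wo + P$bo[col(X)]
    X2 <- X + attn
    c2 <- ln_fwd(X2, P$ln2_g, P$ln2_b)
    H1 <- c2$y %*% P$W1 + P$b1[col(matrix(0, L, 4L * d))]
    Z <- pmax(H1, 0)                      # ReLU feed-forward
    FF <- Z %*% P$W2 + P$b2[col(X)]
    Xout <- X2 + FF
    caches[[li]] <- list(c1 = c1, Q = Q, K = K, V = V, O = O, A = A_list,
                         X = X, X2 = X2, c2 = c2, H1 = H1, Z = Z)
    X <- Xout
  }
  cf <- ln_fwd(X, params$lnf_g, params$lnf_b)
  H <- cf$y
  if (is.null(targets))
    return(list(hidden = H, loss = NA_real_))
  if (!length(mpos))
    return(list(hidden = H, loss = 0, grads = NULL))
  logits <- H[mpos, , drop = FALSE] %*% params$W_out +
    params$b_out[col(matrix(0, length(mpos), ncol(params$W_out)))]
  pr <- softmax_rows(logits)
  nm <- length(mpos)
  loss <- -mean(log(pmax(pr[cbind(seq_len(nm), targets)], 1e-12)))
  # ---- backward ----
  dlog <- pr
  dlog[cbind(seq_len(nm), targets)] <- dlog[cbind(seq_len(nm), targets)] - 1
  dlog <- dlog / nm
  g <- list(W_out = crossprod(H[mpos, , drop = FALSE], dlog),
            b_out = colSums(dlog))
  dH <- matrix(0, L, d)
  dH[mpos, ] <- dlog %*% t(params$W_out)
  bf <- ln_bwd(dH, cf, params$lnf_g)
  g$lnf_g <- bf$dg; g$lnf_b <- bf$db
  dX <- bf$dx
  g$layers <- vector("list", cfg$n_layers)
  for (li in rev(seq_len(cfg$n_layers))) {
    P <- params$layers[[li]]; ca <- caches[[li]]
    # FFN block
    dFF <- dX
    gW2 <- crossprod(ca$Z, dFF); gb2 <- colSums(dFF)
    dZ <- dFF %*% t(P$W2)
    dH1 <- dZ * (ca$H1 > 0)
    gW1 <- crossprod(ca$c2$y, dH1); gb1 <- colSums(dH1)
    d_c2y <- dH1 %*% t(P$W1)
    b2n <- ln_bwd(d_c2y, ca$c2, P$ln2_g)
    dX2 <- dX + b2n$dx
    # attention block
    dattn <- dX2
    gWo <- crossprod(ca$O, dattn); gbo <- colSums(dattn)
    dO <- dattn %*% t(P$Wo)
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (k in seq_len(nh)) {
      ix <- h_idx[[k]]; A <- ca$A[[k]]
      dOk <- dO[, ix, drop = FALSE]
      dA <- dOk %*% t(ca$V[, ix, drop = FALSE])
      dV[, ix] <- crossprod(A, dOk)
      dS <- A * (dA - .rowSums(dA * A, nrow(A), ncol(A)))
      dQ[, ix] <- dS %*% ca$K[, ix, drop = FALSE] / sqrt(dh)
      dK[, ix] <- crossprod(dS, ca$Q[, ix, drop = FALSE]) / sqrt(dh)
    }
    gWq <- crossprod(ca$c1$y, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(ca$c1$y, dK); gbk <- colSums(dK)
    gWv <- crossprod(ca$c1$y, dV); gbv <- colSums(dV)
    d_c1y <- dQ %*% t(P$Wq) + dK %*% t(P$Wk) + dV %*% t(P$Wv)
    b1n <- ln_bwd(d_c1y, ca$c1, P$ln1_g)
    dX <- dX2 + b1n$dx
    g$layers[[li]] <- list(ln1_g = b1n$dg, ln1_b = b1n$db,
                           Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo,
                           bq = gbq, bk = gbk, bv = gbv, bo = gbo,
                           ln2_g = b2n$dg, ln2_b = b2n$db,
                           W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  # embeddings
  g$tok_emb <- list(rows = ids, grad = dX)   # sparse row update
  g$pos_emb <- dX
  list(hidden = H, loss = loss, grads = g)
}

# Adam with sparse token-embedding rows handled densely per used row
adam_update <- function(params, grads, state, lr, t,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      idx <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in idx) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    upd(p, g, m, v)
  }
  # token embedding: scatter the per-position grads into a dense grad
  ge <- grads$tok_emb
  dense <- matrix(0, nrow(params$tok_emb), ncol(params$tok_emb))
  for (i in seq_along(ge$rows))
    dense[ge$rows[i], ] <- dense[ge$rows[i], ] + ge$grad[i, ]
  grads$tok_emb <- dense
  pe <- grads$pos_emb
  dense_p <- matrix(0, nrow(params$pos_emb), ncol(params$pos_emb))
  dense_p[seq_len(nrow(pe)), ] <- pe
  grads$pos_emb <- dense_p
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

#' Train the masked-language-model encoder
#'
#' Per step one sequence is processed: `mask_rate` of its positions are
#' selected uniformly at random (seeded), replaced according to the
#' masking scheme, and the encoder is updated by Adam on the
#' cross-entropy of the true tokens at masked positions. Training is
#' deterministic given config seed (single-threaded).
#'
#' @param tokenized named list of integer token-id vectors (from
#'   [tokenize_and_filter()])
#' @param vocab_size tokenizer vocabulary size
#' @param config an [mlm_config()]
#' @param verbose print per-epoch mean loss
#' @return object of class `mlm_encoder` with `params`, `config`,
#'   `vocab_size` and `loss_history` (mean loss per epoch)
#' @export
train_mlm <- function(tokenized, vocab_size, config = mlm_config(),
                      verbose = FALSE) {
  if (!length(tokenized)) config_error("empty tokenized corpus")
  too_long <- lengths(tokenized) > config$max_tokens
  if (any(too_long))
    data_error("sequence longer than max_tokens; run tokenize_and_filter first")
  mask_id <- vocab_size + 1L
  with_seed(config$seed, {
    params <- init_mlm_params(vocab_size, config)
    state <- list(m = zero_like(params), v = zero_like(params))
    state$m$tok_emb <- params$tok_emb * 0; state$v$tok_emb <- params$tok_emb * 0
    t_step <- 0L
    loss_hist <- numeric(config$epochs)
    n_seq <- length(tokenized)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_seq)
      ep_loss <- 0; ep_n <- 0L
      acc <- NULL; nb <- 0L
      flush <- function() {
        if (nb == 0L) return(invisible())
        sc <- scale_grads(acc, 1 / nb)
        sc$tok_emb$rows <- acc$tok_emb$rows
        t_step <<- t_step + 1L
        r <- adam_update(params, sc, state, config$learning_rate, t_step)
        params <<- r$params; state <<- r$state
        acc <<- NULL; nb <<- 0L
        invisible()
      }
      for (si in ord) {
        ids <- tokenized[[si]]
        L <- length(ids)
        n_mask <- round(config$mask_rate * L)
        if (n_mask < 1L) next
        mpos <- sample.int(L, n_mask)
        targets <- ids[mpos]
        corrupted <- ids
        if (config$mask_scheme == "mask_all") {
          corrupted[mpos] <- mask_id
        } else {
          u <- runif(n_mask)
          corrupted[mpos] <- ifelse(
            u < 0.8, mask_id,
            ifelse(u < 0.9, sample.int(vocab_size, n_mask, replace = TRUE),
                   ids[mpos]))
        }
        out <- mlm_seq_pass(params, config, corrupted, mpos, targets)
        acc <- add_grads(acc, out$grads)
        nb <- nb + 1L
        if (nb >= config$batch_size) flush()
        ep_loss <- ep_loss + out$loss; ep_n <- ep_n + 1L
      }
      flush()
      loss_hist[ep] <- if (ep_n) ep_loss / ep_n else 0
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", ep, config$epochs,
                        loss_hist[ep]))
    }
    structure(list(params = params, config = config,
                   vocab_size = vocab_size, loss_history = loss_hist,
                   schema = "islandmeth-mlm-1"),
              class = "mlm_encoder")
  })
}

#' Masked-token prediction accuracy on a corpus (seeded)
#' @param model trained `mlm_encoder`
#' @param tokenized token-id list
#' @param seed masking seed
#' @return fraction of masked tokens predicted correctly
#' @export
mlm_masked_accuracy <- function(model, tokenized, seed = 1L) {
  cfg <- model$config
  mask_id <- model$vocab_size + 1L
  with_seed(seed, {
    hit <- 0L; tot <- 0L
    for (ids in tokenized) {
      L <- length(ids)
      n_mask <- max(1L, round(cfg$mask_rate * L))
      mpos <- sample.int(L, n_mask)
      corrupted <- ids; corrupted[mpos] <- mask_id
      H <- mlm_seq_pass(model$params, cfg, corrupted)$hidden
      logits <- H[mpos, , drop = FALSE] %*% model$params$W_out
      pred <- max.col(logits, ties.method = "first")
      hit <- hit + sum(pred == ids[mpos]); tot <- tot + n_mask
    }
    hit / tot
  })
}

#' Mean-pooled per-sequence embeddings
#'
#' Runs the encoder without masking; each sequence's vector is the
#' arithmetic mean of its final-layer token vectors. Per-sequence
#' computation makes embeddings invariant to corpus order.
#'
#' @param tokenized named list of token-id vectors
#' @param model trained `mlm_encoder`
#' @return matrix, one row per sequence (rownames = ids)
#' @export
embed_cgis <- function(tokenized, model) {
  bad <- vapply(tokenized, function(ids)
    any(ids < 1L | ids > model$vocab_size), logical(1))
  if (any(bad))
    data_error(sprintf("unknown token id in sequence %s",
                       names(tokenized)[bad][1]))
  out <- t(vapply(tokenized, function(ids) {
    H <- mlm_seq_pass(model$params, model$config, ids)$hidden
    colMeans(H)
  }, numeric(model$config$embed_dim)))
  rownames(out) <- names(tokenized)
  out
}

#' Serialize / reload a trained encoder (RDS with schema tag)
#' @param model `mlm_encoder`
#' @param path file
#' @export
write_mlm <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_mlm
#' @export
read_mlm <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "islandmeth-mlm-1"))
    data_error("not an islandmeth MLM checkpoint")
  x
}
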