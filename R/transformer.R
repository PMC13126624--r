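## Transformer encoder-decoder (pre-layer-norm variant, which trains stably
## without a warmup schedule at the small scales this package targets).
## Sequences are processed one at a time as T x d matrices; the target side
## of this task is at most 6 tokens long, so incremental decoding simply
## re-runs the decoder on the growing prefix.
##
## In the multimodal variant the standardized descriptor vector is
## concatenated to every encoder memory position and each position is
## projected back to the model dimension by a fully connected layer, so the
## decoder interface is unchanged from the unimodal case.

## ---- primitive blocks (forward caches + exact backward) -----------------

t_ln_f <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

t_ln_b <- function(cache, dy, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

t_attn_f <- function(xq, xkv, w, nh, causal = FALSE) {
  d <- ncol(xq)
  dk <- d / nh
  Q <- xq %*% w$Wq + rep(w$bq, each = nrow(xq))
  K <- xkv %*% w$Wk + rep(w$bk, each = nrow(xkv))
  V <- xkv %*% w$Wv + rep(w$bv, each = nrow(xkv))
  O <- matrix(0, nrow(xq), d)
  A_list <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
    if (causal && nrow(S) > 1) S[upper.tri(S)] <- -Inf
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  y <- O %*% w$Wo + rep(w$bo, each = nrow(xq))
  list(y = y, Q = Q, K = K, V = V, O = O, A = A_list,
       xq = xq, xkv = xkv, nh = nh, dk = dk)
}

t_attn_b <- function(cache, dy, w) {
  nh <- cache$nh; dk <- cache$dk
  dO <- dy %*% t(w$Wo)
  g <- list(Wo = crossprod(cache$O, dy), bo = colSums(dy))
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  g$Wq <- crossprod(cache$xq, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(cache$xkv, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(cache$xkv, dV); g$bv <- colSums(dV)
  list(dxq = dQ %*% t(w$Wq),
       dxkv = dK %*% t(w$Wk) + dV %*% t(w$Wv),
       grads = g)
}

t_ffn_f <- function(x, w) {
  z <- x %*% w$W1 + rep(w$b1, each = nrow(x))
  a <- pmax(z, 0)
  list(y = a %*% w$W2 + rep(w$b2, each = nrow(x)), x = x, z = z, a = a)
}

t_ffn_b <- function(cache, dy, w) {
  da <- dy %*% t(w$W2)
  dz <- da * (cache$z > 0)
  list(dx = dz %*% t(w$W1),
       grads = list(W1 = crossprod(cache$x, dz), b1 = colSums(dz),
                    W2 = crossprod(cache$a, dy), b2 = colSums(dy)))
}

drop_f <- function(x, p) {
  if (p <= 0) return(list(y = x, m = NULL))
  m <- matrix((stats::runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(y = x * m, m = m)
}

drop_b <- function(dy, m) if (is.null(m)) dy else dy * m

## ---- parameter initialisation ------------------------------------------

t_attn_params <- function(d) {
  list(Wq = glorot(d, d), bq = numeric(d), Wk = glorot(d, d), bk = numeric(d),
       Wv = glorot(d, d), bv = numeric(d), Wo = glorot(d, d), bo = numeric(d))
}

t_layer_params <- function(d, ffn, cross = FALSE) {
  p <- list(ln1_g = rep(1, d), ln1_b = numeric(d), self = t_attn_params(d))
  if (cross) {
    p$ln2_g <- rep(1, d); p$ln2_b <- numeric(d)
    p$cross <- t_attn_params(d)
  }
  p$lnf_g <- rep(1, d); p$lnf_b <- numeric(d)
  p$ffn <- list(W1 = glorot(d, ffn), b1 = numeric(ffn),
                W2 = glorot(ffn, d), b2 = numeric(d))
  p
}

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) out <- c(out, flatten_params(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

## view into a flat param list: sub("enc1") returns the nested sublist
pview <- function(params, prefix) {
  keys <- grep(paste0("^", prefix, "\\."), names(params), value = TRUE)
  nested <- list()
  for (k in keys) {
    parts <- strsplit(sub(paste0("^", prefix, "\\."), "", k), ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      nested[[parts]] <- params[[k]]
    } else {
      if (is.null(nested[[parts[1]]])) nested[[parts[1]]] <- list()
      nested[[parts[1]]][[parts[2]]] <- params[[k]]
    }
  }
  nested
}

prefix_grads <- function(grads, prefix) {
  flat <- flatten_params(grads, prefix)
  flat
}

transformer_init <- function(cfg, n_src, n_tgt, desc_dim, max_src, max_tgt) {
  d <- cfg$embedding_dim
  if (d %% cfg$heads != 0) {
    stop("`embedding_dim` must be divisible by `heads`", call. = FALSE)
  }
  with_seed(derive_seed(cfg$seed, "transformer-init"), {
    p <- list(
      E_src = glorot(n_src, d), E_tgt = glorot(n_tgt, d),
      P_src = matrix(stats::rnorm(max_src * d, 0, 0.02), max_src, d),
      P_tgt = matrix(stats::rnorm(max_tgt * d, 0, 0.02), max_tgt, d),
      enc_lnf_g = rep(1, d), enc_lnf_b = numeric(d),
      dec_lnf_g = rep(1, d), dec_lnf_b = numeric(d),
      W_out = glorot(d, n_tgt), b_out = numeric(n_tgt)
    )
    if (desc_dim > 0) {
      p$W_fuse <- glorot(d + desc_dim, d)
      p$b_fuse <- numeric(d)
    }
    for (l in seq_len(cfg$layers)) {
      p <- c(p, flatten_params(t_layer_params(d, cfg$ffn_dim), paste0("enc", l)))
      p <- c(p, flatten_params(t_layer_params(d, cfg$ffn_dim, cross = TRUE),
                               paste0("dec", l)))
    }
    p
  })
}

## ---- encoder / decoder forward (with caches) ----------------------------

transformer_encode <- function(params, cfg, src_ids, desc = NULL, p_drop = 0) {
  d <- cfg$embedding_dim
  Tn <- length(src_ids)
  Tn_use <- min(Tn, nrow(params$P_src))
  src_ids <- src_ids[seq_len(Tn_use)]
  x <- params$E_src[src_ids, , drop = FALSE] * sqrt(d) +
    params$P_src[seq_len(Tn_use), , drop = FALSE]
  dr0 <- drop_f(x, p_drop)
  x <- dr0$y
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    w <- pview(params, paste0("enc", l))
    ln1 <- t_ln_f(x, w$ln1_g, w$ln1_b)
    at <- t_attn_f(ln1$y, ln1$y, w$self, cfg$heads)
    dr1 <- drop_f(at$y, p_drop)
    a <- x + dr1$y
    ln2 <- t_ln_f(a, w$lnf_g, w$lnf_b)
    ff <- t_ffn_f(ln2$y, w$ffn)
    dr2 <- drop_f(ff$y, p_drop)
    xo <- a + dr2$y
    caches[[l]] <- list(ln1 = ln1, at = at, dr1 = dr1$m, x_in = x,
                        ln2 = ln2, ff = ff, dr2 = dr2$m, a = a)
    x <- xo
  }
  lnf <- t_ln_f(x, params$enc_lnf_g, params$enc_lnf_b)
  mem_pre <- lnf$y
  fuse <- NULL
  mem <- mem_pre
  if (!is.null(desc)) {
    du <- cbind(mem_pre, matrix(desc, nrow(mem_pre), length(desc), byrow = TRUE))
    mem <- du %*% params$W_fuse + rep(params$b_fuse, each = nrow(du))
    fuse <- du
  }
  list(mem = mem, ids = src_ids, dr0 = dr0$m, caches = caches, lnf = lnf,
       x_final = x, fuse = fuse)
}

transformer_decode_forward <- function(params, cfg, tgt_ids, mem, p_drop = 0) {
  d <- cfg$embedding_dim
  Tn <- length(tgt_ids)
  x <- params$E_tgt[tgt_ids, , drop = FALSE] * sqrt(d) +
    params$P_tgt[seq_len(Tn), , drop = FALSE]
  dr0 <- drop_f(x, p_drop)
  x <- dr0$y
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    w <- pview(params, paste0("dec", l))
    ln1 <- t_ln_f(x, w$ln1_g, w$ln1_b)
    sa <- t_attn_f(ln1$y, ln1$y, w$self, cfg$heads, causal = TRUE)
    dr1 <- drop_f(sa$y, p_drop)
    a <- x + dr1$y
    ln2 <- t_ln_f(a, w$ln2_g, w$ln2_b)
    ca <- t_attn_f(ln2$y, mem, w$cross, cfg$heads)
    dr2 <- drop_f(ca$y, p_drop)
    b2 <- a + dr2$y
    ln3 <- t_ln_f(b2, w$lnf_g, w$lnf_b)
    ff <- t_ffn_f(ln3$y, w$ffn)
    dr3 <- drop_f(ff$y, p_drop)
    xo <- b2 + dr3$y
    caches[[l]] <- list(ln1 = ln1, sa = sa, dr1 = dr1$m, x_in = x,
                        ln2 = ln2, ca = ca, dr2 = dr2$m, a = a,
                        ln3 = ln3, ff = ff, dr3 = dr3$m, b2 = b2)
    x <- xo
  }
  lnf <- t_ln_f(x, params$dec_lnf_g, params$dec_lnf_b)
  logits <- lnf$y %*% params$W_out + rep(params$b_out, each = Tn)
  list(logits = logits, ids = tgt_ids, dr0 = dr0$m, caches = caches,
       lnf = lnf, x_final = x, h = lnf$y)
}

## Full backward pass for one sequence.  `denc`/`ddec` are the cache lists
## returned by the forward passes; `dlogits` the gradient at the decoder
## output.  Returns a flat named grad list plus dE accumulators.
transformer_backward <- function(params, cfg, enc, dec, dlogits) {
  d <- cfg$embedding_dim
  g <- list()
  g$W_out <- crossprod(dec$h, dlogits)
  g$b_out <- colSums(dlogits)
  dh <- dlogits %*% t(params$W_out)
  lb <- t_ln_b(dec$lnf, dh, params$dec_lnf_g)
  g$dec_lnf_g <- lb$dg; g$dec_lnf_b <- lb$db
  dx <- lb$dx
  dmem <- matrix(0, nrow(enc$mem), d)
  for (l in rev(seq_len(cfg$layers))) {
    w <- pview(params, paste0("dec", l))
    cc <- dec$caches[[l]]
    pre <- paste0("dec", l)
    ## ffn sublayer
    dff_out <- drop_b(dx, cc$dr3)
    fb <- t_ffn_b(cc$ff, dff_out, w$ffn)
    g <- add_grads(g, prefix_grads(fb$grads, paste0(pre, ".ffn")))
    l3 <- t_ln_b(cc$ln3, fb$dx, w$lnf_g)
    g[[paste0(pre, ".lnf_g")]] <- l3$dg; g[[paste0(pre, ".lnf_b")]] <- l3$db
    db2 <- dx + l3$dx
    ## cross-attention sublayer
    dca_out <- drop_b(db2, cc$dr2)
    ab <- t_attn_b(cc$ca, dca_out, w$cross)
    g <- add_grads(g, prefix_grads(ab$grads, paste0(pre, ".cross")))
    dmem <- dmem + ab$dxkv
    l2 <- t_ln_b(cc$ln2, ab$dxq, w$ln2_g)
    g[[paste0(pre, ".ln2_g")]] <- l2$dg; g[[paste0(pre, ".ln2_b")]] <- l2$db
    da <- db2 + l2$dx
    ## self-attention sublayer
    dsa_out <- drop_b(da, cc$dr1)
    sb <- t_attn_b(cc$sa, dsa_out, w$self)
    g <- add_grads(g, prefix_grads(sb$grads, paste0(pre, ".self")))
    l1 <- t_ln_b(cc$ln1, sb$dxq + sb$dxkv, w$ln1_g)
    g[[paste0(pre, ".ln1_g")]] <- l1$dg; g[[paste0(pre, ".ln1_b")]] <- l1$db
    dx <- da + l1$dx
  }
  dx <- drop_b(dx, dec$dr0)
  g$E_tgt <- embedding_grad(nrow(params$E_tgt), dec$ids, dx * sqrt(d))
  g$P_tgt <- matrix(0, nrow(params$P_tgt), d)
  g$P_tgt[seq_len(nrow(dx)), ] <- dx

  ## through the fusion layer into the encoder stack
  if (!is.null(enc$fuse)) {
    g$W_fuse <- crossprod(enc$fuse, dmem)
    g$b_fuse <- colSums(dmem)
    dmem <- (dmem %*% t(params$W_fuse))[, seq_len(d), drop = FALSE]
  }
  le <- t_ln_b(enc$lnf, dmem, params$enc_lnf_g)
  g$enc_lnf_g <- le$dg; g$enc_lnf_b <- le$db
  dx <- le$dx
  for (l in rev(seq_len(cfg$layers))) {
    w <- pview(params, paste0("enc", l))
    cc <- enc$caches[[l]]
    pre <- paste0("enc", l)
    dff_out <- drop_b(dx, cc$dr2)
    fb <- t_ffn_b(cc$ff, dff_out, w$ffn)
    g <- add_grads(g, prefix_grads(fb$grads, paste0(pre, ".ffn")))
    l2 <- t_ln_b(cc$ln2, fb$dx, w$lnf_g)
    g[[paste0(pre, ".lnf_g")]] <- l2$dg; g[[paste0(pre, ".lnf_b")]] <- l2$db
    da <- dx + l2$dx
    dat_out <- drop_b(da, cc$dr1)
    ab <- t_attn_b(cc$at, dat_out, w$self)
    g <- add_grads(g, prefix_grads(ab$grads, paste0(pre, ".self")))
    l1 <- t_ln_b(cc$ln1, ab$dxq + ab$dxkv, w$ln1_g)
    g[[paste0(pre, ".ln1_g")]] <- l1$dg; g[[paste0(pre, ".ln1_b")]] <- l1$db
    dx <- da + l1$dx
  }
  dx <- drop_b(dx, enc$dr0)
  g$E_src <- embedding_grad(nrow(params$E_src), enc$ids, dx * sqrt(d))
  g$P_src <- matrix(0, nrow(params$P_src), d)
  g$P_src[seq_len(nrow(dx)), ] <- dx
  g
}

## Mean token cross-entropy over a list of (src, tgt_in, tgt_out, desc)
## sequences, with exact gradients.
transformer_loss <- function(params, seqs, cfg, compute_grads = TRUE,
                             training = FALSE) {
  p_drop <- if (training) cfg$dropout else 0
  n_tok <- sum(vapply(seqs, function(s) length(s$tgt_out), 1L))
  loss <- 0
  grads <- if (compute_grads) zeros_like(params)
  for (s in seqs) {
    enc <- transformer_encode(params, cfg, s$src, s$desc, p_drop)
    dec <- transformer_decode_forward(params, cfg, s$tgt_in, enc$mem, p_drop)
    lp <- log_softmax_rows(dec$logits)
    Tn <- length(s$tgt_out)
    loss <- loss - sum(lp[cbind(seq_len(Tn), s$tgt_out)])
    if (compute_grads) {
      dlogits <- exp(lp)
      dlogits[cbind(seq_len(Tn), s$tgt_out)] <-
        dlogits[cbind(seq_len(Tn), s$tgt_out)] - 1
      dlogits <- dlogits / n_tok
      grads <- add_grads(grads, transformer_backward(params, cfg, enc, dec, dlogits))
    }
  }
  out <- list(loss = loss / n_tok)
  if (compute_grads) out$grads <- grads
  out
}

## ---- incremental decoding interface ------------------------------------

#' @export
decode_init.transformer_seq2seq <- function(model, src_ids, descriptor = NULL, ...) {
  desc <- NULL
  if (isTRUE(model$config$multimodal)) {
    if (is.null(descriptor)) {
      stop("multimodal model requires a descriptor vector", call. = FALSE)
    }
    if (length(descriptor) != model$desc_dim) {
      stop(sprintf("descriptor length %d does not match fit-time length %d",
                   length(descriptor), model$desc_dim), call. = FALSE)
    }
    desc <- as.numeric(descriptor)
  }
  enc <- transformer_encode(model$params, model$config, src_ids, desc)
  list(mem = enc$mem, prefix = integer(0))
}

#' @export
decode_step.transformer_seq2seq <- function(model, state, token, ...) {
  prefix <- c(state$prefix, token)
  dec <- transformer_decode_forward(model$params, model$config, prefix,
                                    state$mem)
  lp <- log_softmax_rows(dec$logits[nrow(dec$logits), , drop = FALSE])
  list(logp = as.numeric(lp), state = list(mem = state$mem, prefix = prefix))
}
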