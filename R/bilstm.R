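## BiLSTM encoder-decoder.
##
## The encoder runs a forward and a backward LSTM over the embedded SMILES
## characters; their final hidden states are concatenated (together with the
## standardized descriptor vector when the model is multimodal) and passed
## through fully connected tanh layers ("bridge") to form the initial hidden
## and cell state of the unidirectional LSTM decoder.  The bridged hidden
## state additionally serves as a fixed context vector appended to the
## decoder input at every step (the classic RNN encoder-decoder context
## feed), so the source summary does not have to survive in the recurrent
## state across the whole target sequence.  ATC characters are emitted
## through a softmax output layer.

bilstm_init <- function(cfg, n_src, n_tgt, desc_dim) {
  d <- cfg$embedding_dim; H <- cfg$hidden_dim
  u_dim <- 2 * H + desc_dim   # final hidden states of both directions
  with_seed(derive_seed(cfg$seed, "bilstm-init"), list(
    E_src = glorot(n_src, d),
    E_tgt = glorot(n_tgt, d),
    Wf = glorot(d + H, 4 * H), bf = init_lstm_bias(H),
    Wb = glorot(d + H, 4 * H), bb = init_lstm_bias(H),
    Wbr_h = glorot(u_dim, H), bbr_h = numeric(H),
    Wbr_c = glorot(u_dim, H), bbr_c = numeric(H),
    Wd = glorot(d + 2 * H, 4 * H), bd = init_lstm_bias(H),
    Wo = glorot(H, n_tgt), bo = numeric(n_tgt)
  ))
}

## forget-gate bias of 1 (standard trick for trainability)
init_lstm_bias <- function(H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  b
}

embed_seq <- function(E, ids) {
  lapply(seq_len(ncol(ids)), function(t) E[ids[, t], , drop = FALSE])
}

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

## Teacher-forced token-level cross-entropy (mean over real target tokens)
## and, optionally, exact gradients for every parameter.
bilstm_loss <- function(params, batch, cfg, compute_grads = TRUE,
                        training = FALSE) {
  H <- cfg$hidden_dim
  B <- nrow(batch$src_ids)
  p_drop <- if (training) cfg$dropout else 0

  X <- embed_seq(params$E_src, batch$src_ids)
  fwd <- lstm_forward(X, batch$src_mask, params$Wf, params$bf, H)
  bwd <- lstm_forward(X, batch$src_mask, params$Wb, params$bb, H, reverse = TRUE)
  u <- cbind(fwd$h, bwd$h)
  if (!is.null(batch$desc)) u <- cbind(u, batch$desc)
  mu <- dropout_mask(nrow(u), ncol(u), p_drop)
  if (!is.null(mu)) u <- u * mu
  h0 <- tanh(u %*% params$Wbr_h + rep(params$bbr_h, each = B))
  c0 <- tanh(u %*% params$Wbr_c + rep(params$bbr_c, each = B))

  Y <- lapply(embed_seq(params$E_tgt, batch$tgt_in), cbind, h0)
  dec <- lstm_forward(Y, batch$tgt_mask, params$Wd, params$bd, H,
                      h0 = h0, c0 = c0)
  Tt <- ncol(batch$tgt_in)
  n_tok <- sum(batch$tgt_mask)
  loss <- 0
  dh_steps <- if (compute_grads) vector("list", Tt)
  dWo <- if (compute_grads) matrix(0, H, ncol(params$Wo))
  dbo <- if (compute_grads) numeric(ncol(params$Wo))
  for (t in seq_len(Tt)) {
    h_t <- dec$hs[[t]]
    m_t <- dropout_mask(B, H, p_drop)
    if (!is.null(m_t)) h_t <- h_t * m_t
    logits <- h_t %*% params$Wo + rep(params$bo, each = B)
    lp <- log_softmax_rows(logits)
    tgt <- batch$tgt_out[, t]
    msk <- batch$tgt_mask[, t]
    loss <- loss - sum(lp[cbind(seq_len(B), tgt)] * msk)
    if (compute_grads) {
      dlogits <- exp(lp)
      dlogits[cbind(seq_len(B), tgt)] <- dlogits[cbind(seq_len(B), tgt)] - 1
      dlogits <- dlogits * (msk / n_tok)
      dWo <- dWo + crossprod(h_t, dlogits)
      dbo <- dbo + colSums(dlogits)
      dh <- dlogits %*% t(params$Wo)
      if (!is.null(m_t)) dh <- dh * m_t
      dh_steps[[t]] <- dh
    }
  }
  loss <- loss / n_tok
  if (!compute_grads) return(list(loss = loss))

  dec_bk <- lstm_backward(dec, dh_steps = dh_steps)
  ## gradient into h0: initial-state path plus the per-step context feed
  d_emb <- ncol(params$E_tgt)
  for (t in seq_len(Tt)) {
    dec_bk$dh0 <- dec_bk$dh0 + dec_bk$dX[[t]][, (d_emb + 1):(d_emb + H), drop = FALSE]
    dec_bk$dX[[t]] <- dec_bk$dX[[t]][, 1:d_emb, drop = FALSE]
  }
  dtanh_h <- dec_bk$dh0 * (1 - h0^2)
  dtanh_c <- dec_bk$dc0 * (1 - c0^2)
  du <- dtanh_h %*% t(params$Wbr_h) + dtanh_c %*% t(params$Wbr_c)
  if (!is.null(mu)) du <- du * mu
  u_for_grad <- u
  grads <- list(
    Wd = dec_bk$dW, bd = dec_bk$db,
    Wbr_h = crossprod(u_for_grad, dtanh_h), bbr_h = colSums(dtanh_h),
    Wbr_c = crossprod(u_for_grad, dtanh_c), bbr_c = colSums(dtanh_c),
    Wo = dWo, bo = dbo
  )
  fwd_bk <- lstm_backward(fwd, dh_last = du[, 1:H, drop = FALSE])
  bwd_bk <- lstm_backward(bwd, dh_last = du[, (H + 1):(2 * H), drop = FALSE])
  grads$Wf <- fwd_bk$dW; grads$bf <- fwd_bk$db
  grads$Wb <- bwd_bk$dW; grads$bb <- bwd_bk$db

  src_ids_vec <- as.vector(batch$src_ids)
  dsrc <- do.call(rbind, lapply(seq_along(fwd_bk$dX), function(t) {
    fwd_bk$dX[[t]] + bwd_bk$dX[[t]]
  }))
  grads$E_src <- embedding_grad(nrow(params$E_src), src_ids_vec, dsrc)
  grads$E_tgt <- embedding_grad(nrow(params$E_tgt),
                                as.vector(batch$tgt_in),
                                do.call(rbind, dec_bk$dX))
  list(loss = loss, grads = grads)
}

## ---- incremental decoding interface ------------------------------------

#' @export
decode_init.bilstm_seq2seq <- function(model, src_ids, descriptor = NULL, ...) {
  p <- model$params
  H <- model$config$hidden_dim
  ids <- matrix(src_ids, nrow = 1)
  mask <- matrix(1, 1, length(src_ids))
  X <- embed_seq(p$E_src, ids)
  fwd <- lstm_forward(X, mask, p$Wf, p$bf, H)
  bwd <- lstm_forward(X, mask, p$Wb, p$bb, H, reverse = TRUE)
  u <- cbind(fwd$h, bwd$h)
  u <- fuse_descriptor(model, u, descriptor)
  h0 <- tanh(u %*% p$Wbr_h + rep(p$bbr_h, each = 1))
  c0 <- tanh(u %*% p$Wbr_c + rep(p$bbr_c, each = 1))
  list(h = h0, c = c0, ctx = h0)
}

#' @export
decode_step.bilstm_seq2seq <- function(model, state, token, ...) {
  p <- model$params
  H <- model$config$hidden_dim
  x <- cbind(p$E_tgt[token, , drop = FALSE], state$ctx)
  st <- lstm_step(x, state$h, state$c, p$Wd, p$bd, H)
  logits <- st$h %*% p$Wo + p$bo
  list(logp = as.numeric(log_softmax_rows(logits)),
       state = list(h = st$h, c = st$c, ctx = state$ctx))
}

## Concatenate the descriptor vector onto the combined encoder state (the
## multimodal fusion input); identity pass-through for unimodal models.
fuse_descriptor <- function(model, u, descriptor) {
  if (!isTRUE(model$config$multimodal)) return(u)
  if (is.null(descriptor)) {
    stop("multimodal model requires a descriptor vector", call. = FALSE)
  }
  if (length(descriptor) != model$desc_dim) {
    stop(sprintf("descriptor length %d does not match fit-time length %d",
                 length(descriptor), model$desc_dim), call. = FALSE)
  }
  cbind(u, matrix(descriptor, nrow = nrow(u), ncol = length(descriptor),
                  byrow = TRUE))
}
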