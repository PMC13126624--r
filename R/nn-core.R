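## Minimal neural-network primitives: parameter initialisation, Adam, and
## a batched LSTM cell with exact hand-derived gradients.  Written here
## because no neural framework is part of the package's dependency set and
## the models involved are small enough for plain matrix code.

sigmoid <- function(x) 1 / (1 + exp(-x))

## rows of x -> log softmax (numerically stable)
log_softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  z <- x - m
  z - log(rowSums(exp(z)))
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

zeros_like <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

## Decoupled weight decay (applied to matrices only, not bias vectors).
adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      step <- step + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = st)
}

clip_global_norm <- function(grads, max_norm) {
  if (is.null(max_norm) || max_norm <= 0) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (total > max_norm) grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

## ---- batched LSTM over time --------------------------------------------
##
## X: list over time of B x d input matrices; mask: B x T (1 = real token).
## W: (d + H) x 4H with gate column blocks [input, forget, cell, output];
## b: length-4H bias.  Padded steps pass the previous state through, so the
## final state is the state at each sequence's last real token.

lstm_forward <- function(X, mask, W, b, H, reverse = FALSE, h0 = NULL, c0 = NULL) {
  Tlen <- length(X)
  B <- nrow(X[[1]])
  h <- h0 %||% matrix(0, B, H)
  cc <- c0 %||% matrix(0, B, H)
  order_t <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  cache <- vector("list", Tlen)
  hs <- vector("list", Tlen)
  for (t in order_t) {
    Z <- cbind(X[[t]], h)
    G <- Z %*% W + rep(b, each = B)
    i <- sigmoid(G[, 1:H, drop = FALSE])
    f <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
    c_raw <- f * cc + i * g
    h_raw <- o * tanh(c_raw)
    m <- mask[, t]
    cache[[t]] <- list(Z = Z, i = i, f = f, g = g, o = o,
                       c_prev = cc, c_raw = c_raw, m = m)
    h <- m * h_raw + (1 - m) * h
    cc <- m * c_raw + (1 - m) * cc
    hs[[t]] <- h
  }
  list(h = h, c = cc, hs = hs, cache = cache, order_t = order_t,
       W = W, H = H, B = B, d = ncol(X[[1]]))
}

## dh_steps: optional list over time of gradients w.r.t. the emitted h_t;
## dh_last / dc_last: gradients w.r.t. the final state.  Returns parameter
## grads, per-time input grads dX, and grads w.r.t. the initial state.
lstm_backward <- function(fw, dh_steps = NULL, dh_last = NULL, dc_last = NULL) {
  H <- fw$H; B <- fw$B; W <- fw$W
  dh <- dh_last %||% matrix(0, B, H)
  dc <- dc_last %||% matrix(0, B, H)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dX <- vector("list", length(fw$cache))
  for (t in rev(fw$order_t)) {
    if (!is.null(dh_steps) && !is.null(dh_steps[[t]])) dh <- dh + dh_steps[[t]]
    cc <- fw$cache[[t]]
    m <- cc$m
    dh_raw <- m * dh
    dc_m <- m * dc
    dh_pass <- (1 - m) * dh
    dc_pass <- (1 - m) * dc
    tc <- tanh(cc$c_raw)
    do_ <- dh_raw * tc
    dc_acc <- dc_m + dh_raw * cc$o * (1 - tc^2)
    df <- dc_acc * cc$c_prev
    di <- dc_acc * cc$g
    dg <- dc_acc * cc$i
    dc_prev <- dc_acc * cc$f + dc_pass
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$Z, dG)
    db <- db + colSums(dG)
    dZ <- dG %*% t(W)
    dX[[t]] <- dZ[, 1:fw$d, drop = FALSE]
    dh <- dZ[, (fw$d + 1):(fw$d + H), drop = FALSE] + dh_pass
    dc <- dc_prev
  }
  list(dW = dW, db = db, dX = dX, dh0 = dh, dc0 = dc)
}

## one LSTM cell step (inference)
lstm_step <- function(x, h, cc, W, b, H) {
  Z <- cbind(x, h)
  G <- Z %*% W + rep(b, each = nrow(Z))
  i <- sigmoid(G[, 1:H, drop = FALSE])
  f <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
  c_new <- f * cc + i * g
  list(h = o * tanh(c_new), c = c_new)
}

## Accumulate embedding gradients: ids (integer vector) indexing rows of the
## embedding, dx the matching stack of row gradients.
embedding_grad <- function(n_rows, ids, dx) {
  out <- matrix(0, n_rows, ncol(dx))
  agg <- rowsum(dx, group = ids)
  out[as.integer(rownames(agg)), ] <- agg
  out
}
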