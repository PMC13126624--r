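## Exact-gradient verification by central finite differences, at tiny
## dimensions.  This is the load-bearing correctness check for the
## hand-written backpropagation of both architectures.

fd_max_rel_err <- function(loss_fn, params, grads, n_probe = 2, eps = 1e-5,
                           seed = 1) {
  set.seed(seed)
  worst <- 0
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(n_probe, length(params[[nm]])))
    for (j in idx) {
      p1 <- params; p1[[nm]][j] <- p1[[nm]][j] + eps
      p2 <- params; p2[[nm]][j] <- p2[[nm]][j] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      ana <- grads[[nm]][j]
      denom <- max(1e-6, abs(num) + abs(ana))
      worst <- max(worst, abs(num - ana) / denom)
    }
  }
  worst
}

make_toy_examples <- function(n_src, n_tgt, D, B = 3, seed = 42) {
  set.seed(seed)
  lapply(seq_len(B), function(i) {
    tgt <- c(2L, sample(5:n_tgt, 3, replace = TRUE))
    list(src = c(2L, sample(5:n_src, sample(2:5, 1), TRUE), 3L),
         tgt_in = tgt, tgt_out = c(tgt[-1], 3L),
         desc = rnorm(D))
  })
}

test_that("BiLSTM gradients match finite differences (uni- and multimodal)", {
  cfg <- seq2seq_config("bilstm", embedding_dim = 5, hidden_dim = 6, seed = 3)
  ex <- make_toy_examples(9, 8, D = 3)
  for (D in c(0, 3)) {
    params <- atcgen:::bilstm_init(cfg, 9, 8, D)
    batch <- atcgen:::pad_batch(ex)
    if (D == 0) batch$desc <- NULL
    res <- atcgen:::bilstm_loss(params, batch, cfg, compute_grads = TRUE)
    err <- fd_max_rel_err(
      function(p) atcgen:::bilstm_loss(p, batch, cfg, compute_grads = FALSE)$loss,
      params, res$grads
    )
    expect_lt(err, 1e-4)
  }
})

test_that("Transformer gradients match finite differences (uni- and multimodal)", {
  cfg <- seq2seq_config("transformer", embedding_dim = 8, heads = 2,
                        ffn_dim = 10, layers = 2, seed = 5)
  ex <- make_toy_examples(9, 8, D = 3, seed = 7)
  for (D in c(0, 3)) {
    params <- atcgen:::transformer_init(cfg, 9, 8, D, 12, 8)
    seqs <- if (D == 0) lapply(ex, function(e) { e$desc <- NULL; e }) else ex
    res <- atcgen:::transformer_loss(params, seqs, cfg, compute_grads = TRUE)
    err <- fd_max_rel_err(
      function(p) atcgen:::transformer_loss(p, seqs, cfg, compute_grads = FALSE)$loss,
      params, res$grads
    )
    expect_lt(err, 1e-4)
  }
})

test_that("per-step decoder distributions sum to one for both architectures", {
  ds <- generate_dataset(grammar_spec(seed = 21), 30)
  for (arch in c("bilstm", "transformer")) {
    cfg <- seq2seq_config(arch, embedding_dim = 8, hidden_dim = 10,
                          ffn_dim = 12, heads = 2, epochs = 2, seed = 2)
    m <- train_seq2seq(ds$records, NULL, cfg)
    state <- decode_init(m, tokenize_string(ds$records$smiles[1], m$src_vocab))
    tok <- m$tgt_vocab$start
    for (i in 1:4) {
      st <- decode_step(m, state, tok)
      expect_equal(sum(exp(st$logp)), 1, tolerance = 1e-5)
      tok <- which.max(st$logp)
      state <- st$state
    }
  }
})

test_that("a single example is memorized to near-zero loss", {
  rec <- compound_records("one", "CCNOCCSP", list("A02BC"))
  cfg <- seq2seq_config("bilstm", embedding_dim = 12, hidden_dim = 16,
                        learning_rate = 1e-2, batch_size = 1, epochs = 150,
                        patience = 150, seed = 4)
  m <- train_seq2seq(rec, NULL, cfg)
  expect_lt(min(m$history$train_loss), 0.1)
  out <- beam_generate(m, "CCNOCCSP", beam_width = 2, k = 1)
  expect_identical(out$code, "A02BC")
})

test_that("training is reproducible: same config and seed give identical loss traces", {
  ds <- generate_dataset(grammar_spec(seed = 33), 40)
  cfg <- seq2seq_config("bilstm", embedding_dim = 8, hidden_dim = 12,
                        epochs = 4, dropout = 0.2, seed = 6)
  m1 <- train_seq2seq(ds$records[1:30, ], ds$records[31:40, ], cfg)
  m2 <- train_seq2seq(ds$records[1:30, ], ds$records[31:40, ], cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("multimodal models require and respond to descriptors", {
  ds <- generate_dataset(grammar_spec(seed = 51), 40)
  dm <- fit_apply_standardization(ds$descriptors)
  dstd <- descriptor_values(dm)
  cfg <- seq2seq_config("bilstm", embedding_dim = 8, hidden_dim = 10,
                        epochs = 2, seed = 2, multimodal = TRUE)
  m <- train_seq2seq(ds$records, NULL, cfg, descriptors = dstd)
  ids <- tokenize_string(ds$records$smiles[1], m$src_vocab)

  ## same SMILES, different descriptors -> different decoder initial states
  s1 <- decode_init(m, ids, dstd[1, ])
  s2 <- decode_init(m, ids, dstd[2, ])
  expect_false(isTRUE(all.equal(s1$h, s2$h)))

  ## zero vector is a valid descriptor and yields finite state
  s0 <- decode_init(m, ids, rep(0, ncol(dstd)))
  expect_true(all(is.finite(s0$h)))

  ## fit-time dimensionality is enforced at inference
  expect_error(decode_init(m, ids, rep(0, 3)), "does not match fit-time")
  expect_error(decode_init(m, ids, NULL), "requires a descriptor")

  ## unimodal models pass encoder state through unchanged
  mu <- train_seq2seq(ds$records, NULL,
                      seq2seq_config("bilstm", embedding_dim = 8,
                                     hidden_dim = 10, epochs = 1, seed = 2))
  u <- matrix(rnorm(20), 1, 20)
  expect_identical(atcgen:::fuse_descriptor(mu, u, NULL), u)
})

test_that("training rejects inconsistent inputs", {
  ds <- generate_dataset(grammar_spec(seed = 3), 10)
  cfg <- seq2seq_config("bilstm", epochs = 1, multimodal = TRUE)
  expect_error(train_seq2seq(ds$records[0, ], NULL, seq2seq_config(epochs = 1)),
               "empty training set")
  expect_error(train_seq2seq(ds$records, NULL, cfg, descriptors = NULL),
               "requires `descriptors`")
  dm <- descriptor_values(fit_apply_standardization(ds$descriptors))
  expect_error(train_seq2seq(ds$records, NULL, cfg,
                             descriptors = dm[1:3, ]),
               "descriptor rows missing")
  expect_error(train_seq2seq(ds$records, NULL, seq2seq_config(epochs = 1),
                             descriptors = dm),
               "multimodal")
})

test_that("transformer multimodal decoding distinguishes descriptors per position", {
  ds <- generate_dataset(grammar_spec(seed = 52), 30)
  dstd <- descriptor_values(fit_apply_standardization(ds$descriptors))
  cfg <- seq2seq_config("transformer", embedding_dim = 8, heads = 2,
                        ffn_dim = 12, epochs = 2, seed = 2, multimodal = TRUE)
  m <- train_seq2seq(ds$records, NULL, cfg, descriptors = dstd)
  ids <- tokenize_string(ds$records$smiles[1], m$src_vocab)
  s1 <- decode_init(m, ids, dstd[1, ])
  s2 <- decode_init(m, ids, dstd[2, ])
  expect_false(isTRUE(all.equal(s1$mem, s2$mem)))
  expect_identical(nrow(s1$mem), length(ids))
  expect_error(decode_init(m, ids, dstd[1, 1:4]), "does not match fit-time")
})
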