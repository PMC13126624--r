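#' Configuration for sequence-to-sequence generators
#'
#' @param architecture `"bilstm"` or `"transformer"`.
#' @param embedding_dim character embedding size (also the model dimension
#'   of the transformer).
#' @param hidden_dim LSTM hidden state size (BiLSTM architecture only).
#' @param ffn_dim transformer feed-forward inner dimension.
#' @param heads number of attention heads (must divide `embedding_dim`).
#' @param layers number of transformer encoder/decoder layers (the BiLSTM
#'   encoder-decoder is single-layer).
#' @param dropout dropout probability applied during training.
#' @param learning_rate,weight_decay Adam step size and decoupled weight
#'   decay.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience in epochs, on validation loss
#'   (training loss when no validation set is given).
#' @param clip_norm global gradient-norm clipping threshold.
#' @param seed integer seed making training fully reproducible.
#' @param multimodal if `TRUE` the model fuses a molecular descriptor
#'   vector with the encoded SMILES (see [train_seq2seq()]).
#' @return a list of class `seq2seq_config`.
#' @export
seq2seq_config <- function(architecture = c("bilstm", "transformer"),
                           embedding_dim = 24, hidden_dim = 48,
                           ffn_dim = 64, heads = 2, layers = 1,
                           dropout = 0, learning_rate = 3e-3,
                           weight_decay = 0, batch_size = 32,
                           epochs = 40, patience = 10, clip_norm = 5,
                           seed = 1L, multimodal = FALSE) {
  architecture <- match.arg(architecture)
  structure(
    list(architecture = architecture, embedding_dim = embedding_dim,
         hidden_dim = hidden_dim, ffn_dim = ffn_dim, heads = heads,
         layers = layers, dropout = dropout, learning_rate = learning_rate,
         weight_decay = weight_decay, batch_size = batch_size,
         epochs = epochs, patience = patience, clip_norm = clip_norm,
         seed = as.integer(seed), multimodal = isTRUE(multimodal)),
    class = "seq2seq_config"
  )
}

#' Train a SMILES-to-ATC sequence-to-sequence model
#'
#' Trains a character-level encoder-decoder (BiLSTM or Transformer,
#' according to `config$architecture`) to map SMILES strings to 5-character
#' ATC codes.  A compound annotated with several codes contributes one
#' (SMILES, code) training example per code.  The decoder is trained with
#' teacher forcing under a token-level cross-entropy loss (padding masked),
#' optimised by Adam with early stopping on the validation loss; the whole
#' run is reproducible given `config$seed`.
#'
#' When `config$multimodal` is `TRUE`, `descriptors` must be a numeric
#' matrix of standardized descriptor values with compound ids as rownames
#' (see [fit_apply_standardization()]); the descriptor dimensionality is
#' recorded on the model and enforced at inference time.
#'
#' @param train_records,val_records `compound_records` tibbles; every
#'   training compound must carry at least one code.  `val_records` may be
#'   `NULL`.
#' @param config a [seq2seq_config()].
#' @param descriptors standardized descriptor matrix (multimodal only).
#' @return an object of class `<architecture>_seq2seq` / `seq2seq_model`.
#' @export
train_seq2seq <- function(train_records, val_records = NULL,
                          config = seq2seq_config(), descriptors = NULL) {
  stopifnot(inherits(config, "seq2seq_config"))
  if (nrow(train_records) == 0L) stop("empty training set", call. = FALSE)
  if (any(vapply(train_records$atc_codes, length, 1L) == 0L)) {
    stop("every training compound needs at least one ATC code", call. = FALSE)
  }
  desc_mat <- NULL
  desc_dim <- 0L
  if (config$multimodal) {
    desc_mat <- as_desc_matrix(descriptors)
    miss <- setdiff(train_records$compound_id, rownames(desc_mat))
    if (length(miss)) {
      stop("descriptor rows missing for compound(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    desc_dim <- ncol(desc_mat)
  } else if (!is.null(descriptors)) {
    stop("`descriptors` supplied but `config$multimodal` is FALSE", call. = FALSE)
  }

  src_vocab <- build_vocab(train_records$smiles)
  tgt_vocab <- build_vocab(unlist(train_records$atc_codes))

  train_ex <- expand_examples(train_records, src_vocab, tgt_vocab, desc_mat)
  val_ex <- if (!is.null(val_records) && nrow(val_records) > 0) {
    expand_examples(val_records, src_vocab, tgt_vocab, desc_mat)
  }

  model <- structure(
    list(architecture = config$architecture, params = NULL, config = config,
         src_vocab = src_vocab, tgt_vocab = tgt_vocab, desc_dim = desc_dim,
         history = NULL),
    class = c(paste0(config$architecture, "_seq2seq"), "seq2seq_model")
  )
  n_src <- length(src_vocab$tokens)
  n_tgt <- length(tgt_vocab$tokens)
  max_src <- max(vapply(train_ex, function(e) length(e$src), 1L)) + 8L
  params <- if (config$architecture == "bilstm") {
    bilstm_init(config, n_src, n_tgt, desc_dim)
  } else {
    transformer_init(config, n_src, n_tgt, desc_dim, max_src, 16L)
  }

  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", config$epochs)
  wait <- 0L
  lr <- config$learning_rate
  with_seed(derive_seed(config$seed, "train"), {
    n_ex <- length(train_ex)
    src_len <- vapply(train_ex, function(e) length(e$src), 1L)
    for (epoch in seq_len(config$epochs)) {
      ## length-bucketed batches (shuffle, stable-sort by length, shuffle
      ## batch order) to keep padding waste low
      ord <- sample.int(n_ex)
      ord <- ord[order(src_len[ord])]
      starts <- sample(seq(1, n_ex, by = config$batch_size))
      ep_loss <- 0; ep_tok <- 0
      for (start in starts) {
        idx <- ord[start:min(start + config$batch_size - 1, n_ex)]
        res <- example_loss(config, params, train_ex[idx],
                            compute_grads = TRUE, training = TRUE)
        res$grads <- clip_global_norm(res$grads, config$clip_norm)
        up <- adam_update(params, res$grads, opt, lr = lr,
                          weight_decay = config$weight_decay)
        params <- up$params; opt <- up$state
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_tok <- ep_tok + length(idx)
      }
      train_loss <- ep_loss / ep_tok
      val_loss <- if (!is.null(val_ex)) {
        example_loss(config, params, val_ex, compute_grads = FALSE)$loss
      } else train_loss
      hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                      val_loss = val_loss)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        ## halve the step size when the validation loss plateaus
        if (wait %% max(2L, config$patience %/% 2L) == 0L) lr <- lr / 2
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$best_epoch <- best$epoch
  model$fingerprint <- model_fingerprint(best$params)
  model
}

as_desc_matrix <- function(descriptors) {
  if (is.null(descriptors)) {
    stop("multimodal training requires `descriptors`", call. = FALSE)
  }
  m <- if (inherits(descriptors, "descriptor_matrix")) {
    descriptor_values(descriptors)
  } else as.matrix(descriptors)
  if (is.null(rownames(m))) {
    stop("descriptor matrix must have compound ids as rownames", call. = FALSE)
  }
  m
}

model_fingerprint <- function(params) {
  signif(sum(vapply(params, function(p) sum(abs(p)), 0)), 10)
}

expand_examples <- function(records, src_vocab, tgt_vocab, desc_mat) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    src <- tokenize_string(records$smiles[i], src_vocab)
    desc <- if (!is.null(desc_mat)) {
      as.numeric(desc_mat[records$compound_id[i], ])
    }
    for (code in records$atc_codes[[i]]) {
      full <- tokenize_string(code, tgt_vocab)
      out[[length(out) + 1L]] <- list(
        src = src, tgt_in = full[-length(full)], tgt_out = full[-1],
        desc = desc, compound_id = records$compound_id[i]
      )
    }
  }
  out
}

## Dispatch the architecture-specific loss over a list of examples.
example_loss <- function(config, params, examples, compute_grads, training = FALSE) {
  if (config$architecture == "transformer") {
    transformer_loss(params, examples, config, compute_grads, training)
  } else {
    batch <- pad_batch(examples, pad = 1L)
    bilstm_loss(params, batch, config, compute_grads, training)
  }
}

pad_batch <- function(examples, pad = 1L) {
  B <- length(examples)
  Ts <- max(vapply(examples, function(e) length(e$src), 1L))
  Tt <- max(vapply(examples, function(e) length(e$tgt_in), 1L))
  src_ids <- matrix(pad, B, Ts); src_mask <- matrix(0, B, Ts)
  tgt_in <- matrix(pad, B, Tt); tgt_out <- matrix(pad, B, Tt)
  tgt_mask <- matrix(0, B, Tt)
  for (b in seq_len(B)) {
    e <- examples[[b]]
    src_ids[b, seq_along(e$src)] <- e$src
    src_mask[b, seq_along(e$src)] <- 1
    tgt_in[b, seq_along(e$tgt_in)] <- e$tgt_in
    tgt_out[b, seq_along(e$tgt_out)] <- e$tgt_out
    tgt_mask[b, seq_along(e$tgt_out)] <- 1
  }
  desc <- if (!is.null(examples[[1]]$desc)) {
    do.call(rbind, lapply(examples, `[[`, "desc"))
  }
  list(src_ids = src_ids, src_mask = src_mask, tgt_in = tgt_in,
       tgt_out = tgt_out, tgt_mask = tgt_mask, desc = desc)
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat(sprintf("<%s seq2seq model>%s  src vocab %d, tgt vocab %d tokens\n",
              x$architecture,
              if (isTRUE(x$config$multimodal)) sprintf(" multimodal (%d descriptors)", x$desc_dim) else "",
              length(x$src_vocab$tokens), length(x$tgt_vocab$tokens)))
  if (!is.null(x$best_epoch)) {
    cat(sprintf("  best epoch %d, validation loss %.4f\n", x$best_epoch,
                min(x$history$val_loss)))
  }
  invisible(x)
}

## ---- decoding -----------------------------------------------------------

#' Incremental decoding interface
#'
#' Low-level generics used by [beam_generate()].  `decode_init()` encodes a
#' tokenized source sequence (fusing a descriptor vector for multimodal
#' models) and returns an opaque decoder state; `decode_step()` consumes
#' one target token and returns the log-probability vector over the target
#' vocabulary for the next token together with the advanced state.  Custom
#' decoders (e.g. [functional_decoder()]) can plug into beam search by
#' implementing these two methods.
#'
#' @param model a `seq2seq_model`.
#' @param src_ids integer token indices of the source sequence.
#' @param descriptor optional numeric descriptor vector.
#' @param ... passed on to methods.
#' @return `decode_init()`: a decoder state; `decode_step()`: a list with
#'   `logp` (numeric over target vocabulary) and `state`.
#' @export
decode_init <- function(model, src_ids, descriptor = NULL, ...) {
  UseMethod("decode_init")
}

#' @rdname decode_init
#' @param state a decoder state.
#' @param token the integer index of the token being consumed.
#' @export
decode_step <- function(model, state, token, ...) {
  UseMethod("decode_step")
}

#' Generate ranked candidate codes by beam search
#'
#' Breadth-limited best-first decoding: at each step every live hypothesis
#' is expanded over the target vocabulary and the `beam_width` best partial
#' sequences by total log-probability are retained (no length
#' normalisation -- ATC targets are near-constant length).  Hypotheses end
#' when they emit the end token or reach `max_len` characters.  The top `k`
#' distinct finished strings are returned.  Generation is unconstrained:
#' outputs need not match the ATC pattern, and downstream metrics score
#' invalid strings as incorrect.
#'
#' @param model a `seq2seq_model` (or any object implementing
#'   [decode_init()]/[decode_step()]).
#' @param smiles a single non-empty source string; characters unknown to
#'   the model's vocabulary map to the unknown token.
#' @param descriptor standardized descriptor vector (multimodal models).
#' @param beam_width beam size (>= `k`).
#' @param k number of distinct candidates to return.
#' @param max_len maximum generated length in characters (>= 6 so a full
#'   5-character code plus end token always fits).
#' @return tibble with columns `rank`, `code`, `log_prob`, sorted by
#'   non-increasing `log_prob`; `log_prob` is the total sequence
#'   log-probability (always <= 0).
#' @export
beam_generate <- function(model, smiles, descriptor = NULL, beam_width = 10,
                          k = 1, max_len = 8) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  if (k > beam_width) stop("`k` must be <= `beam_width`", call. = FALSE)
  if (max_len < 6) stop("`max_len` must be >= 6", call. = FALSE)
  v <- model$tgt_vocab
  src_ids <- tokenize_string(smiles, model$src_vocab)
  state0 <- decode_init(model, src_ids, descriptor)
  allowed <- setdiff(seq_along(v$tokens), c(v$pad, v$start, v$unk))
  live <- list(list(seq = integer(0), lp = 0, state = state0, last = v$start))
  finished_seq <- list(); finished_lp <- numeric(0)
  for (t in seq_len(max_len)) {
    cand_beam <- integer(0); cand_tok <- integer(0); cand_lp <- numeric(0)
    steps <- vector("list", length(live))
    for (b in seq_along(live)) {
      steps[[b]] <- decode_step(model, live[[b]]$state, live[[b]]$last)
      cand_beam <- c(cand_beam, rep(b, length(allowed)))
      cand_tok <- c(cand_tok, allowed)
      cand_lp <- c(cand_lp, live[[b]]$lp + steps[[b]]$logp[allowed])
    }
    finite <- which(is.finite(cand_lp))   # zero-probability continuations die
    keep <- finite[order(cand_lp[finite], decreasing = TRUE)]
    keep <- keep[seq_len(min(beam_width, length(keep)))]
    new_live <- list()
    for (j in keep) {
      b <- cand_beam[j]; tok <- cand_tok[j]
      if (tok == v$end) {
        finished_seq[[length(finished_seq) + 1L]] <- live[[b]]$seq
        finished_lp <- c(finished_lp, cand_lp[j])
      } else {
        new_live[[length(new_live) + 1L]] <- list(
          seq = c(live[[b]]$seq, tok), lp = cand_lp[j],
          state = steps[[b]]$state, last = tok
        )
      }
    }
    live <- new_live
    if (length(live) == 0L) break
  }
  for (b in seq_along(live)) {   # force-finish hypotheses at max_len
    finished_seq[[length(finished_seq) + 1L]] <- live[[b]]$seq
    finished_lp <- c(finished_lp, live[[b]]$lp)
  }
  strings <- vapply(finished_seq, function(s) {
    paste(v$tokens[s], collapse = "")
  }, "")
  ord <- order(finished_lp, decreasing = TRUE)
  strings <- strings[ord]; finished_lp <- finished_lp[ord]
  dup <- duplicated(strings)
  strings <- strings[!dup]; finished_lp <- finished_lp[!dup]
  n_out <- min(k, length(strings))
  tibble::tibble(rank = seq_len(n_out), code = strings[seq_len(n_out)],
                 log_prob = finished_lp[seq_len(n_out)])
}

#' Generate candidates for a whole compound table
#'
#' Runs [beam_generate()] for each record, looking descriptors up by
#' compound id when the model is multimodal.
#'
#' @inheritParams beam_generate
#' @param records a `compound_records` tibble.
#' @param descriptors standardized descriptor matrix with compound ids as
#'   rownames (multimodal models only).
#' @return tibble with columns `compound_id`, `rank`, `code`, `log_prob`.
#' @export
generate_codes <- function(model, records, descriptors = NULL, k = 1,
                           beam_width = max(10, k), max_len = 8) {
  desc_mat <- if (isTRUE(model$config$multimodal)) as_desc_matrix(descriptors)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    dv <- if (!is.null(desc_mat)) as.numeric(desc_mat[records$compound_id[i], ])
    cand <- beam_generate(model, records$smiles[i], dv,
                          beam_width = beam_width, k = k, max_len = max_len)
    cand$compound_id <- records$compound_id[i]
    out[[i]] <- cand[, c("compound_id", "rank", "code", "log_prob")]
  }
  do.call(rbind, out)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single-file archive embedding the learned parameters,
#' both vocabularies, the configuration and (for multimodal models) the
#' descriptor dimensionality, so generation needs nothing but the file.
#'
#' @param model a `seq2seq_model` or `atc_meta` object.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seq2seq_model") || inherits(model, "atc_meta"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "seq2seq_model") && !inherits(obj, "atc_meta")) {
    stop("file is not an atcgen checkpoint", call. = FALSE)
  }
  obj
}

#' A decoder defined by an arbitrary next-character distribution
#'
#' Wraps a function `step_fn(generated_string)` returning a named
#' log-probability vector over the possible next characters plus the
#' element `"<end>"`, as a `seq2seq_model` that [beam_generate()] can
#' decode.  Used to test beam search against exhaustive enumeration with
#' hand-set probabilities.
#'
#' @param step_fn function of the string generated so far.
#' @param target_chars character vector of the emittable characters.
#' @return an object of class `functional_seq2seq` / `seq2seq_model`.
#' @export
functional_decoder <- function(step_fn, target_chars) {
  v <- build_vocab(paste(target_chars, collapse = ""))
  structure(
    list(architecture = "functional", step_fn = step_fn,
         src_vocab = v, tgt_vocab = v,
         config = list(multimodal = FALSE), desc_dim = 0L),
    class = c("functional_seq2seq", "seq2seq_model")
  )
}

#' @export
decode_init.functional_seq2seq <- function(model, src_ids, descriptor = NULL, ...) {
  list(gen = "")
}

#' @export
decode_step.functional_seq2seq <- function(model, state, token, ...) {
  v <- model$tgt_vocab
  gen <- if (token > 4L) paste0(state$gen, v$tokens[token]) else state$gen
  named <- model$step_fn(gen)
  logp <- rep(-Inf, length(v$tokens))
  for (nm in names(named)) {
    idx <- if (nm == "<end>") v$end else unname(v$index[nm])
    if (!is.na(idx)) logp[idx] <- named[[nm]]
  }
  list(logp = logp, state = list(gen = gen))
}
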