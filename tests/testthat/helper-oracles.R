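## Independent brute-force oracles and shared fixtures for the test suite.
## These re-derive expected values straight from the metric definitions and
## from exhaustive enumeration; they deliberately share no code with the
## package implementation they check.

## ---- brute-force level-wise metrics -------------------------------------
## Direct transcription of the level-wise precision/recall definitions:
## Yhat^1 / Y^1 are the full predicted / actual sets; for n > 1 the sets are
## rebuilt from scratch as "codes correct up to level n-1"; C^n is the set
## of compounds with >= 1 level-n-correct prediction.

bf_prefix <- function(code, n) substr(code, 1, c(1, 3, 4, 5)[n])

bf_is_valid <- function(code) grepl("^[A-Z][0-9]{2}[A-Z][A-Z]$", code)

bf_match_at <- function(yhat, y, n) {
  bf_is_valid(yhat) && bf_prefix(yhat, n) == bf_prefix(y, n)
}

bf_level_metrics <- function(predicted, actual) {
  nc <- length(predicted)
  ## per-compound survivor sets, rebuilt from the definitions
  sets <- lapply(seq_len(nc), function(i) {
    yh <- list(unique(predicted[[i]]))
    ya <- list(unique(actual[[i]]))
    for (n in 2:4) {
      prev_yh <- yh[[n - 1]]; prev_ya <- ya[[n - 1]]
      yh[[n]] <- prev_yh[vapply(prev_yh, function(p) {
        any(vapply(prev_ya, function(a) bf_match_at(p, a, n - 1), TRUE))
      }, TRUE)]
      ya[[n]] <- prev_ya[vapply(prev_ya, function(a) {
        any(vapply(prev_yh, function(p) bf_match_at(p, a, n - 1), TRUE))
      }, TRUE)]
    }
    list(yh = yh, ya = ya)
  })
  correct_at <- function(i, n) {
    yh <- sets[[i]]$yh[[n]]; ya <- sets[[i]]$ya[[n]]
    sum(vapply(yh, function(p) any(vapply(ya, function(a) bf_match_at(p, a, n), TRUE)), TRUE))
  }
  in_C <- function(i, n) {
    if (n == 0) return(TRUE)
    correct_at(i, n) >= 1
  }
  out <- data.frame(level = 1:4, l_precision = NA_real_, l_recall = NA_real_,
                    evaluated_count = 0L)
  for (n in 1:4) {
    elig <- which(vapply(seq_len(nc), in_C, TRUE, n = n - 1))
    out$evaluated_count[n] <- length(elig)
    if (length(elig) == 0) next
    prec <- vapply(elig, function(i) {
      yh <- sets[[i]]$yh[[n]]
      if (length(yh) == 0) return(0)
      correct_at(i, n) / length(yh)
    }, 0)
    rec <- vapply(elig, function(i) {
      ya <- sets[[i]]$ya[[n]]
      hit <- sum(vapply(ya, function(a) {
        any(vapply(sets[[i]]$yh[[n]], function(p) bf_match_at(p, a, n), TRUE))
      }, TRUE))
      hit / length(ya)
    }, 0)
    out$l_precision[n] <- mean(prec)
    out$l_recall[n] <- mean(rec)
  }
  out
}

bf_exact_prf <- function(predicted, actual) {
  p <- vapply(seq_along(predicted), function(i) {
    ph <- unique(predicted[[i]])
    if (length(ph) == 0) return(0)
    sum(ph %in% actual[[i]]) / length(ph)
  }, 0)
  r <- vapply(seq_along(predicted), function(i) {
    ya <- unique(actual[[i]])
    sum(ya %in% predicted[[i]]) / length(ya)
  }, 0)
  f <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  list(precision = mean(p), recall = mean(r), f1 = mean(f))
}

## random evaluation instances over a restricted alphabet (<= 5 codes per
## side, occasionally invalid predicted strings)
random_instances <- function(n_compounds, seed) {
  set.seed(seed)
  rand_code <- function(k) {
    paste0(sample(c("A", "B", "C"), k, TRUE),
           sprintf("%02d", sample(1:3, k, TRUE)),
           sample(c("A", "B"), k, TRUE), sample(c("A", "B", "C"), k, TRUE))
  }
  actual <- lapply(seq_len(n_compounds), function(i) unique(rand_code(sample(1:5, 1))))
  predicted <- lapply(seq_len(n_compounds), function(i) {
    k <- sample(0:5, 1)
    out <- if (k == 0) character(0) else unique(rand_code(k))
    if (length(out) && runif(1) < 0.2) out[1] <- "a02b"   # invalid string
    out
  })
  list(predicted = predicted, actual = actual)
}

## ---- exhaustive beam-search oracle --------------------------------------
## Enumerates every sequence the functional decoder can finish (end token or
## the length cap), with its total log-probability, ranked.
enumerate_sequences <- function(step_fn, chars, max_len) {
  res_str <- character(0); res_lp <- numeric(0)
  recurse <- function(gen, lp, depth) {
    probs <- step_fn(gen)
    for (nm in names(probs)) {
      if (!is.finite(probs[[nm]])) next
      if (nm == "<end>") {
        res_str[[length(res_str) + 1]] <<- gen
        res_lp[[length(res_lp) + 1]] <<- lp + probs[[nm]]
      } else if (depth < max_len) {
        recurse(paste0(gen, nm), lp + probs[[nm]], depth + 1)
      } else {
        ## hypotheses at the cap are force-finished without an end step
        res_str[[length(res_str) + 1]] <<- paste0(gen, nm)
        res_lp[[length(res_lp) + 1]] <<- lp + probs[[nm]]
      }
    }
  }
  recurse("", 0, 1)
  ord <- order(res_lp, decreasing = TRUE)
  res_str <- res_str[ord]; res_lp <- res_lp[ord]
  keep <- !duplicated(res_str)
  data.frame(code = res_str[keep], log_prob = res_lp[keep],
             stringsAsFactors = FALSE)
}

## ---- shared trained fixture model ---------------------------------------
## A small BiLSTM trained once per session on the default grammar, reused by
## decoding-related tests.
.fixture_cache <- new.env(parent = emptyenv())

tiny_trained_model <- function() {
  if (is.null(.fixture_cache$model)) {
    ds <- generate_dataset(grammar_spec(seed = 31), 120)
    .fixture_cache$records <- ds$records
    .fixture_cache$model <- train_seq2seq(
      ds$records[1:100, ], ds$records[101:120, ],
      seq2seq_config("bilstm", embedding_dim = 16, hidden_dim = 24,
                     learning_rate = 5e-3, batch_size = 16, epochs = 12,
                     patience = 12, seed = 9)
    )
  }
  list(model = .fixture_cache$model, records = .fixture_cache$records)
}

## greedy decoding via the incremental interface (reference for beam-1)
greedy_decode <- function(model, smiles, max_len = 8) {
  v <- model$tgt_vocab
  ids <- tokenize_string(smiles, model$src_vocab)
  state <- decode_init(model, ids)
  allowed <- setdiff(seq_along(v$tokens), c(v$pad, v$start, v$unk))
  tok <- v$start
  out <- character(0)
  lp <- 0
  for (i in seq_len(max_len)) {
    st <- decode_step(model, state, tok)
    pick <- allowed[which.max(st$logp[allowed])]
    lp <- lp + st$logp[pick]
    if (pick == v$end) break
    out <- c(out, v$tokens[pick])
    state <- st$state
    tok <- pick
  }
  list(code = paste(out, collapse = ""), log_prob = lp)
}
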