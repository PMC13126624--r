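#' F1-optimal number of candidates to accept
#'
#' Given a ranked candidate list and the compound's annotated code set,
#' finds the smallest k in 1..`k_max` maximising the per-compound F1 of
#' exact 4-level matches between the top-k candidates and the actual set.
#' When no candidate is correct every k scores F1 = 0 and the smallest-k
#' tie-break returns 1 (favouring precision).
#'
#' @param candidates character vector of generated code strings, ranked by
#'   decreasing log-probability.
#' @param actual non-empty character vector of annotated ATC codes.
#' @param k_max largest k considered (<= `length(candidates)`).
#' @return an integer k.
#' @export
optimal_k <- function(candidates, actual, k_max = length(candidates)) {
  if (length(candidates) == 0L) stop("`candidates` must be non-empty", call. = FALSE)
  if (length(actual) == 0L) stop("`actual` must be non-empty", call. = FALSE)
  k_max <- min(k_max, length(candidates))
  f1 <- vapply(seq_len(k_max), function(k) {
    inter <- length(intersect(candidates[seq_len(k)], actual))
    p <- inter / k
    r <- inter / length(unique(actual))
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, 0)
  which.max(f1)   # ties broken toward the smallest k
}

META_SENTINEL <- -1e9

#' Build the meta-model training set
#'
#' For each compound, generates `k_max` candidate codes with the base
#' model, records the vector of the 10 highest candidate log-probabilities
#' (sorted non-increasing, padded with the sentinel -1e9 when fewer than 10
#' candidates exist) and labels it with the F1-optimal k from
#' [optimal_k()].
#'
#' @param model a trained `seq2seq_model`.
#' @param records `compound_records` with annotated codes.
#' @param descriptors standardized descriptor matrix (multimodal models).
#' @param k_max number of candidates generated per compound (default 10).
#' @param beam_width beam size used for generation.
#' @return tibble with columns `compound_id`, `lp1` .. `lp10` and
#'   `optimal_k`.
#' @export
build_meta_training_set <- function(model, records, descriptors = NULL,
                                    k_max = 10, beam_width = max(10, k_max)) {
  preds <- generate_codes(model, records, descriptors, k = k_max,
                          beam_width = beam_width)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- preds[preds$compound_id == records$compound_id[i], , drop = FALSE]
    lp <- sort(p$log_prob, decreasing = TRUE)
    lp <- c(lp, rep(META_SENTINEL, max(0, 10 - length(lp))))[1:10]
    kk <- optimal_k(p$code[order(p$log_prob, decreasing = TRUE)],
                    records$atc_codes[[i]], k_max = min(k_max, nrow(p)))
    row <- as.list(stats::setNames(lp, paste0("lp", 1:10)))
    row$compound_id <- records$compound_id[i]
    row$optimal_k <- as.integer(kk)
    out[[i]] <- tibble::as_tibble(row[c("compound_id", paste0("lp", 1:10), "optimal_k")])
  }
  do.call(rbind, out)
}

#' Train the candidate-count meta-model
#'
#' A feed-forward network with one hidden layer (two fully connected
#' layers, softmax output) framed as a 10-way classification of the
#' optimal candidate count from the 10 highest candidate log-probabilities.
#' Sentinel entries (and any log-probability below `floor`) are clamped to
#' `floor` before entering the network, so absent candidates are encoded as
#' a finite, very unlikely value rather than -1e9.
#'
#' @param samples tibble from [build_meta_training_set()] (columns `lp1` ..
#'   `lp10`, `optimal_k`).
#' @param hidden hidden layer width (default 32).
#' @param floor clamp value for log-probabilities (default -20).
#' @param seed integer seed.
#' @param maxit optimisation iterations for the network.
#' @param base_fingerprint optional fingerprint of the base model the
#'   samples came from, stored for a provenance check.
#' @return an object of class `atc_meta`.
#' @export
train_meta <- function(samples, hidden = 32, floor = -20, seed = 1L,
                       maxit = 400, base_fingerprint = NULL) {
  x <- meta_features(samples, floor)
  y <- factor(samples$optimal_k, levels = 1:10)
  if (length(unique(samples$optimal_k)) < 2L) {
    return(structure(list(constant = unique(samples$optimal_k)[1],
                          floor = floor, net = NULL,
                          base_fingerprint = base_fingerprint),
                     class = "atc_meta"))
  }
  net <- with_seed(derive_seed(seed, "meta"), {
    nnet::nnet(x, nnet::class.ind(y), size = hidden, softmax = TRUE,
               maxit = maxit, decay = 1e-4, trace = FALSE, MaxNWts = 5000)
  })
  structure(list(constant = NULL, floor = floor, net = net,
                 base_fingerprint = base_fingerprint),
            class = "atc_meta")
}

meta_features <- function(samples, floor) {
  x <- as.matrix(samples[, paste0("lp", 1:10)])
  pmax(x, floor)
}

#' @rdname train_meta
#' @param meta an `atc_meta` model.
#' @param top_logprobs numeric vector of length 10 (or matrix with 10
#'   columns) of candidate log-probabilities, sorted non-increasing and
#'   sentinel-padded.
#' @return `predict_k()` returns integer(s) in 1..10.
#' @export
predict_k <- function(meta, top_logprobs) {
  stopifnot(inherits(meta, "atc_meta"))
  if (is.null(dim(top_logprobs))) top_logprobs <- matrix(top_logprobs, nrow = 1)
  if (ncol(top_logprobs) != 10L) {
    stop("`top_logprobs` must have exactly 10 entries per compound", call. = FALSE)
  }
  if (!is.null(meta$constant)) {
    return(rep(as.integer(meta$constant), nrow(top_logprobs)))
  }
  x <- pmax(top_logprobs, meta$floor)
  colnames(x) <- paste0("lp", 1:10)
  pr <- stats::predict(meta$net, x)
  as.integer(apply(pr, 1, which.max))
}

#' Adaptive-count generation
#'
#' Generates `k_max` ranked candidates per compound, asks the meta-model
#' how many to accept, and returns the truncated prediction sets.
#'
#' @inheritParams build_meta_training_set
#' @param meta an `atc_meta` model trained against this base model.
#' @return list with `predicted` (list of character vectors, one per
#'   record) and `k` (integer vector of accepted counts).
#' @export
generate_adaptive <- function(model, meta, records, descriptors = NULL,
                              k_max = 10, beam_width = max(10, k_max)) {
  stopifnot(inherits(meta, "atc_meta"))
  if (!is.null(meta$base_fingerprint) && !is.null(model$fingerprint) &&
      !isTRUE(all.equal(meta$base_fingerprint, model$fingerprint))) {
    warning("meta-model was trained against a different base model")
  }
  preds <- generate_codes(model, records, descriptors, k = k_max,
                          beam_width = beam_width)
  predicted <- vector("list", nrow(records))
  ks <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- preds[preds$compound_id == records$compound_id[i], , drop = FALSE]
    p <- p[order(p$log_prob, decreasing = TRUE), , drop = FALSE]
    lp <- c(p$log_prob, rep(META_SENTINEL, max(0, 10 - nrow(p))))[1:10]
    ks[i] <- min(predict_k(meta, lp), nrow(p))
    predicted[[i]] <- p$code[seq_len(ks[i])]
  }
  list(predicted = predicted, k = ks)
}
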