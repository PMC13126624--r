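#' Synthetic SMILES-like grammar specification
#'
#' The synthetic generator emulates the statistical shape of a curated
#' compound/ATC dataset without any chemistry: "SMILES" are random strings
#' over a small alphabet, and each annotated code is a deterministic
#' function of a 4-symbol window of the string, so that a sequence model can
#' in principle recover every code exactly.  Concretely, the j-th code of a
#' compound is read off source positions `4(j-1)+1 .. 4j`: the symbol at the
#' first position selects the level-1 letter through a fixed random
#' permutation, the second selects the two-digit level-2 unit, and the third
#' and fourth the level-3 and level-4 letters.  Compounds carry 1-4 codes
#' with a configurable count distribution (most real compounds have one
#' code, a minority several).
#'
#' Descriptor vectors are noisy encodings of the first eight code-bearing
#' positions plus pure-noise nuisance features.  With
#' `descriptor_only_signal = TRUE` the level-4 letter of every code is
#' instead driven by a latent variable visible only through the last
#' descriptor feature -- a string-only model then cannot beat chance at
#' level 4, while a multimodal model can, which is exactly the situation the
#' descriptor-fusion architecture is meant to exploit.
#'
#' @param alphabet source alphabet (default 12 SMILES-ish symbols).
#' @param length_range integer range of source string lengths.
#' @param label_count_probs probabilities of a compound carrying 1..4 codes.
#' @param descriptor_dim number of descriptor features (>= 9).
#' @param descriptor_sigma Gaussian noise s.d. added to signal features.
#' @param descriptor_only_signal see above.
#' @param noise_rate per-code probability of corrupting one level segment.
#' @param seed integer seed fixing the grammar's permutation rules.
#' @return an object of class `grammar_spec`.
#' @export
grammar_spec <- function(alphabet = c("C", "N", "O", "S", "P", "F", "B", "I",
                                      "c", "n", "o", "s"),
                         length_range = c(8L, 30L),
                         label_count_probs = c(0.70, 0.20, 0.06, 0.04),
                         descriptor_dim = 16L,
                         descriptor_sigma = 0.1,
                         descriptor_only_signal = FALSE,
                         noise_rate = 0,
                         seed = 1L) {
  if (length(alphabet) < 2L || anyDuplicated(alphabet)) {
    stop("`alphabet` must contain at least 2 distinct symbols", call. = FALSE)
  }
  if (abs(sum(label_count_probs) - 1) > 1e-8 || length(label_count_probs) != 4L) {
    stop("`label_count_probs` must be 4 probabilities summing to 1", call. = FALSE)
  }
  if (length_range[2] < 4L * max(which(label_count_probs > 0))) {
    stop("maximum source length cannot host the largest label count", call. = FALSE)
  }
  if (descriptor_dim < 9L) stop("`descriptor_dim` must be >= 9", call. = FALSE)
  k <- length(alphabet)
  pick <- function(pool) pool[((seq_len(k) - 1L) %% length(pool)) + 1L]
  rules <- with_seed(derive_seed(seed, "grammar-rules"), list(
    level1 = stats::setNames(sample(pick(c("A", "B", "C", "D", "G", "H",
                                           "J", "L", "M", "N", "P", "R"))), alphabet),
    level2 = stats::setNames(sample(pick(sprintf("%02d", 1:12))), alphabet),
    level3 = stats::setNames(sample(pick(LETTERS[1:12])), alphabet),
    level4 = stats::setNames(sample(pick(LETTERS[1:12])), alphabet)
  ))
  structure(
    list(alphabet = alphabet, length_range = as.integer(length_range),
         label_count_probs = label_count_probs,
         descriptor_dim = as.integer(descriptor_dim),
         descriptor_sigma = descriptor_sigma,
         descriptor_only_signal = isTRUE(descriptor_only_signal),
         noise_rate = noise_rate, seed = as.integer(seed), rules = rules),
    class = "grammar_spec"
  )
}

#' Read codes off a synthetic source string (generation oracle)
#'
#' Applies the grammar rules directly, returning the codes a noise-free
#' generator would have attached to `smiles`.  Under
#' `descriptor_only_signal` the level-4 letter depends on the latent
#' variable `z`, which must then be supplied.
#'
#' @param spec a `grammar_spec`.
#' @param smiles a synthetic source string.
#' @param n_codes how many codes to derive.
#' @param z latent descriptor signal (required when
#'   `spec$descriptor_only_signal`).
#' @return character vector of `n_codes` code strings (possibly with
#'   duplicates; the generator rejects strings whose codes collide).
#' @export
synthetic_oracle <- function(spec, smiles, n_codes = 1L, z = NULL) {
  stopifnot(inherits(spec, "grammar_spec"))
  syms <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (length(syms) < 4L * n_codes) stop("source string too short", call. = FALSE)
  vapply(seq_len(n_codes), function(j) {
    w <- syms[(4L * (j - 1L) + 1L):(4L * j)]
    l4 <- if (spec$descriptor_only_signal) {
      if (is.null(z)) stop("`z` required under descriptor_only_signal", call. = FALSE)
      if (z > 0) "A" else "B"
    } else spec$rules$level4[[w[4]]]
    paste0(spec$rules$level1[[w[1]]], spec$rules$level2[[w[2]]],
           spec$rules$level3[[w[3]]], l4)
  }, "")
}

#' Generate a synthetic compound dataset
#'
#' Draws `n` compounds from the grammar: a label count, a source string long
#' enough to host that many codes (re-drawn until the derived codes are
#' distinct), the codes themselves, a pseudo molecular weight, and a
#' descriptor vector.  Descriptor feature *f* (for *f* = 1..8) encodes the
#' alphabet index of source position *f* rescaled to `[-1, 1]` plus
#' `N(0, descriptor_sigma)` noise; the remaining features are `N(0, 1)`
#' nuisance, except that under `descriptor_only_signal` the last feature
#' carries the latent level-4 variable.  With `noise_rate > 0`, each code
#' independently has one random level segment replaced by a random legal
#' value.  The output is deterministic given `spec$seed` and `n`, and passes
#' [filter_dataset()] unchanged.
#'
#' @param spec a `grammar_spec`.
#' @param n number of compounds (>= 1).
#' @return list with `records` (a `compound_records` tibble) and
#'   `descriptors` (an unpruned `descriptor_matrix` with matching rownames).
#' @export
generate_dataset <- function(spec, n) {
  stopifnot(inherits(spec, "grammar_spec"), n >= 1)
  with_seed(derive_seed(spec$seed, paste0("dataset-", n)), {
    k <- length(spec$alphabet)
    ids <- sprintf("SYN%05d", seq_len(n))
    smiles <- character(n)
    codes <- vector("list", n)
    z <- stats::rnorm(n)
    desc <- matrix(NA_real_, n, spec$descriptor_dim,
                   dimnames = list(ids, paste0("D", seq_len(spec$descriptor_dim))))
    for (i in seq_len(n)) {
      m <- sample.int(4L, 1L, prob = spec$label_count_probs)
      lo <- max(spec$length_range[1], 4L * m)
      len <- sample(lo:spec$length_range[2], 1L)
      repeat {
        syms <- sample(spec$alphabet, len, replace = TRUE)
        cc <- synthetic_oracle(spec, paste(syms, collapse = ""), m,
                               z = if (spec$descriptor_only_signal) z[i])
        if (!anyDuplicated(cc)) break
      }
      if (spec$noise_rate > 0) {
        cc <- vapply(cc, function(code) {
          if (stats::runif(1) >= spec$noise_rate) return(code)
          seg <- sample.int(4L, 1L)
          repl <- switch(seg,
                         sample(LETTERS[1:20], 1L),
                         sprintf("%02d", sample.int(12L, 1L)),
                         sample(LETTERS[1:12], 1L),
                         sample(LETTERS[1:12], 1L))
          substr(code, level_prefix_length(seg) - nchar(repl) + 1L,
                 level_prefix_length(seg)) <- repl
          code
        }, "")
        cc <- unique(unname(cc))
      }
      smiles[i] <- paste(syms, collapse = "")
      codes[[i]] <- unname(cc)
      sig <- (match(syms[seq_len(min(8L, len))], spec$alphabet) - 1) / (k - 1) * 2 - 1
      row <- stats::rnorm(spec$descriptor_dim)
      row[seq_along(sig)] <- sig + stats::rnorm(length(sig), 0, spec$descriptor_sigma)
      if (spec$descriptor_only_signal) {
        row[spec$descriptor_dim] <- z[i] + stats::rnorm(1, 0, spec$descriptor_sigma)
      }
      desc[i, ] <- row
    }
    mw <- round(10.5 * nchar(smiles) + stats::rnorm(n, 0, 5), 1)
    records <- compound_records(ids, smiles, codes, source = "synthetic",
                                mol_weight = mw)
    list(records = records, descriptors = descriptor_matrix(desc))
  })
}
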