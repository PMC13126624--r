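#' Character vocabularies for sequence models
#'
#' Both SMILES strings and ATC codes are tokenized character by character;
#' two-letter element symbols such as `"Cl"` are deliberately split into two
#' tokens (`"C"`, `"l"`).  Four special tokens occupy fixed, reserved
#' indices: `<pad>` = 1, `<start>` = 2, `<end>` = 3, `<unk>` = 4.  Regular
#' characters are indexed from 5 upward in first-appearance order, so a
#' vocabulary built from the same corpus is always identical.
#'
#' @param strings non-empty character vector whose characters populate the
#'   vocabulary.
#' @return an object of class `token_vocab`: a list with `tokens` (all
#'   tokens, specials first), `index` (named integer map) and the four
#'   special indices `pad`, `start`, `end`, `unk`.
#' @examples
#' v <- build_vocab(c("A02BC", "B01AC"))
#' tokenize_string("A02BC", v)
#' @export
build_vocab <- function(strings) {
  if (length(strings) == 0L) stop("`strings` must be non-empty", call. = FALSE)
  chars <- unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE)
  uniq <- unique(chars)
  specials <- c("<pad>", "<start>", "<end>", "<unk>")
  tokens <- c(specials, uniq)
  index <- seq_along(tokens)
  names(index) <- tokens
  structure(
    list(tokens = tokens, index = index, pad = 1L, start = 2L, end = 3L,
         unk = 4L),
    class = "token_vocab"
  )
}

#' @rdname build_vocab
#' @param s a single string to tokenize.
#' @param vocab a `token_vocab`.
#' @param wrap if `TRUE` (default) the index sequence is wrapped in the
#'   start/end indices.
#' @return `tokenize_string()` returns an integer vector of token indices;
#'   characters absent from the vocabulary map to the unknown index.
#' @export
tokenize_string <- function(s, vocab, wrap = TRUE) {
  stopifnot(inherits(vocab, "token_vocab"), length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  ids <- unname(vocab$index[chars])
  ids[is.na(ids)] <- vocab$unk
  if (wrap) c(vocab$start, ids, vocab$end) else ids
}

#' @rdname build_vocab
#' @param ids integer vector of token indices.
#' @return `detokenize_ids()` returns the string formed by the non-special
#'   tokens of `ids`.
#' @export
detokenize_ids <- function(ids, vocab) {
  stopifnot(inherits(vocab, "token_vocab"))
  keep <- ids > 4L
  paste(vocab$tokens[ids[keep]], collapse = "")
}

#' @rdname build_vocab
#' @param path file path for the JSON persisted form.
#' @export
save_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "token_vocab"))
  jsonlite::write_json(list(tokens = vocab$tokens), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname build_vocab
#' @export
load_vocab <- function(path) {
  tokens <- unlist(jsonlite::read_json(path)$tokens)
  index <- seq_along(tokens)
  names(index) <- tokens
  structure(
    list(tokens = tokens, index = index, pad = 1L, start = 2L, end = 3L,
         unk = 4L),
    class = "token_vocab"
  )
}

#' @export
print.token_vocab <- function(x, ...) {
  cat(sprintf("<token_vocab> %d tokens (4 special + %d characters)\n",
              length(x$tokens), length(x$tokens) - 4L))
  invisible(x)
}
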