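#' Standardize a SMILES string
#'
#' Produces the canonical, neutralized form used for merging datasets:
#' \enumerate{
#'   \item syntactic validation (balanced parentheses/brackets, paired ring
#'     bond digits, legal characters);
#'   \item removal of monatomic counterions -- single-atom charged fragments
#'     such as `[Na+]` or `[Cl-]` -- whenever at least one multi-atom
#'     fragment remains;
#'   \item charge neutralization followed by canonicalization with Open
#'     Babel (via the ChemmineOB bindings).
#' }
#' One toolkit's canonical dialect is used uniformly for every source so
#' that string equality after standardization implies chemical identity
#' within that dialect.  The function is idempotent: re-standardizing its
#' output returns the same string.
#'
#' @param raw a single non-empty SMILES string.
#' @return the canonical standardized SMILES string.
#' @examples
#' \dontrun{
#' standardize_smiles("[Na+].CC(=O)[O-]")  # "CC(=O)O"
#' }
#' @export
standardize_smiles <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw))) {
    stop("`raw` must be a single non-empty SMILES string", call. = FALSE)
  }
  raw <- trimws(raw)
  check_smiles_syntax(raw)
  frags <- strsplit(raw, ".", fixed = TRUE)[[1]]
  if (any(!nzchar(frags))) {
    stop(sprintf("cannot parse SMILES '%s': empty fragment", raw), call. = FALSE)
  }
  mono <- grepl("^\\[[A-Z][a-z]?(\\+{1,3}|-{1,3}|[+-][0-9])\\]$", frags)
  if (any(!mono)) frags <- frags[!mono]
  joined <- paste(frags, collapse = ".")
  canonicalize_smiles(joined, neutralize = TRUE)
}

## Canonicalize (optionally neutralizing charges) through Open Babel.
canonicalize_smiles <- function(smiles, neutralize = TRUE) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES standardization requires the ChemmineOB package ",
         "(Open Babel bindings); it is not available", call. = FALSE)
  }
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else NULL
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", smiles, options = opts)
  )
  out <- trimws(gsub("[\t\n].*$", "", out))
  if (!nzchar(out)) {
    stop(sprintf("cannot parse SMILES '%s'", smiles), call. = FALSE)
  }
  out
}

## Lightweight syntactic screen.  Open Babel silently "repairs" some
## malformed inputs (e.g. "C(" parses as "C"), so structural balance is
## checked up front and unparsable inputs raise an error naming the input.
check_smiles_syntax <- function(s) {
  fail <- function(why) {
    stop(sprintf("cannot parse SMILES '%s': %s", s, why), call. = FALSE)
  }
  if (grepl("[^A-Za-z0-9@+\\[\\]()=#$:/\\\\%.*-]", s, perl = TRUE)) {
    fail("illegal character")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth_p <- 0L; depth_b <- 0L
  for (ch in chars) {
    if (ch == "(") depth_p <- depth_p + 1L
    if (ch == ")") { depth_p <- depth_p - 1L; if (depth_p < 0L) fail("unbalanced ')'") }
    if (ch == "[") { depth_b <- depth_b + 1L; if (depth_b > 1L) fail("nested '['") }
    if (ch == "]") { depth_b <- depth_b - 1L; if (depth_b < 0L) fail("unbalanced ']'") }
  }
  if (depth_p != 0L) fail("unbalanced parenthesis")
  if (depth_b != 0L) fail("unbalanced bracket")
  ## ring-bond digits outside brackets must pair up
  outside <- gsub("\\[[^]]*\\]", "", s)
  outside <- gsub("%[0-9]{2}", "", outside)
  digits <- regmatches(outside, gregexpr("[0-9]", outside))[[1]]
  if (length(digits) && any(table(digits) %% 2 != 0)) fail("unpaired ring bond")
  invisible(TRUE)
}
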