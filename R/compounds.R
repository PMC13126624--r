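#' Compound record tables
#'
#' A compound dataset is represented as a tibble with columns `compound_id`
#' (character), `smiles` (character), `atc_codes` (list column of character
#' vectors of 5-character codes), `source` (character tag) and `mol_weight`
#' (numeric Daltons, `NA` when unknown).
#'
#' @param compound_id,smiles,source character vectors.
#' @param atc_codes list of character vectors (or a character vector of
#'   semicolon-separated codes).
#' @param mol_weight numeric vector of molecular weights in Daltons.
#' @param validate_codes if `TRUE`, reject codes not matching the ATC
#'   pattern.
#' @return a `compound_records` tibble.
#' @export
compound_records <- function(compound_id, smiles, atc_codes,
                             source = "unknown", mol_weight = NA_real_,
                             validate_codes = TRUE) {
  n <- length(compound_id)
  if (is.character(atc_codes)) {
    atc_codes <- strsplit(atc_codes, ";", fixed = TRUE)
  }
  atc_codes <- lapply(atc_codes, function(x) {
    x <- toupper(trimws(x))
    unique(x[nzchar(x) & !is.na(x)])
  })
  if (validate_codes) {
    for (cc in atc_codes) if (length(cc)) assert_atc(cc)
  }
  out <- tibble::tibble(
    compound_id = as.character(compound_id),
    smiles = as.character(smiles),
    atc_codes = atc_codes,
    source = rep_len(as.character(source), n),
    mol_weight = rep_len(as.numeric(mol_weight), n)
  )
  class(out) <- c("compound_records", class(out))
  out
}

#' Read / write compound datasets
#'
#' The on-disk format is a UTF-8 CSV or TSV (chosen by file extension, `.tsv`
#' meaning tab-separated) with a header and columns `compound_id`, `smiles`,
#' `atc_codes` (semicolon-separated 5-character codes) and optionally
#' `mol_weight` and `source`.
#'
#' @param path file path.
#' @param validate_codes passed to [compound_records()].
#' @return `read_compound_table()` returns a `compound_records` tibble.
#' @export
read_compound_table <- function(path, validate_codes = TRUE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  need <- c("compound_id", "smiles", "atc_codes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("dataset is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  compound_records(
    df$compound_id, df$smiles, df$atc_codes,
    source = df$source %||% "unknown",
    mol_weight = if ("mol_weight" %in% names(df)) df$mol_weight else NA_real_,
    validate_codes = validate_codes
  )
}

#' @rdname read_compound_table
#' @param records a `compound_records` tibble.
#' @export
write_compound_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(
    compound_id = records$compound_id,
    smiles = records$smiles,
    atc_codes = vapply(records$atc_codes, paste, "", collapse = ";"),
    source = records$source,
    mol_weight = records$mol_weight,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter a standardized compound dataset
#'
#' Applies, in order, the curation rules used when assembling the training
#' set:
#' \enumerate{
#'   \item drop records lacking a SMILES or any ATC code;
#'   \item drop individual codes in anatomical group "V" unless the code is
#'     exactly `V03AX` ("other therapeutic products"), then drop records
#'     whose code set became empty;
#'   \item drop multicomponent structures (standardized SMILES still
#'     containing the `.` fragment separator);
#'   \item drop records heavier than `mw_cutoff` Daltons; records with
#'     unknown weight are kept, the small-molecule rule being applied only
#'     where a weight was recorded.
#' }
#'
#' @param records a `compound_records` tibble of standardized records.
#' @param mw_cutoff molecular-weight cutoff in Daltons (default 900, the
#'   conventional small-molecule bound).
#' @return the filtered `compound_records` tibble.
#' @export
filter_dataset <- function(records, mw_cutoff = 900) {
  stopifnot(is.data.frame(records))
  has_smiles <- !is.na(records$smiles) & nzchar(trimws(records$smiles))
  codes <- lapply(records$atc_codes, function(cc) {
    if (length(cc) == 0L) return(character())
    keep <- substr(cc, 1, 1) != "V" | vapply(cc, level_prefix, "", n = 4) == "V03AX"
    cc[keep]
  })
  has_codes <- vapply(codes, length, 1L) > 0L
  single_component <- has_smiles & !grepl(".", records$smiles, fixed = TRUE)
  weight_ok <- is.na(records$mol_weight) | records$mol_weight <= mw_cutoff
  keep <- has_smiles & has_codes & single_component & weight_ok
  out <- records[keep, , drop = FALSE]
  out$atc_codes <- codes[keep]
  out
}

#' Merge compound sources on canonical SMILES
#'
#' Records sharing a canonical SMILES are collapsed into one record whose
#' code set is the union of the merged sets; the first seen compound id is
#' kept, source tags are concatenated with `"+"`, and the first non-missing
#' molecular weight is retained.  All inputs must already be standardized so
#' that SMILES string equality is chemically meaningful.
#'
#' @param source_lists a list of `compound_records` tibbles (or a single
#'   tibble).
#' @return a deduplicated `compound_records` tibble with unique SMILES.
#' @export
merge_sources <- function(source_lists) {
  if (is.data.frame(source_lists)) source_lists <- list(source_lists)
  all <- do.call(rbind, source_lists)
  groups <- split(seq_len(nrow(all)), factor(all$smiles, levels = unique(all$smiles)))
  rows <- lapply(groups, function(ix) {
    srcs <- unique(all$source[ix])
    mw <- all$mol_weight[ix]
    tibble::tibble(
      compound_id = all$compound_id[ix[1]],
      smiles = all$smiles[ix[1]],
      atc_codes = list(unique(unlist(all$atc_codes[ix]))),
      source = paste(srcs, collapse = "+"),
      mol_weight = if (all(is.na(mw))) NA_real_ else mw[!is.na(mw)][1]
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("compound_records", class(out))
  out
}
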