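#' New-drug evaluation split
#'
#' Partitions a deduplicated compound table into train / validation / test
#' sets such that no molecule appears in more than one partition and the
#' proportion of multi-code compounds is preserved in every partition (the
#' split is stratified on the binary single- vs multi-code indicator, using
#' largest-remainder apportionment within each stratum).
#'
#' @param records a deduplicated `compound_records` tibble.
#' @param ratios named numeric vector of train/validation/test fractions
#'   summing to 1; default `c(train = .8, validation = .1, test = .1)`.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return an object of class `split_result` with elements `train`,
#'   `validation`, `test` (compound tibbles), `scenario = "newdrug"` and
#'   `seed`.
#' @export
new_drug_split <- function(records,
                           ratios = c(train = 0.8, validation = 0.1, test = 0.1),
                           seed = 1L) {
  stopifnot(is.data.frame(records))
  if (abs(sum(ratios) - 1) > 1e-8) stop("`ratios` must sum to 1", call. = FALSE)
  if (anyDuplicated(records$smiles)) {
    stop("records must be deduplicated by SMILES before splitting", call. = FALSE)
  }
  if (nrow(records) < sum(ratios > 0)) {
    stop("fewer records than partitions", call. = FALSE)
  }
  nm <- names(ratios) %||% c("train", "validation", "test")
  part <- character(nrow(records))
  with_seed(derive_seed(seed, "newdrug"), {
    multi <- vapply(records$atc_codes, length, 1L) > 1L
    for (stratum in unique(multi)) {
      idx <- which(multi == stratum)
      counts <- apportion(length(idx), ratios)
      shuffled <- sample(idx)
      part[shuffled] <- rep(nm, counts)
    }
  })
  out <- lapply(stats::setNames(nm, nm), function(p) {
    records[part == p, , drop = FALSE]
  })
  structure(c(out, list(scenario = "newdrug", seed = as.integer(seed))),
            class = "split_result")
}

#' Drug-repurposing evaluation split
#'
#' Splits each compound's *code set* rather than the compounds themselves:
#' every single-code compound goes entirely to training; for each multi-code
#' compound the codes are shuffled and divided with `ceiling(m/2)` codes to
#' training and the remainder to test, so the model must generate the
#' held-out indications of molecules it has seen with other indications.  A
#' validation set of whole compounds (with their training-side codes) is
#' then drawn from training, stratified on the original single/multi-code
#' indicator.
#'
#' @param records a deduplicated `compound_records` tibble.
#' @param val_fraction fraction of training compounds moved to validation
#'   (default 0.1).
#' @param seed integer seed.
#' @return a `split_result` with `train`, `validation`, `test` compound
#'   tibbles (test contains only multi-code compounds, carrying their
#'   held-out codes), `assignments` (tibble of compound_id / code /
#'   partition), `scenario = "repurposing"` and `seed`.
#' @export
repurposing_split <- function(records, val_fraction = 0.1, seed = 1L) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$smiles)) {
    stop("records must be deduplicated by SMILES before splitting", call. = FALSE)
  }
  with_seed(derive_seed(seed, "repurposing"), {
    n <- nrow(records)
    multi <- vapply(records$atc_codes, length, 1L) > 1L
    train_codes <- vector("list", n)
    test_codes <- vector("list", n)
    for (i in seq_len(n)) {
      cc <- records$atc_codes[[i]]
      if (length(cc) == 1L) {
        train_codes[[i]] <- cc
        test_codes[[i]] <- character(0)
      } else {
        cc <- sample(cc)
        n_tr <- ceiling(length(cc) / 2)
        train_codes[[i]] <- sort(cc[seq_len(n_tr)])
        test_codes[[i]] <- sort(cc[-seq_len(n_tr)])
      }
    }
    train <- records
    train$atc_codes <- train_codes
    has_test <- vapply(test_codes, length, 1L) > 0L
    test <- records[has_test, , drop = FALSE]
    test$atc_codes <- test_codes[has_test]

    ## validation: whole compounds drawn from train, stratified on the
    ## multi-code indicator
    val_idx <- integer(0)
    for (stratum in unique(multi)) {
      idx <- which(multi == stratum)
      n_val <- round(length(idx) * val_fraction)
      if (n_val > 0) val_idx <- c(val_idx, sample(idx, n_val))
    }
    validation <- train[val_idx, , drop = FALSE]
    train <- train[setdiff(seq_len(n), val_idx), , drop = FALSE]

    assignments <- tibble::tibble(
      compound_id = rep(records$compound_id, times = lengths(records$atc_codes)),
      code = unlist(records$atc_codes),
      partition = unlist(lapply(seq_len(n), function(i) {
        c(rep("train", length(train_codes[[i]])),
          rep("test", length(test_codes[[i]])))[
            match(records$atc_codes[[i]],
                  c(train_codes[[i]], test_codes[[i]]))]
      }))
    )
    structure(
      list(train = train, validation = validation, test = test,
           assignments = assignments, scenario = "repurposing",
           seed = as.integer(seed)),
      class = "split_result"
    )
  })
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result: %s, seed %d> train %d / validation %d / test %d compounds\n",
              x$scenario, x$seed, nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Write a split to disk
#'
#' Writes each partition as a standard dataset CSV plus a JSON manifest
#' recording the scenario, seed and (for repurposing splits) the
#' per-compound code assignments.
#'
#' @param split a `split_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "split_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in c("train", "validation", "test")) {
    write_compound_table(split[[p]], file.path(dir, paste0(p, ".csv")))
  }
  manifest <- list(scenario = split$scenario, seed = split$seed)
  if (!is.null(split$assignments)) {
    manifest$assignments <- split$assignments
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(dir)
}
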