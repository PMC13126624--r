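#' Descriptor matrices
#'
#' A `descriptor_matrix` bundles a compounds x descriptors numeric grid with
#' the bookkeeping needed to use it in models: the per-column keep/drop mask
#' produced by pruning, and the imputation medians and centering/scaling
#' statistics fitted on training rows so that the identical transformation
#' can be applied to new compounds.
#'
#' @param values numeric matrix, one row per compound (rownames are compound
#'   ids) and one named column per descriptor.
#' @return an object of class `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  structure(
    list(values = values, names = colnames(values),
         kept = rep(TRUE, ncol(values)),
         medians = NULL, center = NULL, scale = NULL, standardized = FALSE),
    class = "descriptor_matrix"
  )
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d compounds x %d descriptors (%d kept%s)\n",
              nrow(x$values), ncol(x$values), sum(x$kept),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Extract the model-ready value matrix
#'
#' @param dm a `descriptor_matrix`.
#' @return the numeric matrix restricted to kept columns (standardized if
#'   [fit_apply_standardization()] has been applied).
#' @export
descriptor_values <- function(dm) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  dm$values[, dm$kept, drop = FALSE]
}

#' Compute 1D/2D molecular descriptors from SMILES
#'
#' Computes a compact set of one- and two-dimensional descriptors (hydrogen
#' bond donor/acceptor counts, logP, molar refractivity, molecular weight,
#' TPSA, halogen count and per-element heavy-atom counts) with Open Babel
#' through the ChemmineR/ChemmineOB bindings.  Cells that cannot be computed
#' for a molecule are recorded as `NA`.
#'
#' @param smiles_list character vector of parseable SMILES strings.
#' @return an unpruned `descriptor_matrix` with one row per input.
#' @export
compute_descriptors <- function(smiles_list) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("descriptor computation requires the ChemmineR and ChemmineOB ",
         "packages; supply a precomputed descriptor file via ",
         "`read_descriptor_table()` instead", call. = FALSE)
  }
  prop_names <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  cols <- c(prop_names, paste0("n", elements))
  out <- matrix(NA_real_, nrow = length(smiles_list), ncol = length(cols),
                dimnames = list(names(smiles_list), cols))
  for (i in seq_along(smiles_list)) {
    row <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles_list[i]))
      p <- suppressWarnings(ChemmineR::propOB(sdf))
      counts <- ChemmineR::atomcountMA(sdf, addH = FALSE)
      elem <- vapply(elements, function(e) {
        if (e %in% colnames(counts)) as.numeric(counts[1, e]) else 0
      }, 0)
      c(vapply(prop_names, function(nm) {
        v <- suppressWarnings(as.numeric(p[[nm]]))
        if (length(v) == 1L) v else NA_real_
      }, 0), elem)
    }, error = function(e) rep(NA_real_, length(cols)))
    out[i, ] <- row
  }
  descriptor_matrix(out)
}

#' Read a precomputed descriptor table
#'
#' @param path CSV file whose first column is `compound_id` and whose
#'   remaining named columns are numeric descriptors.
#' @return an unpruned `descriptor_matrix` with compound ids as rownames.
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("descriptor file needs an id column plus data", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  descriptor_matrix(vals)
}

#' Prune constant and highly correlated descriptors
#'
#' First drops columns that are entirely missing or constant, then walks the
#' remaining columns in order, keeping a column only if its absolute Pearson
#' correlation with every already-kept column is at most `corr_threshold`
#' (greedy keep-first, so the result is deterministic for a fixed column
#' order).  Correlations use pairwise-complete observations.
#'
#' @param dm a `descriptor_matrix` with at least 2 rows.
#' @param corr_threshold maximum tolerated absolute pairwise correlation,
#'   in (0, 1]; default 0.95.
#' @return the `descriptor_matrix` with an updated keep mask.
#' @export
prune_descriptors <- function(dm, corr_threshold = 0.95) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  if (!is.numeric(corr_threshold) || length(corr_threshold) != 1L ||
      is.na(corr_threshold) || corr_threshold <= 0 || corr_threshold > 1) {
    stop("`corr_threshold` must be a number in (0, 1]", call. = FALSE)
  }
  v <- dm$values
  if (nrow(v) < 2L) stop("pruning needs at least 2 rows", call. = FALSE)
  sds <- apply(v, 2, stats::sd, na.rm = TRUE)
  n_obs <- colSums(!is.na(v))
  usable <- n_obs > 0L & !is.na(sds) & sds > 0
  keep <- rep(FALSE, ncol(v))
  cand <- which(usable)
  if (length(cand)) {
    cc <- suppressWarnings(stats::cor(v[, cand, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    kept_local <- integer(0)
    for (j in seq_along(cand)) {
      r <- abs(cc[j, kept_local])
      if (length(kept_local) == 0L || all(is.na(r) | r <= corr_threshold)) {
        kept_local <- c(kept_local, j)
      }
    }
    keep[cand[kept_local]] <- TRUE
  }
  dm$kept <- keep
  dm$medians <- dm$center <- dm$scale <- NULL
  dm$standardized <- FALSE
  dm
}

#' Impute and standardize descriptors on training rows
#'
#' Missing cells of every kept column are imputed with the column median of
#' the fitting rows; each kept column is then centered and scaled by the
#' fitting rows' mean and population standard deviation (a zero standard
#' deviation scales by 1).  The fitted statistics are stored on the object so the same
#' transformation can be replayed on unseen compounds with
#' [apply_standardization()].
#'
#' @param dm a `descriptor_matrix` (typically after [prune_descriptors()]).
#' @param fit_rows integer or logical index of the rows (training
#'   compounds) used to fit the statistics; defaults to all rows.
#' @return the `descriptor_matrix` with finite, standardized kept columns.
#' @export
fit_apply_standardization <- function(dm, fit_rows = seq_len(nrow(dm$values))) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  if (length(fit_rows) == 0L) stop("`fit_rows` must be non-empty", call. = FALSE)
  v <- dm$values
  kept <- which(dm$kept)
  med <- ctr <- scl <- stats::setNames(numeric(length(kept)), colnames(v)[kept])
  for (j in seq_along(kept)) {
    col <- v[, kept[j]]
    m <- stats::median(col[fit_rows], na.rm = TRUE)
    if (is.na(m)) m <- 0
    col[is.na(col)] <- m
    mu <- mean(col[fit_rows])
    s <- sqrt(mean((col[fit_rows] - mu)^2))   # population std
    if (is.na(s) || s == 0) s <- 1
    v[, kept[j]] <- (col - mu) / s
    med[j] <- m; ctr[j] <- mu; scl[j] <- s
  }
  dm$values <- v
  dm$medians <- med; dm$center <- ctr; dm$scale <- scl
  dm$standardized <- TRUE
  dm
}

#' @rdname fit_apply_standardization
#' @param new_values numeric matrix of raw descriptor values for new
#'   compounds, with (at least) the kept columns of `dm`.
#' @return `apply_standardization()` returns the matrix of standardized
#'   kept columns for the new compounds.
#' @export
apply_standardization <- function(dm, new_values) {
  stopifnot(inherits(dm, "descriptor_matrix"), dm$standardized)
  nms <- names(dm$center)
  miss <- setdiff(nms, colnames(new_values))
  if (length(miss)) {
    stop("new data lacks kept descriptor column(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  out <- new_values[, nms, drop = FALSE]
  for (j in seq_along(nms)) {
    col <- out[, j]
    col[is.na(col)] <- dm$medians[j]
    out[, j] <- (col - dm$center[j]) / dm$scale[j]
  }
  out
}
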