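#' Level-wise evaluation of generated ATC codes
#'
#' Hierarchical codes make flat set metrics misleading: a prediction that is
#' right at the anatomical level but wrong at the chemical level scores the
#' same as one that is wrong everywhere.  The level-wise metrics implemented
#' here (L-Precision and L-Recall) evaluate correctness one level at a time,
#' restricting attention at level *n* to the compounds -- and, within each
#' compound, to the predicted and actual codes -- that were already correct
#' through level *n*-1.
#'
#' For a compound \eqn{\alpha} with predicted set \eqn{\hat{Y}_\alpha} and
#' actual set \eqn{Y_\alpha}:
#' \itemize{
#'   \item a pair \eqn{(\hat{y}, y)} is correct at level *n* when their
#'     level-*n* prefixes are equal;
#'   \item \eqn{\hat{Y}^n_\alpha} / \eqn{Y^n_\alpha} are the predicted /
#'     actual codes correct up to level *n*-1 (all codes for *n* = 1);
#'   \item \eqn{C^n} is the subset of compounds with at least one correct
#'     prediction at level *n*, with \eqn{C^0 = C};
#'   \item L-Precision(C, n) averages, over \eqn{\alpha \in C^{n-1}}, the
#'     fraction of \eqn{\hat{Y}^n_\alpha} matching some code in
#'     \eqn{Y^n_\alpha} at level *n*; L-Recall(C, n) averages the fraction
#'     of \eqn{Y^n_\alpha} matched by some prediction.
#' }
#'
#' Generated strings that do not match the ATC pattern are retained in the
#' predicted set but can never be correct at any level, so they depress
#' precision (unconstrained generation is penalised rather than silently
#' dropped).  Levels whose evaluation set \eqn{C^{n-1}} is empty are reported
#' as `NA` with `evaluated_count` 0, never as 0.
#'
#' @param predicted list of character vectors, one per compound; generated
#'   code strings (possibly empty, possibly invalid).
#' @param actual list of character vectors of the same length; each element
#'   is the non-empty set of annotated 5-character ATC codes.
#' @return A tibble of class `level_metrics` with one row per level:
#'   `level`, `l_precision`, `l_recall`, `evaluated_count` (\eqn{|C^{n-1}|})
#'   and `surviving_count` (\eqn{|C^n|}).
#' @seealso [compute_exact_prf()] for flat metrics on complete codes.
#' @examples
#' compute_level_metrics(list(c("A02BA")), list(c("A02BC", "C07AB")))
#' @export
compute_level_metrics <- function(predicted, actual) {
  check_instances(predicted, actual)
  nc <- length(predicted)

  ## Per-compound running state: surviving predicted / actual sets and
  ## whether the compound is still in C^{n-1}.
  yhat <- lapply(predicted, function(p) unique(as.character(p)))
  yact <- lapply(actual, function(a) unique(as.character(a)))
  alive <- rep(TRUE, nc)   # membership in C^{n-1}; C^0 = C

  out <- tibble::tibble(
    level = 1:4, l_precision = NA_real_, l_recall = NA_real_,
    evaluated_count = 0L, surviving_count = 0L
  )

  for (n in 1:4) {
    idx <- which(alive)
    out$evaluated_count[n] <- length(idx)
    if (length(idx) == 0L) break
    prec <- rec <- numeric(length(idx))
    next_alive <- logical(nc)
    for (j in seq_along(idx)) {
      i <- idx[j]
      ph <- yhat[[i]]; ya <- yact[[i]]
      valid <- is_valid_atc(ph)
      ph_pref <- ifelse(valid, level_prefix(ph, n), NA_character_)
      ya_pref <- level_prefix(ya, n)
      hit_pred <- !is.na(ph_pref) & ph_pref %in% ya_pref
      hit_act <- ya_pref %in% ph_pref[!is.na(ph_pref)]
      prec[j] <- if (length(ph) == 0L) 0 else sum(hit_pred) / length(ph)
      rec[j] <- sum(hit_act) / length(ya)
      if (any(hit_pred)) {
        next_alive[i] <- TRUE
        yhat[[i]] <- ph[hit_pred]
        yact[[i]] <- ya[hit_act]
      }
    }
    out$l_precision[n] <- mean(prec)
    out$l_recall[n] <- mean(rec)
    out$surviving_count[n] <- sum(next_alive)
    alive <- next_alive
  }
  class(out) <- c("level_metrics", class(out))
  out
}

#' Exact-code precision, recall and F1
#'
#' Flat, example-based metrics on complete 4-level codes.  For each compound
#' the precision is the fraction of predicted codes that are annotated, the
#' recall the fraction of annotated codes that were predicted, and F1 their
#' harmonic mean (0 when both are 0); the reported values are the means over
#' compounds.  `aggregate = "of_means"` instead computes F1 from the mean
#' precision and mean recall.
#'
#' @inheritParams compute_level_metrics
#' @param aggregate `"per_compound"` (default: mean of per-compound F1,
#'   consistent with the meta-model's training objective) or `"of_means"`.
#' @return list with `precision`, `recall`, `f1` and the vector
#'   `per_compound_f1`.
#' @examples
#' compute_exact_prf(list("A02BC"), list(c("A02BC", "C07AB")))
#' @export
compute_exact_prf <- function(predicted, actual,
                              aggregate = c("per_compound", "of_means")) {
  aggregate <- match.arg(aggregate)
  check_instances(predicted, actual)
  p <- r <- f <- numeric(length(predicted))
  for (i in seq_along(predicted)) {
    ph <- unique(as.character(predicted[[i]]))
    ya <- unique(as.character(actual[[i]]))
    inter <- length(intersect(ph, ya))
    p[i] <- if (length(ph) == 0L) 0 else inter / length(ph)
    r[i] <- inter / length(ya)
    f[i] <- if (p[i] + r[i] == 0) 0 else 2 * p[i] * r[i] / (p[i] + r[i])
  }
  precision <- mean(p); recall <- mean(r)
  f1 <- if (aggregate == "per_compound") {
    mean(f)
  } else if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1, per_compound_f1 = f)
}

#' Full evaluation report
#'
#' Convenience wrapper combining [compute_level_metrics()] and
#' [compute_exact_prf()] into one report mirroring the usual per-level +
#' exact-code result layout.
#'
#' @inheritParams compute_exact_prf
#' @return list with elements `levels` (the level metrics tibble) and
#'   `exact` (precision/recall/f1).
#' @export
evaluate_predictions <- function(predicted, actual,
                                 aggregate = c("per_compound", "of_means")) {
  list(
    levels = compute_level_metrics(predicted, actual),
    exact = compute_exact_prf(predicted, actual, aggregate = aggregate)
  )
}

check_instances <- function(predicted, actual) {
  if (!is.list(predicted) || !is.list(actual)) {
    stop("`predicted` and `actual` must be lists of character vectors",
         call. = FALSE)
  }
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have the same length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("no evaluation instances", call. = FALSE)
  if (any(vapply(actual, length, 1L) == 0L)) {
    stop("every compound must have a non-empty actual code set", call. = FALSE)
  }
  for (a in actual) assert_atc(a, "actual ATC code")
  invisible(TRUE)
}
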