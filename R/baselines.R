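#' Empirical per-level code distributions (random baseline)
#'
#' Fits, for each ATC level, the empirical conditional distribution of the
#' level's continuation given the previous-level prefix, counting each
#' (compound, code) pair once.  Level 2 (the two-digit therapeutic unit) is
#' treated as a single categorical outcome.  Marginal per-level
#' distributions are kept as fallback for prefixes never observed.
#'
#' @param train_records `compound_records` tibble.
#' @return an object of class `level_distribution`.
#' @export
fit_level_distribution <- function(train_records) {
  codes <- unlist(train_records$atc_codes)
  if (length(codes) == 0L) stop("no training codes", call. = FALSE)
  assert_atc(codes)
  seg <- function(n) {
    from <- c(1L, 2L, 4L, 5L)[n]
    to <- c(1L, 3L, 4L, 5L)[n]
    substr(codes, from, to)
  }
  ## level-1 continuations are conditioned on a single "root" prefix
  prefix <- function(n) if (n == 1L) rep("root", length(codes)) else level_prefix(codes, n - 1L)
  cond <- lapply(1:4, function(n) {
    tab <- table(prefix = prefix(n), cont = seg(n))
    lapply(stats::setNames(rownames(tab), rownames(tab)), function(pf) {
      p <- stats::setNames(as.numeric(tab[pf, , drop = FALSE]), colnames(tab))
      p <- p[p > 0]
      p / sum(p)
    })
  })
  marginal <- lapply(1:4, function(n) {
    tab <- table(seg(n))
    stats::setNames(as.numeric(tab), names(tab)) / sum(tab)
  })
  structure(list(cond = cond, marginal = marginal), class = "level_distribution")
}

#' Random per-level baseline sampler
#'
#' Generates codes by sampling each level's continuation from the fitted
#' conditional distribution given the prefix sampled so far (falling back
#' to the level's marginal distribution for unseen prefixes).  Sampled
#' codes are therefore always valid-pattern codes built from observed
#' continuations.
#'
#' @param dist a `level_distribution`.
#' @param seed integer seed.
#' @param k number of distinct codes to return.
#' @param max_tries sampling attempts before giving up on distinctness.
#' @return character vector of up to `k` distinct code strings.
#' @export
random_predict <- function(dist, seed = 1L, k = 1, max_tries = 200 * k) {
  stopifnot(inherits(dist, "level_distribution"))
  with_seed(derive_seed(seed, "random-baseline"), {
    out <- character(0)
    tries <- 0L
    while (length(out) < k && tries < max_tries) {
      code <- ""
      for (n in 1:4) {
        key <- if (n == 1L) "root" else code
        pool <- dist$cond[[n]][[key]] %||% dist$marginal[[n]]
        code <- paste0(code, sample(names(pool), 1L, prob = as.numeric(pool)))
      }
      out <- unique(c(out, code))
      tries <- tries + 1L
    }
    out
  })
}

#' Hierarchical per-level probabilistic classifiers
#'
#' Trains one multiclass probabilistic model per ATC level: the level-1
#' model sees only the molecular descriptors, and each deeper model sees
#' the descriptors plus one-hot encodings of the characters chosen at the
#' previous levels.  The learner is pluggable: `"rf"` uses a probability
#' random forest (ranger), `"ffnn"` a single-hidden-layer softmax network
#' (nnet), and a custom learner may be given as
#' `list(fit = function(x, y, seed), prob = function(fit, x))` where
#' `prob()` returns a named probability vector/matrix over classes.
#'
#' @param train_records `compound_records` tibble.
#' @param descriptors standardized descriptor matrix with compound ids as
#'   rownames.
#' @param learner `"rf"`, `"ffnn"`, or a custom `list(fit, prob)`.
#' @param seed integer seed.
#' @param num_trees forest size for the `"rf"` learner.
#' @param hidden hidden width for the `"ffnn"` learner.
#' @return an object of class `hierarchical_model`.
#' @export
train_hierarchical <- function(train_records, descriptors,
                               learner = c("rf", "ffnn"), seed = 1L,
                               num_trees = 200, hidden = 16) {
  desc_mat <- as_desc_matrix(descriptors)
  lrn <- resolve_learner(learner, num_trees, hidden)
  pairs <- expand_code_pairs(train_records)
  x0 <- desc_mat[pairs$compound_id, , drop = FALSE]
  segs <- list(substr(pairs$code, 1, 1), substr(pairs$code, 2, 3),
               substr(pairs$code, 4, 4), substr(pairs$code, 5, 5))
  models <- vector("list", 4)
  levels_seen <- vector("list", 4)
  x <- x0
  for (n in 1:4) {
    y <- factor(segs[[n]])
    levels_seen[[n]] <- levels(y)
    models[[n]] <- lrn$fit(x, y, derive_seed(seed, paste0("hier-", n)))
    ## feed the true previous-level characters forward during training
    x <- cbind(x, onehot(segs[[n]], levels(y), prefix = paste0("l", n)))
  }
  structure(list(models = models, levels = levels_seen, prob = lrn$prob,
                 desc_names = colnames(desc_mat)),
            class = "hierarchical_model")
}

expand_code_pairs <- function(records) {
  data.frame(
    compound_id = rep(records$compound_id, lengths(records$atc_codes)),
    code = unlist(records$atc_codes),
    stringsAsFactors = FALSE
  )
}

onehot <- function(values, lev, prefix = "oh") {
  m <- matrix(0, length(values), length(lev),
              dimnames = list(NULL, paste0(prefix, "_", lev)))
  m[cbind(seq_along(values), match(values, lev))] <- 1
  m
}

resolve_learner <- function(learner, num_trees, hidden) {
  if (is.list(learner)) {
    stopifnot(is.function(learner$fit), is.function(learner$prob))
    return(learner)
  }
  learner <- match.arg(learner, c("rf", "ffnn"))
  if (learner == "rf") {
    list(
      fit = function(x, y, seed) {
        df <- data.frame(x, check.names = FALSE)
        ranger::ranger(y = y, x = df, probability = TRUE,
                       num.trees = num_trees, seed = seed, num.threads = 1)
      },
      prob = function(fit, x) {
        stats::predict(fit, data.frame(x, check.names = FALSE),
                       num.threads = 1)$predictions
      }
    )
  } else {
    list(
      fit = function(x, y, seed) {
        with_seed(seed, {
          if (nlevels(droplevels(y)) < 2L) {
            structure(list(constant = levels(droplevels(y))), class = "const_fit")
          } else {
            nnet::nnet(x, nnet::class.ind(y), size = hidden, softmax = TRUE,
                       maxit = 200, decay = 1e-4, trace = FALSE, MaxNWts = 20000)
          }
        })
      },
      prob = function(fit, x) {
        if (inherits(fit, "const_fit")) {
          matrix(1, nrow(x), 1, dimnames = list(NULL, fit$constant))
        } else stats::predict(fit, x)
      }
    )
  }
}

#' @rdname train_hierarchical
#' @param model a `hierarchical_model`.
#' @param descriptor_vector named numeric vector (or 1-row matrix) of
#'   standardized descriptors for one compound.
#' @return `hierarchical_predict()` returns a single 5-character code
#'   string sampled level by level, feeding each chosen character to the
#'   next level's model.
#' @export
hierarchical_predict <- function(model, descriptor_vector, seed = 1L) {
  stopifnot(inherits(model, "hierarchical_model"))
  if (any(vapply(model$models, is.null, TRUE))) {
    stop("a level model is missing", call. = FALSE)
  }
  x <- matrix(as.numeric(descriptor_vector), nrow = 1,
              dimnames = list(NULL, model$desc_names))
  with_seed(derive_seed(seed, "hier-predict"), {
    code <- ""
    for (n in 1:4) {
      pr <- model$prob(model$models[[n]], x)
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
      cls <- colnames(pr)
      pick <- sample(cls, 1L, prob = pmax(as.numeric(pr[1, ]), 0))
      code <- paste0(code, pick)
      x <- cbind(x, onehot(pick, model$levels[[n]], prefix = paste0("l", n)))
    }
    code
  })
}

#' @rdname train_hierarchical
#' @param k number of distinct codes to sample.
#' @param max_tries sampling attempts before giving up on distinctness.
#' @return `hierarchical_generate()` returns up to `k` distinct codes.
#' @export
hierarchical_generate <- function(model, descriptor_vector, seed = 1L, k = 1,
                                  max_tries = 50 * k) {
  out <- character(0)
  tries <- 0L
  while (length(out) < k && tries < max_tries) {
    out <- unique(c(out, hierarchical_predict(model, descriptor_vector,
                                              seed = derive_seed(seed, tries))))
    tries <- tries + 1L
  }
  out
}
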