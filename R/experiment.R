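#' Experiment configuration
#'
#' Describes a repeated-seed evaluation: the scenario (new-drug annotation
#' or drug repurposing), the model selector, the list of split seeds (ten
#' by default, matching the convention of averaging over ten independent
#' train-test repetitions) and the sweep over the number of generated codes
#' per compound.
#'
#' @param scenario `"newdrug"` or `"repurposing"`.
#' @param model `"bilstm"`, `"transformer"`, `"random"`, `"rf"` or
#'   `"ffnn"`.
#' @param seeds integer vector of per-repetition seeds (default `1:10`).
#' @param multimodal fuse descriptors into the seq2seq model.
#' @param k_sweep integer vector of generated-code counts to evaluate.
#' @param beam_width beam size for seq2seq generation.
#' @param ratios new-drug split fractions.
#' @param val_fraction repurposing validation fraction.
#' @param seq2seq named list of overrides passed to [seq2seq_config()].
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("newdrug", "repurposing"),
                              model = c("bilstm", "transformer", "random",
                                        "rf", "ffnn"),
                              seeds = 1:10, multimodal = FALSE,
                              k_sweep = 1:3, beam_width = 10,
                              ratios = c(train = 0.8, validation = 0.1,
                                         test = 0.1),
                              val_fraction = 0.1, seq2seq = list()) {
  structure(
    list(scenario = match.arg(scenario), model = match.arg(model),
         seeds = as.integer(seeds), multimodal = isTRUE(multimodal),
         k_sweep = as.integer(k_sweep), beam_width = beam_width,
         ratios = ratios, val_fraction = val_fraction, seq2seq = seq2seq),
    class = "experiment_config"
  )
}

#' @rdname experiment_config
#' @param path YAML file whose keys mirror the arguments of
#'   `experiment_config()`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(experiment_config)))]
  if (!is.null(args$ratios)) args$ratios <- unlist(args$ratios)
  do.call(experiment_config, args)
}

#' Run a repeated-seed evaluation experiment
#'
#' For every seed: builds the scenario's split, trains the selected model
#' on the training partition, generates `k` candidate codes per test
#' compound for each `k` in the sweep, and scores the predictions with the
#' level-wise metrics and the exact-code precision/recall/F1.  All
#' randomness (splitting, model initialisation, sampling baselines) is
#' derived from the per-repetition seed, so the same configuration always
#' yields the identical report.
#'
#' @param config an [experiment_config()].
#' @param records a deduplicated `compound_records` tibble.
#' @param descriptors an unstandardized `descriptor_matrix` (pruned or
#'   not); for every repetition the imputation/standardization statistics
#'   are fitted on that repetition's training rows only.  Required for
#'   multimodal and hierarchical models.
#' @return an object of class `atc_experiment`: list with `per_seed`
#'   (tibble of seed x k x metric values) and `summary` (per k x metric
#'   mean, sd and the number of repetitions where the metric was defined).
#' @export
run_experiment <- function(config, records, descriptors = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (seed in config$seeds) {
    res <- tryCatch(
      run_one_repetition(config, records, descriptors, seed),
      error = function(e) {
        stop(sprintf("repetition with seed %d failed: %s", seed,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    rows[[length(rows) + 1L]] <- res
  }
  per_seed <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ k + metric, data = per_seed,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)),
                          na.action = stats::na.omit)
  summary <- tibble::tibble(
    k = agg$k, metric = agg$metric,
    mean = agg$value[, "mean"],
    sd = ifelse(is.na(agg$value[, "sd"]), 0, agg$value[, "sd"]),
    n_defined = as.integer(agg$value[, "n"])
  )
  structure(list(per_seed = tibble::as_tibble(per_seed), summary = summary,
                 config = config),
            class = "atc_experiment")
}

run_one_repetition <- function(config, records, descriptors, seed) {
  split <- if (config$scenario == "newdrug") {
    new_drug_split(records, config$ratios, seed = seed)
  } else {
    repurposing_split(records, config$val_fraction, seed = seed)
  }
  needs_desc <- config$multimodal || config$model %in% c("rf", "ffnn")
  desc_std <- NULL
  if (needs_desc) {
    if (is.null(descriptors)) {
      stop("this model configuration requires `descriptors`", call. = FALSE)
    }
    dm <- descriptors
    if (!inherits(dm, "descriptor_matrix")) dm <- descriptor_matrix(as.matrix(dm))
    fit_rows <- rownames(dm$values) %in% split$train$compound_id
    dm <- fit_apply_standardization(dm, fit_rows)
    desc_std <- descriptor_values(dm)
  }

  test <- split$test
  actual <- test$atc_codes
  model <- switch(
    config$model,
    bilstm = ,
    transformer = {
      args <- utils::modifyList(
        list(architecture = config$model, multimodal = config$multimodal,
             seed = derive_seed(seed, "model")),
        config$seq2seq
      )
      train_seq2seq(split$train, split$validation,
                    do.call(seq2seq_config, args),
                    descriptors = if (config$multimodal) desc_std)
    },
    random = fit_level_distribution(split$train),
    rf = train_hierarchical(split$train, desc_std, "rf",
                            seed = derive_seed(seed, "model")),
    ffnn = train_hierarchical(split$train, desc_std, "ffnn",
                              seed = derive_seed(seed, "model"))
  )

  k_max <- max(config$k_sweep)
  predicted_full <- predict_test_set(config, model, test, desc_std, k_max, seed)
  out <- list()
  for (k in config$k_sweep) {
    predicted <- lapply(predicted_full, utils::head, k)
    lm <- compute_level_metrics(predicted, actual)
    ex <- compute_exact_prf(predicted, actual)
    vals <- c(
      stats::setNames(lm$l_precision, paste0("l_precision_", 1:4)),
      stats::setNames(lm$l_recall, paste0("l_recall_", 1:4)),
      precision = ex$precision, recall = ex$recall, f1 = ex$f1
    )
    out[[length(out) + 1L]] <- tibble::tibble(
      seed = seed, k = k, metric = names(vals), value = unname(vals)
    )
  }
  do.call(rbind, out)
}

## Ranked candidate lists (length k_max) for every test compound.
predict_test_set <- function(config, model, test, desc_std, k_max, seed) {
  if (config$model %in% c("bilstm", "transformer")) {
    preds <- generate_codes(model, test,
                            descriptors = if (config$multimodal) desc_std,
                            k = k_max, beam_width = max(config$beam_width, k_max))
    lapply(test$compound_id, function(id) {
      p <- preds[preds$compound_id == id, , drop = FALSE]
      p$code[order(p$log_prob, decreasing = TRUE)]
    })
  } else if (config$model == "random") {
    lapply(seq_len(nrow(test)), function(i) {
      random_predict(model, seed = derive_seed(seed, paste0("rand-", i)),
                     k = k_max)
    })
  } else {
    lapply(seq_len(nrow(test)), function(i) {
      hierarchical_generate(model, desc_std[test$compound_id[i], ],
                            seed = derive_seed(seed, paste0("hier-", i)),
                            k = k_max)
    })
  }
}

#' @export
print.atc_experiment <- function(x, ...) {
  cat(sprintf("<atc_experiment: %s, model %s%s, %d seeds>\n",
              x$config$scenario, x$config$model,
              if (x$config$multimodal) " (multimodal)" else "",
              length(x$config$seeds)))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
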