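two_code_records <- function() {
  compound_records(c("p", "q"), c("CC", "CN"), list("A02BC", "A02BA"))
}

test_that("level distributions are empirical conditional frequencies", {
  dist <- fit_level_distribution(two_code_records())
  l4 <- dist$cond[[4]][["A02B"]]
  expect_setequal(names(l4), c("A", "C"))
  expect_equal(unname(l4[c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(dist$cond[[1]][["root"]]["A"]), 1)
  expect_equal(unname(dist$cond[[2]][["A"]]["02"]), 1)
})

test_that("each (compound, code) pair counts once when fitting", {
  rec <- compound_records(c("a", "b", "c"), c("C", "CC", "CCC"),
                          list(c("A02BC", "B01AC"), "A02BC", "A02BC"))
  dist <- fit_level_distribution(rec)
  l1 <- dist$cond[[1]][["root"]]
  expect_equal(unname(l1["A"]), 3 / 4)
  expect_equal(unname(l1["B"]), 1 / 4)
})

test_that("point-mass distributions always reproduce the single training code", {
  rec <- compound_records("solo", "CC", list("N06AB"))
  dist <- fit_level_distribution(rec)
  for (seed in 1:5) {
    expect_identical(random_predict(dist, seed = seed, k = 1), "N06AB")
  }
  ## only one code exists, so k > 1 cannot be satisfied
  expect_identical(random_predict(dist, seed = 1, k = 3, max_tries = 50),
                   "N06AB")
})

test_that("sampling frequencies match the fitted conditionals", {
  dist <- fit_level_distribution(two_code_records())
  draws <- vapply(1:10000, function(s) random_predict(dist, seed = s, k = 1), "")
  expect_true(all(is_valid_atc(draws)))
  expect_setequal(unique(draws), c("A02BC", "A02BA"))
  frac_c <- mean(substr(draws, 5, 5) == "C")
  sigma <- sqrt(0.25 / 10000)
  expect_lt(abs(frac_c - 0.5), 3 * sigma)
  ## chi-square goodness of fit against the fitted level-4 conditional
  tab <- table(factor(substr(draws, 5, 5), levels = c("A", "C")))
  expect_gt(chisq.test(tab, p = c(0.5, 0.5))$p.value, 0.01)
})

test_that("random predictions are seeded and valid-pattern", {
  set.seed(99)
  rec <- compound_records(
    sprintf("r%d", 1:30), sprintf("C%d", 1:30),
    lapply(1:30, function(i) {
      paste0(sample(LETTERS[1:5], 1), sprintf("%02d", sample(1:9, 1)),
             sample(LETTERS[1:4], 1), sample(LETTERS[1:4], 1))
    })
  )
  dist <- fit_level_distribution(rec)
  a <- random_predict(dist, seed = 7, k = 5)
  b <- random_predict(dist, seed = 7, k = 5)
  expect_identical(a, b)
  expect_identical(anyDuplicated(a), 0L)
  expect_true(all(is_valid_atc(a)))
})

hier_fixture <- function(n = 240, seed = 5) {
  set.seed(seed)
  desc <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(sprintf("h%03d", 1:n), paste0("D", 1:6)))
  ## level-1 letter is a threshold function of descriptor 1; deeper levels
  ## are constants so the fixture isolates level-1 learnability
  l1 <- ifelse(desc[, 1] > 0, "A", "B")
  rec <- compound_records(rownames(desc), sprintf("C%d", 1:n),
                          as.list(paste0(l1, "02BC")))
  list(records = rec, descriptors = desc)
}

test_that("hierarchical forest classifiers recover a separable level-1 rule", {
  fx <- hier_fixture()
  train <- 1:200
  model <- train_hierarchical(fx$records[train, ], fx$descriptors[train, ],
                              learner = "rf", seed = 2)
  test_idx <- 201:240
  pred <- vapply(test_idx, function(i) {
    hierarchical_predict(model, fx$descriptors[i, ], seed = 1000 + i)
  }, "")
  actual <- vapply(fx$records$atc_codes[test_idx], `[[`, "", 1)
  lm <- compute_level_metrics(as.list(pred), as.list(actual))
  expect_gte(lm$l_precision[1], 0.9)
  expect_true(all(is_valid_atc(pred)))
})

test_that("hierarchical prediction is deterministic and respects point masses", {
  fx <- hier_fixture(n = 60)
  model <- train_hierarchical(fx$records, fx$descriptors, learner = "rf",
                              seed = 2, num_trees = 50)
  a <- hierarchical_predict(model, fx$descriptors[1, ], seed = 3)
  b <- hierarchical_predict(model, fx$descriptors[1, ], seed = 3)
  expect_identical(a, b)
  ## deeper levels were constant in training -> deterministic suffix
  expect_identical(substr(a, 2, 5), "02BC")
  broken <- model
  broken$models[2] <- list(NULL)
  expect_error(hierarchical_predict(broken, fx$descriptors[1, ], seed = 1),
               "level model is missing")
})

test_that("the ffnn learner and custom learners plug into the same interface", {
  fx <- hier_fixture(n = 120)
  model <- train_hierarchical(fx$records, fx$descriptors, learner = "ffnn",
                              seed = 4, hidden = 8)
  p <- hierarchical_predict(model, fx$descriptors[1, ], seed = 9)
  expect_true(is_valid_atc(p))
  ## custom learner: majority-class probabilities
  maj <- list(
    fit = function(x, y, seed) table(y) / length(y),
    prob = function(fit, x) matrix(as.numeric(fit), nrow(x), length(fit),
                                   byrow = TRUE, dimnames = list(NULL, names(fit)))
  )
  m2 <- train_hierarchical(fx$records, fx$descriptors, learner = maj, seed = 1)
  expect_true(is_valid_atc(hierarchical_predict(m2, fx$descriptors[2, ], seed = 2)))
  g <- hierarchical_generate(m2, fx$descriptors[2, ], seed = 2, k = 2)
  expect_lte(length(g), 2L)
  expect_identical(anyDuplicated(g), 0L)
})
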