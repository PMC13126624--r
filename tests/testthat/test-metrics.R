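test_that("the hand-walked partial-credit instance scores as derived", {
  ## actual {A02BC, C07AB}, predicted {A02BA}: the single prediction is
  ## correct through level 3 and wrong at level 4
  lm <- compute_level_metrics(list("A02BA"), list(c("A02BC", "C07AB")))
  expect_equal(lm$l_precision, c(1, 1, 1, 0))
  expect_equal(lm$l_recall, c(0.5, 1, 1, 0))
  expect_identical(lm$evaluated_count, c(1L, 1L, 1L, 1L))
  expect_identical(lm$surviving_count, c(1L, 1L, 1L, 0L))
})

test_that("perfect prediction yields unit metrics at every level", {
  actual <- list(c("A02BC", "C07AB"), "N06AB", c("B01AC", "J01CA", "R03AC"))
  lm <- compute_level_metrics(actual, actual)
  expect_equal(lm$l_precision, rep(1, 4))
  expect_equal(lm$l_recall, rep(1, 4))
  expect_identical(lm$evaluated_count, rep(3L, 4))
  ex <- compute_exact_prf(actual, actual)
  expect_equal(c(ex$precision, ex$recall, ex$f1), c(1, 1, 1))
})

test_that("a total miss zeroes level 1 and leaves deeper levels undefined", {
  lm <- compute_level_metrics(list("B01AC"), list("A02BC"))
  expect_equal(lm$l_precision[1], 0)
  expect_equal(lm$l_recall[1], 0)
  expect_identical(lm$surviving_count[1], 0L)
  expect_true(all(is.na(lm$l_precision[2:4])))
  expect_true(all(is.na(lm$l_recall[2:4])))
  expect_identical(lm$evaluated_count[2:4], rep(0L, 3))
})

test_that("empty prediction sets are allowed and score zero at level 1", {
  lm <- compute_level_metrics(list(character(0), "A02BC"),
                              list("A02BC", "A02BC"))
  expect_equal(lm$l_precision[1], 0.5)   # mean of 0 and 1
  expect_equal(lm$l_recall[1], 0.5)
  expect_identical(lm$evaluated_count[1], 2L)
})

test_that("invalid generated strings are retained but never count as correct", {
  ## "A02B" (too short) would share the level-1 letter but must not match
  lm <- compute_level_metrics(list(c("A02BC", "A02B", "xxxxx")),
                              list("A02BC"))
  expect_equal(lm$l_precision[1], 1 / 3)
  expect_equal(lm$l_recall[1], 1)
  ## the invalid strings do not survive into deeper levels
  expect_equal(lm$l_precision[2], 1)
})

test_that("implementation matches the brute-force enumerator on random instances", {
  inst <- random_instances(60, seed = 404)
  for (grp in split(seq_len(60), rep(1:6, each = 10))) {
    mine <- compute_level_metrics(inst$predicted[grp], inst$actual[grp])
    ref <- bf_level_metrics(inst$predicted[grp], inst$actual[grp])
    expect_equal(mine$l_precision, ref$l_precision, tolerance = 1e-12)
    expect_equal(mine$l_recall, ref$l_recall, tolerance = 1e-12)
    expect_identical(mine$evaluated_count, ref$evaluated_count)
    ex <- compute_exact_prf(inst$predicted[grp], inst$actual[grp])
    exr <- bf_exact_prf(inst$predicted[grp], inst$actual[grp])
    expect_equal(ex$precision, exr$precision, tolerance = 1e-12)
    expect_equal(ex$recall, exr$recall, tolerance = 1e-12)
    expect_equal(ex$f1, exr$f1, tolerance = 1e-12)
  }
})

test_that("with one prediction and one actual code, L-Precision equals L-Recall", {
  set.seed(7)
  rand_code <- function() {
    paste0(sample(c("A", "B"), 1), sprintf("%02d", sample(1:2, 1)),
           sample(c("A", "B"), 1), sample(c("A", "B"), 1))
  }
  for (i in 1:25) {
    pred <- replicate(10, rand_code(), simplify = FALSE)
    act <- replicate(10, rand_code(), simplify = FALSE)
    lm <- compute_level_metrics(pred, act)
    expect_equal(lm$l_precision, lm$l_recall)
  }
})

test_that("evaluated-compound counts never increase with depth", {
  for (i in 1:10) {
    inst <- random_instances(20, seed = 2000 + i)
    lm <- compute_level_metrics(inst$predicted, inst$actual)
    expect_true(all(diff(lm$evaluated_count) <= 0))
    expect_true(lm$evaluated_count[1] == 20L)
    expect_true(all(lm$surviving_count <= lm$evaluated_count))
  }
})

test_that("exact precision/recall/F1 follow per-compound set arithmetic", {
  ex <- compute_exact_prf(list("A02BC"), list(c("A02BC", "C07AB")))
  expect_equal(ex$precision, 1)
  expect_equal(ex$recall, 0.5)
  expect_equal(ex$f1, 2 / 3)
  dis <- compute_exact_prf(list("B01AC"), list("A02BC"))
  expect_equal(c(dis$precision, dis$recall, dis$f1), c(0, 0, 0))
})

test_that("F1-of-means aggregation flag is honoured", {
  pred <- list("A02BC", "B01AC")
  act <- list(c("A02BC", "C07AB"), "N06AB")
  per <- compute_exact_prf(pred, act, aggregate = "per_compound")
  oom <- compute_exact_prf(pred, act, aggregate = "of_means")
  expect_equal(per$f1, mean(c(2 / 3, 0)))
  expect_equal(oom$f1, 2 * 0.5 * 0.25 / (0.5 + 0.25))
})

test_that("malformed evaluation inputs are rejected", {
  expect_error(compute_level_metrics(list("A02BC"), list(character(0))),
               "non-empty actual")
  expect_error(compute_level_metrics(list("A02BC"), list("A02BC", "C07AB")),
               "same length")
  expect_error(compute_level_metrics(list(), list()), "no evaluation instances")
})
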