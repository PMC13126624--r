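test_that("optimal_k maximizes per-compound F1 with a smallest-k tie-break", {
  expect_identical(optimal_k(c("A02BC", "C07AB", "B01AC"),
                             c("A02BC", "C07AB")), 2L)
  expect_identical(optimal_k(c("A02BC", "B01AC", "C07AB"), "A02BC"), 1L)
  ## no candidate correct: every k ties at F1 = 0 -> smallest k
  expect_identical(optimal_k(c("X01AA", "X02AA"), "A02BC"), 1L)
  expect_error(optimal_k(character(0), "A02BC"), "non-empty")
  expect_error(optimal_k("A02BC", character(0)), "non-empty")
})

test_that("optimal_k agrees with direct F1 maximization on random instances", {
  set.seed(12)
  pool <- c(outer(c("A02B", "C07A", "B01A"), c("A", "B", "C"), paste0))
  for (i in 1:200) {
    cand <- sample(pool, sample(1:8, 1))
    act <- sample(pool, sample(1:4, 1))
    f1_at <- vapply(seq_along(cand), function(k) {
      inter <- length(intersect(cand[1:k], act))
      if (inter == 0) return(0)
      p <- inter / k; r <- inter / length(act)
      2 * p * r / (p + r)
    }, 0)
    expect_identical(optimal_k(cand, act), which.max(f1_at))
  }
})

## a deterministic toy generator with controllable candidate counts
fixed_decoder <- function(n_seqs) {
  chars <- c("a", "b", "c", "d")
  functional_decoder(function(gen) {
    n <- nchar(gen)
    if (n >= 1) return(c("<end>" = 0))
    p <- exp(-(seq_len(n_seqs))) / sum(exp(-(seq_len(n_seqs))))
    log(setNames(p, chars[seq_len(n_seqs)]))
  }, chars)
}

test_that("meta training samples are sentinel-padded to length 10", {
  model <- fixed_decoder(4)   # emits exactly 4 distinct one-char sequences
  rec <- compound_records(c("c1", "c2"), c("ab", "ba"),
                          list("A02BC", c("A02BC", "C07AB")))
  samples <- build_meta_training_set(model, rec, k_max = 10, beam_width = 12)
  lp <- as.matrix(samples[, paste0("lp", 1:10)])
  expect_identical(dim(lp), c(2L, 10L))
  expect_identical(rowSums(lp < -1e8), c(6, 6))   # 6 sentinels each
  real <- lp[1, 1:4]
  expect_true(all(diff(real) <= 0))
  expect_true(all(samples$optimal_k <= 4))
  ## deterministic across runs
  samples2 <- build_meta_training_set(model, rec, k_max = 10, beam_width = 12)
  expect_identical(samples, samples2)
})

test_that("meta labels reflect multi-code compounds when top candidates are right", {
  ## generator whose two best candidates are the two annotated codes
  chars <- unique(strsplit("A02BC7", "")[[1]])
  step_fn <- function(gen) {
    targets <- c("A02BC", "A02BB")
    n <- nchar(gen)
    if (n == 5) return(c("<end>" = 0))
    nxt <- unique(substr(targets[startsWith(targets, gen) | gen == ""], n + 1, n + 1))
    p <- rep(0.98 / length(nxt), length(nxt))
    others <- setdiff(chars, nxt)
    log(setNames(c(p, rep(0.02 / length(others), length(others))),
                 c(nxt, others)))
  }
  model <- functional_decoder(step_fn, chars)
  rec <- compound_records("m", "xx", list(c("A02BC", "A02BB")))
  samples <- build_meta_training_set(model, rec, k_max = 10, beam_width = 16)
  expect_identical(samples$optimal_k, 2L)
})

test_that("the meta network recovers a separable rule and is reproducible", {
  set.seed(80)
  n <- 600
  lp1 <- runif(n, -3, -0.1)
  gap <- runif(n, 0, 1.5)
  x <- cbind(lp1, lp1 - gap,
             matrix(sort(runif(n * 8, -12, -4), decreasing = TRUE), n, 8))
  x <- t(apply(x, 1, sort, decreasing = TRUE))
  colnames(x) <- paste0("lp", 1:10)
  samples <- tibble::as_tibble(as.data.frame(x))
  samples$optimal_k <- ifelse(gap < 0.5, 2L, 1L)
  tr <- 1:500; te <- 501:600
  meta <- train_meta(samples[tr, ], seed = 3)
  pred <- predict_k(meta, as.matrix(samples[te, paste0("lp", 1:10)]))
  expect_gt(mean(pred == samples$optimal_k[te]), 0.9)
  meta2 <- train_meta(samples[tr, ], seed = 3)
  pred2 <- predict_k(meta2, as.matrix(samples[te, paste0("lp", 1:10)]))
  expect_identical(pred, pred2)
})

test_that("degenerate and malformed meta inputs are handled", {
  samples <- tibble::as_tibble(as.data.frame(
    matrix(-1, 5, 10, dimnames = list(NULL, paste0("lp", 1:10)))))
  samples$optimal_k <- rep(2L, 5)
  meta <- train_meta(samples, seed = 1)
  expect_identical(predict_k(meta, rep(-1, 10)), 2L)
  expect_error(predict_k(meta, rep(-1, 7)), "10 entries")
})
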