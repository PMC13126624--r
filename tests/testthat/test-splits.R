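synthetic_records <- function(n, n_multi, seed = 1) {
  set.seed(seed)
  codes <- lapply(seq_len(n), function(i) {
    base <- paste0(sample(LETTERS[1:8], 1), sprintf("%02d", sample(1:20, 1)),
                   sample(LETTERS[1:6], 1), sample(LETTERS[1:6], 1))
    if (i <= n_multi) {
      unique(c(base, paste0(sample(LETTERS[9:16], 1), "01AA"),
               paste0(sample(LETTERS[17:20], 1), "02BB")))[1:sample(2:3, 1)]
    } else base
  })
  compound_records(sprintf("m%03d", seq_len(n)),
                   vapply(seq_len(n), function(i) {
                     paste(sample(c("C", "N", "O"), 10, TRUE), collapse = "")
                   }, ""),
                   codes)
}

test_that("new-drug split stratifies the multi-code fraction exactly", {
  rec <- synthetic_records(100, 20)
  rec$smiles <- paste0(rec$smiles, sprintf("%03d", 1:100))  # ensure unique
  sp <- new_drug_split(rec, c(train = 0.8, validation = 0.1, test = 0.1),
                       seed = 5)
  expect_identical(nrow(sp$test), 10L)
  multi_in <- function(part) sum(lengths(part$atc_codes) > 1)
  expect_identical(multi_in(sp$test), 2L)
  expect_identical(multi_in(sp$validation), 2L)
  expect_identical(multi_in(sp$train), 16L)
})

test_that("new-drug partitions are disjoint and cover the input", {
  rec <- synthetic_records(57, 13)
  rec$smiles <- paste0(rec$smiles, seq_len(57))
  for (seed in 1:4) {
    sp <- new_drug_split(rec, seed = seed)
    ids <- c(sp$train$smiles, sp$validation$smiles, sp$test$smiles)
    expect_identical(anyDuplicated(ids), 0L)
    expect_setequal(ids, rec$smiles)
  }
})

test_that("new-drug split is deterministic given the seed", {
  rec <- synthetic_records(40, 10)
  rec$smiles <- paste0(rec$smiles, seq_len(40))
  a <- new_drug_split(rec, seed = 77)
  b <- new_drug_split(rec, seed = 77)
  expect_identical(a$test$compound_id, b$test$compound_id)
  expect_identical(a$train$compound_id, b$train$compound_id)
  d <- new_drug_split(rec, seed = 78)
  expect_false(identical(a$test$compound_id, d$test$compound_id))
})

test_that("degenerate new-drug splits are rejected", {
  rec <- synthetic_records(2, 0)
  rec$smiles <- paste0(rec$smiles, 1:2)
  expect_error(new_drug_split(rec), "fewer records than partitions")
  expect_error(new_drug_split(synthetic_records(10, 2),
                              ratios = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("repurposing split sends single-code compounds wholly to train", {
  rec <- synthetic_records(60, 25)
  rec$smiles <- paste0(rec$smiles, seq_len(60))
  sp <- repurposing_split(rec, val_fraction = 0.1, seed = 3)
  single_ids <- rec$compound_id[lengths(rec$atc_codes) == 1]
  expect_false(any(single_ids %in% sp$test$compound_id))
  tr_val <- rbind(sp$train, sp$validation)
  for (id in single_ids) {
    expect_identical(tr_val$atc_codes[[match(id, tr_val$compound_id)]],
                     rec$atc_codes[[match(id, rec$compound_id)]])
  }
})

test_that("repurposing split partitions each multi-code set with the ceil rule", {
  rec <- synthetic_records(60, 25)
  rec$smiles <- paste0(rec$smiles, seq_len(60))
  sp <- repurposing_split(rec, seed = 3)
  tr_val <- rbind(sp$train, sp$validation)
  for (i in which(lengths(rec$atc_codes) > 1)) {
    id <- rec$compound_id[i]
    cc <- rec$atc_codes[[i]]
    tr <- tr_val$atc_codes[[match(id, tr_val$compound_id)]]
    te <- sp$test$atc_codes[[match(id, sp$test$compound_id)]]
    expect_identical(length(tr), as.integer(ceiling(length(cc) / 2)))
    expect_identical(length(te), length(cc) - length(tr))
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), cc)
  }
  ## no test-only compounds
  expect_true(all(sp$test$compound_id %in% tr_val$compound_id))
})

test_that("repurposing validation keeps the multi-code proportion and the seed fixes everything", {
  rec <- synthetic_records(100, 40)
  rec$smiles <- paste0(rec$smiles, seq_len(100))
  sp <- repurposing_split(rec, val_fraction = 0.1, seed = 9)
  expect_identical(nrow(sp$validation), 10L)
  expect_identical(sum(sp$validation$compound_id %in%
                         rec$compound_id[lengths(rec$atc_codes) > 1]), 4L)
  sp2 <- repurposing_split(rec, val_fraction = 0.1, seed = 9)
  expect_identical(sp$train$atc_codes, sp2$train$atc_codes)
  expect_identical(sp$assignments, sp2$assignments)
})

test_that("the assignments manifest matches the partition contents", {
  rec <- synthetic_records(30, 12)
  rec$smiles <- paste0(rec$smiles, seq_len(30))
  sp <- repurposing_split(rec, seed = 2)
  tr_val <- rbind(sp$train, sp$validation)
  for (i in seq_len(nrow(sp$assignments))) {
    row <- sp$assignments[i, ]
    part <- if (row$partition == "train") tr_val else sp$test
    expect_true(row$code %in%
                  part$atc_codes[[match(row$compound_id, part$compound_id)]])
  }
})

test_that("splits write a dataset CSV per partition plus a JSON manifest", {
  rec <- synthetic_records(20, 8)
  rec$smiles <- paste0(rec$smiles, seq_len(20))
  dir <- tempfile()
  write_split(repurposing_split(rec, seed = 4), dir)
  expect_true(all(file.exists(file.path(dir, c("train.csv", "validation.csv",
                                               "test.csv", "manifest.json")))))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$scenario, "repurposing")
  expect_identical(manifest$seed, 4L)
  back <- read_compound_table(file.path(dir, "train.csv"))
  expect_identical(nrow(back), nrow(rec) - 2L)  # minus validation draw
})
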