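test_that("a balanced 10-sample split yields one member per class per fold", {
  labels <- rep(c(1, 0), each = 5)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f, 2)
    expect_setequal(labels[f], c(0, 1))
  }
})

test_that("folds are disjoint, exhaustive, and stratified within one sample", {
  set.seed(2)
  labels <- sample(c("a", "b"), 83, TRUE, prob = c(0.3, 0.7))
  folds <- stratified_kfold(labels, k = 5, seed = 9)
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_along(labels))
  expect_equal(sum(duplicated(unlist(folds))), 0)
  global_a <- sum(labels == "a")
  for (f in folds) {
    expect_lte(abs(sum(labels[f] == "a") - global_a / 5), 1)
  }
})

test_that("splits are seed-deterministic and seed-sensitive", {
  labels <- rep(c(1, 0), 30)
  a <- stratified_kfold(labels, k = 5, seed = 4)
  b <- stratified_kfold(labels, k = 5, seed = 4)
  c <- stratified_kfold(labels, k = 5, seed = 5)
  expect_identical(a, b)
  expect_false(identical(lapply(a, I), lapply(c, I)))
})

test_that("undersized classes and degenerate k are rejected", {
  expect_error(stratified_kfold(c(1, 1, 1, 0), k = 2), "fewer than k")
  expect_error(stratified_kfold(rep(1, 10), k = 1), "at least 2")
})

test_that("fold assignments export matches the CV splits record-for-record", {
  ds <- tiny_dataset(10, seed = 8)
  fa <- fold_assignments(ds, stage = 1, runs = 2, k = 2, seed = 5)
  expect_equal(nrow(fa), 40)                      # every record, every run
  expect_equal(sort(unique(fa$run)), 1:2)
  for (r in 1:2) {
    sub <- fa[fa$run == r, ]
    expect_setequal(sub$id, ds$id)
    folds <- stratified_kfold(ds$stage1, k = 2, seed = 5 + r - 1)
    expect_setequal(sub$id[sub$fold == 1], ds$id[folds[[1]]])
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fold_assignments(ds, runs = 1, k = 2, seed = 1, path = tsv)
  expect_equal(names(utils::read.delim(tsv)), c("id", "run", "fold"))
})

test_that("one round of 2-fold CV returns a report per fold", {
  ds <- tiny_dataset(12, seed = 6)
  cv <- repeated_cv(ds, stage = 1, config = tiny_config(max_epochs = 2L),
                    runs = 1, k = 2, seed = 3)
  expect_equal(nrow(cv$folds), 2)
  expect_true(all(is.finite(cv$folds$Acc)))
  expect_true(cv$summary$mean[cv$summary$metric == "Acc"] >=
                min(cv$folds$Acc))
  expect_true(cv$summary$mean[cv$summary$metric == "Acc"] <=
                max(cv$folds$Acc))
  # summary means equal recomputation from the per-fold rows
  expect_equal(cv$summary$mean[cv$summary$metric == "MCC"],
               mean(cv$folds$MCC))
})
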