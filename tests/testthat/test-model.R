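test_that("default configuration reproduces the reference architecture", {
  cfg <- promkan_config()
  expect_equal(cfg$kresidual_blocks, 4L)
  expect_equal(cfg$encoder_count, 4L)
  expect_equal(cfg$heads, 4L)
  expect_equal(cfg$batch_size, 30L)
  expect_equal(cfg$seq_length, 81L)
  expect_equal(cfg$trunk_channels, 128L)
  expect_equal(cfg$branch_kernels, c(3L, 5L, 7L, 9L))
  m <- promkan_build(cfg, seed = 1)
  s <- summary(m)
  expect_equal(s$kresidual_blocks, 4L)
  expect_equal(s$encoder_count, 4L)
  expect_equal(s$heads, 4L)
  expect_error(promkan_config(trunk_channels = 126), "divisible")
})

test_that("a forward pass returns one probability per sequence, deterministically", {
  cfg <- tiny_config()
  m <- promkan_build(cfg, seed = 2)
  ds <- tiny_dataset(3, seed = 1)
  p1 <- predict(m, ds, type = "prob")
  expect_length(p1, 6)
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- predict(m, ds, type = "prob")
  expect_identical(p1, p2)
  expect_error(predict(m, simulate_promoters(2, seq_length = 40, motif_position = 11)),
               "length")
})

test_that("full-model gradients match central finite differences", {
  cfg <- tiny_config(seq_length = 12L)
  m <- promkan_build(cfg, seed = 3)
  set.seed(4)
  X <- array(stats::rnorm(3 * 12 * 7), c(3, 12, 7))
  y <- c(1, 0, 1)
  fw <- promkan:::model_fwd(m$params, X, "train", cfg)
  dp <- promkan:::reg_smooth_grad(y, fw$prob, cfg$epsilon, cfg$lambda)
  dscore <- dp * fw$prob * (1 - fw$prob)
  g <- promkan:::model_bwd(m$params, fw$cache, dscore)
  gvec <- unlist(promkan:::model_grads_aligned(g), use.names = FALSE)
  skel <- promkan:::model_trainable(m$params)
  theta <- unlist(skel, use.names = FALSE)
  loss_at <- function(vec) {
    pp <- promkan:::model_set_trainable(m$params, utils::relist(vec, skel))
    f <- promkan:::model_fwd(pp, X, "train", cfg)
    reg_smooth_loss(y, f$prob, cfg$epsilon, cfg$lambda)
  }
  set.seed(5)
  idx <- sample(length(theta), 25)
  h <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    num <- (loss_at(tp) - loss_at(tm)) / (2 * h)
    expect_equal(gvec[i], num, tolerance = 1e-4)
  }
})

test_that("training is reproducible and records finite losses", {
  ds <- tiny_dataset(10, seed = 2)
  cfg <- tiny_config(max_epochs = 1L)
  f1 <- promkan(ds, stage = 1, config = cfg, seed = 11)
  f2 <- promkan(ds, stage = 1, config = cfg, seed = 11)
  expect_equal(f1$history$train_loss, f2$history$train_loss)
  expect_true(all(is.finite(f1$history$train_loss)))
  expect_true(all(is.finite(f1$history$val_loss)))
  expect_true(f1$trained)
})

test_that("single-class or mislabeled training data is rejected", {
  ds <- tiny_dataset(10, seed = 3)
  only_pos <- ds[ds$stage1 == "promoter", ]
  expect_error(promkan(only_pos, stage = 1, config = tiny_config()),
               "both classes")
  # stage-2 training needs strength labels
  no_s2 <- ds
  no_s2$stage2 <- NA_character_
  expect_error(promkan(no_s2, stage = 2, config = tiny_config()), "too few")
})

test_that("two-stage routing partitions promoter calls into strengths", {
  cfg <- tiny_config()
  m1 <- promkan_build(cfg, stage = 1, seed = 21)
  m2 <- promkan_build(cfg, stage = 2, seed = 22)
  ds <- tiny_dataset(10, seed = 4)
  out <- predict_two_stage(m1, m2, ds)
  expect_equal(nrow(out), 20)
  is_prom <- out$stage1_label == "promoter"
  expect_true(all(is.na(out$stage2_label[!is_prom])))
  expect_true(all(out$stage2_label[is_prom] %in% c("strong", "weak")))
  expect_equal(sum(out$stage2_label %in% "strong") +
                 sum(out$stage2_label %in% "weak"), sum(is_prom))
  expect_true(all((out$stage1_prob >= 0.5) == is_prom))
  expect_error(predict_two_stage(m2, m1, ds), "stage-1")
})

test_that("checkpoints restore a model bit-compatibly", {
  ds <- tiny_dataset(8, seed = 5)
  fit <- promkan(ds, stage = 1, config = tiny_config(max_epochs = 2L),
                 seed = 31)
  f <- withr::local_tempfile(fileext = ".json")
  save_promkan(fit, f)
  back <- load_promkan(f)
  expect_equal(predict(back, ds), predict(fit, ds), tolerance = 1e-12)
  expect_equal(back$history$val_loss, fit$history$val_loss, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', bad)
  expect_error(load_promkan(bad), "not a promkan checkpoint")
})
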