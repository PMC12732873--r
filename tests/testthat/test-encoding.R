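test_that("one-hot uses the A/T/C/G column convention", {
  m <- encode_one_hot("ATCG")
  expect_equal(unclass(m), rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                 c(0, 0, 1, 0), c(0, 0, 0, 1)),
               ignore_attr = TRUE)
  m2 <- encode_one_hot("AAAA")
  expect_true(all(rowSums(m2) == 1))
  expect_equal(nrow(unique(unclass(m2))), 1)
})

test_that("NCP rows encode ring / amino / hydrogen-bond chemistry", {
  m <- encode_ncp("ACGT")
  expect_equal(unclass(m), rbind(c(1, 1, 1), c(0, 1, 0),
                                 c(1, 0, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
  # each chemical property splits the four bases two vs two
  expect_equal(colSums(unclass(m)), c(2, 2, 2), ignore_attr = TRUE)
})

test_that("encodings match per-symbol table lookup on random sequences", {
  oh_tab <- list(A = c(1, 0, 0, 0), T = c(0, 1, 0, 0),
                 C = c(0, 0, 1, 0), G = c(0, 0, 0, 1))
  ncp_tab <- list(A = c(1, 1, 1), C = c(0, 1, 0),
                  G = c(1, 0, 0), T = c(0, 0, 1))
  for (seed in 1:3) {
    s <- random_seq(500, seed)
    chars <- strsplit(s, "")[[1]]
    expect_equal(unclass(encode_one_hot(s)),
                 do.call(rbind, oh_tab[chars]), ignore_attr = TRUE)
    expect_equal(unclass(encode_ncp(s)),
                 do.call(rbind, ncp_tab[chars]), ignore_attr = TRUE)
  }
  s81 <- random_seq(81, 7)
  expect_equal(dim(encode_one_hot(s81)), c(81, 4))
  expect_equal(sum(encode_one_hot(s81)), 81)
})

test_that("hybrid is the exact [one-hot | NCP] concatenation", {
  s <- random_seq(60, 11)
  h <- encode_hybrid(s)
  expect_equal(dim(h), c(60, 7))
  expect_equal(unclass(h)[, 1:4], unclass(encode_one_hot(s)),
               ignore_attr = TRUE)
  expect_equal(unclass(h)[, 5:7], unclass(encode_ncp(s)),
               ignore_attr = TRUE)
  expect_equal(unclass(encode_hybrid("A")),
               matrix(c(1, 0, 0, 0, 1, 1, 1), 1), ignore_attr = TRUE)
})

test_that("argmax decoding inverts the encoding exactly", {
  for (seed in 1:5) {
    s <- random_seq(81, seed + 20)
    expect_identical(decode_sequence(encode_hybrid(s)), s)
    expect_identical(decode_sequence(encode_one_hot(s)), s)
  }
})

test_that("invalid symbols are rejected with their position", {
  expect_error(encode_one_hot("ACGN"), "position 4")
  expect_error(encode_ncp(""), "empty")
  expect_error(encode_hybrid("AXGT"), "'X'")
})

test_that("dataset encoding stacks per-record hybrid matrices", {
  ds <- tiny_dataset(3, seed = 5)
  X <- encode_dataset(ds)
  expect_equal(dim(X), c(6, 30, 7))
  expect_equal(X[2, , ], unclass(encode_hybrid(ds$seq[2])),
               ignore_attr = TRUE)
})
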