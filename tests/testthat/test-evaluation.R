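test_that("probability clipping follows the printed formula exactly", {
  expect_equal(clip_probabilities(0.5), 0.5)
  expect_equal(clip_probabilities(0), 1e-15)
  expect_equal(clip_probabilities(1), 1 - 1e-15)

  row <- clip_probabilities(matrix(c(1, 0, 0), 1, 3))
  expect_equal(as.numeric(row), c(1 - 1e-15, 1e-15, 1e-15))
  expect_false(sum(row) == 1)  # no renormalization, by design

  expect_error(clip_probabilities(c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(clip_probabilities(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("log loss matches its closed forms", {
  # perfect prediction: only the clipping constant contributes
  perfect <- prediction_set(c("a", "b"), c("w1", "w2"),
                            rbind(c(1, 0), c(0, 1)))
  truth <- truth_set(c("a", "b"), c("w1", "w2"))
  expect_lte(logloss(perfect, truth), 1e-12)

  # uniform rows over M = 5 classes
  uni <- prediction_set("a", sprintf("w%d", 1:5), matrix(0.2, 1, 5))
  expect_equal(logloss(uni, truth_set("a", "w3")), log(5), tolerance = 1e-12)

  # hand-checked two-image case
  p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.1, 0.8))
  preds <- prediction_set(c("a", "b"), c("w1", "w2", "w3"), p)
  tr <- truth_set(c("a", "b"), c("w1", "w3"))
  expect_equal(logloss(preds, tr), 0.289909, tolerance = 1e-6)
  expect_equal(logloss(preds, tr), -(log(0.7) + log(0.8)) / 2, tolerance = 1e-12)

  # zero mass on the true class costs -log(1e-15) ~ 34.5388
  zp <- prediction_set("a", c("w1", "w2"), matrix(c(1, 0), 1, 2))
  expect_equal(logloss(zp, truth_set("a", "w2")), -log(1e-15), tolerance = 1e-9)
  expect_equal(-log(1e-15), 34.5388, tolerance = 1e-4)
})

test_that("log loss equals a brute-force double loop on random instances", {
  for (case in 1:100) {
    set.seed(case)
    N <- sample(1:50, 1); M <- sample(2:20, 1)
    preds <- rand_prediction_set(N, M, seed = case)
    idx <- sample(M, N, replace = TRUE)
    truth <- truth_set(preds$names, preds$roster[idx])
    expect_lt(abs(logloss(preds, truth) - logloss_bruteforce(preds$p, idx)), 1e-12)
  }
})

test_that("moving mass off the true class never decreases the loss", {
  for (case in 1:30) {
    preds <- rand_prediction_set(8, 6, seed = 100 + case)
    truth <- rand_truth_for(preds, seed = case)
    base <- logloss(preds, truth)
    i <- sample(8, 1)
    j <- match(truth$identity[match(preds$names[i], truth$names)], preds$roster)
    p2 <- preds$p
    delta <- p2[i, j] * 0.5
    p2[i, j] <- p2[i, j] - delta
    others <- setdiff(seq_len(6), j)
    p2[i, others] <- p2[i, others] + delta / length(others)
    worse <- prediction_set(preds$names, preds$roster, p2)
    expect_gte(logloss(worse, truth), base)
  }
})

test_that("top-k accuracy ranks deterministically and monotonically", {
  preds <- rand_prediction_set(7, 6, seed = 3)
  truth <- rand_truth_for(preds, seed = 4)
  expect_equal(top_k_accuracy(preds, truth, 6), 1.0)

  onehot <- prediction_set(truth$names, preds$roster,
                           outer(match(truth$identity, preds$roster),
                                 seq_len(6), `==`) * 1)
  expect_equal(top_k_accuracy(onehot, truth, 1), 1.0)

  # truths ranked 1st, 3rd and 6th: top-5 captures two of three
  p <- rbind(c(0.5, 0.2, 0.1, 0.08, 0.07, 0.05),
             c(0.5, 0.2, 0.1, 0.08, 0.07, 0.05),
             c(0.5, 0.2, 0.1, 0.08, 0.07, 0.05))
  ranked <- prediction_set(c("a", "b", "c"), sprintf("w%d", 1:6), p)
  tr <- truth_set(c("a", "b", "c"), c("w1", "w3", "w6"))
  expect_equal(top_k_accuracy(ranked, tr, 5), 2 / 3)
  expect_equal(top_k_accuracy(ranked, tr, 1), 1 / 3)

  # monotone nondecreasing in k
  accs <- vapply(1:6, function(k) top_k_accuracy(preds, truth, k), numeric(1))
  expect_true(all(diff(accs) >= 0))

  # ties broken by ascending roster order
  tied <- prediction_set("a", c("w1", "w2"), matrix(c(0.5, 0.5), 1, 2))
  expect_equal(top_k_accuracy(tied, truth_set("a", "w1"), 1), 1.0)
  expect_equal(top_k_accuracy(tied, truth_set("a", "w2"), 1), 0.0)

  expect_error(top_k_accuracy(preds, truth, 0), "k")
  expect_error(top_k_accuracy(preds, truth, 7), "k")
})

test_that("metrics are invariant to roster permutations", {
  preds <- rand_prediction_set(10, 8, seed = 5)
  truth <- rand_truth_for(preds, seed = 6)
  set.seed(7)
  perm <- sample(8)
  shuffled <- prediction_set(preds$names, preds$roster[perm], preds$p[, perm])
  expect_equal(logloss(shuffled, truth), logloss(preds, truth), tolerance = 1e-12)
  for (k in c(1, 3, 5)) {
    expect_equal(top_k_accuracy(shuffled, truth, k), top_k_accuracy(preds, truth, k))
  }
})

test_that("submission files round-trip and are validated on read", {
  preds <- rand_prediction_set(12, 5, seed = 8)
  path <- tempfile(fileext = ".csv")
  write_submission(preds, path)
  expect_identical(readLines(path, n = 1),
                   paste(c("Image", preds$roster), collapse = ","))
  back <- read_submission(path, preds$roster)
  expect_lt(max(abs(back$p - preds$p)), 1e-12)

  # shuffled column order aligns back to the roster
  df <- read.csv(path, check.names = FALSE)
  df <- df[, c("Image", rev(preds$roster))]
  path2 <- tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE, quote = FALSE)
  back2 <- read_submission(path2, preds$roster)
  expect_lt(max(abs(back2$p - preds$p)), 1e-12)

  # a missing identity column is named in the error
  df3 <- df[, setdiff(names(df), "whale_002")]
  path3 <- tempfile(fileext = ".csv")
  write.csv(df3, path3, row.names = FALSE, quote = FALSE)
  expect_error(read_submission(path3, preds$roster), "whale_002")

  # malformed probabilities are rejected
  df4 <- read.csv(path, check.names = FALSE)
  df4$whale_001[2] <- "oops"
  path4 <- tempfile(fileext = ".csv")
  write.csv(df4, path4, row.names = FALSE, quote = FALSE)
  expect_error(read_submission(path4, preds$roster), "non-numeric|sum")

  df5 <- read.csv(path, check.names = FALSE)
  df5$whale_001 <- df5$whale_001 + 0.5
  path5 <- tempfile(fileext = ".csv")
  write.csv(df5, path5, row.names = FALSE, quote = FALSE)
  expect_error(read_submission(path5, preds$roster), "sum")
})

test_that("evaluation reports are internally consistent", {
  preds <- rand_prediction_set(15, 7, seed = 9)
  truth <- rand_truth_for(preds, seed = 10)
  rep <- eval_report(preds, truth)
  expect_equal(rep$N, 15)
  expect_equal(rep$M, 7)
  expect_gte(rep$logloss, 0)
  expect_lte(rep$top1, rep$top5)
  expect_equal(rep$top1, top_k_accuracy(preds, truth, 1))
  expect_error(logloss(preds, truth_set("zzz", "w1")), "missing")
})
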