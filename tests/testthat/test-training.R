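test_that("the stratified holdout obeys its counting contracts", {
  labels <- rep(sprintf("w%02d", 1:10), each = 10)
  plan <- split_holdout(labels, fraction = 0.1, seed = 1)
  expect_length(plan$validation, 10)
  expect_length(plan$train, 90)
  expect_length(intersect(plan$train, plan$validation), 0)
  expect_setequal(c(plan$train, plan$validation), seq_along(labels))

  expect_identical(plan, split_holdout(labels, fraction = 0.1, seed = 1))
  expect_false(identical(plan$validation,
                         split_holdout(labels, fraction = 0.1, seed = 2)$validation))

  # a single-image identity always lands in train
  lab2 <- c("solo", rep("busy", 19))
  for (seed in 1:20) {
    p <- split_holdout(lab2, fraction = 0.1, seed = seed)
    expect_true(1L %in% p$train)
  }

  expect_error(split_holdout(labels, fraction = 0), "fraction")
  expect_error(split_holdout(labels, fraction = 1), "fraction")
})

test_that("every multi-image identity stays represented in train", {
  set.seed(30)
  for (case in 1:100) {
    n_ids <- sample(3:12, 1)
    counts <- sample(1:8, n_ids, replace = TRUE)
    labels <- rep(sprintf("w%02d", seq_len(n_ids)), counts)
    plan <- split_holdout(labels, fraction = 0.1, seed = case)
    train_ids <- unique(labels[plan$train])
    multi <- sprintf("w%02d", which(counts >= 2))
    expect_true(all(multi %in% train_ids))
    expect_setequal(c(plan$train, plan$validation), seq_along(labels))
  }
})

test_that("training reduces the loss on a small synthetic set", {
  ds <- tiny_dataset(4, 5, size = c(96, 96), seed = 7)
  pol <- augmentation_policy(max_rotation = 5 * pi / 180, scale_range = c(0.95, 1.05),
                             color_strength = 0)
  net <- build_stage("roi", config = list(input_size = c(32, 32),
                                          widths = c(4, 4, 8, 8, 8), seed = 1))
  run <- train_stage(net, ds$records, pol, config = list(epochs = 8, seed = 2))
  expect_length(run$history, 8)
  expect_true(all(is.finite(run$history)))
  expect_lt(run$history[8], run$history[1])
})

test_that("the identity stage memorizes a tiny two-whale problem", {
  ds <- tiny_dataset(2, 10, size = c(96, 96), seed = 8)
  roster <- sort(unique(vapply(ds$records, `[[`, "", "identity_id")))
  net <- build_stage("identity", n_identities = 2,
                     config = list(input_size = c(48, 48), widths = rep(6, 11),
                                   seed = 3, roster = roster))
  pol <- augmentation_policy(max_rotation = 5 * pi / 180, scale_range = c(0.95, 1.05),
                             color_strength = 0.05)
  run <- train_stage(net, ds$records, pol,
                     config = list(epochs = 12, seed = 4,
                                   passport = passport_spec(c(48, 48))))
  pspec <- passport_spec(c(48, 48))
  passports <- lapply(ds$records, function(r) {
    unclass(warp_to_passport(r$image, r$keypoints, pspec))
  })
  truth <- truth_set(vapply(ds$records, `[[`, "", "source_name"),
                     vapply(ds$records, `[[`, "", "identity_id"))
  preds <- ensemble_predict(list(run$network), passports, names = truth$names)
  expect_equal(top_k_accuracy(preds, truth, 1), 1.0)
})

test_that("a zero-weight auxiliary head leaves training untouched", {
  ds <- tiny_dataset(2, 4, size = c(96, 96), seed = 9)
  roster <- sort(unique(vapply(ds$records, `[[`, "", "identity_id")))
  pol <- augmentation_policy(max_rotation = 0, scale_range = c(1, 1),
                             color_strength = 0, jitter = FALSE, color = FALSE)
  common <- list(input_size = c(48, 48), widths = rep(4, 11), seed = 5,
                 roster = roster)
  with_aux <- build_stage("identity", 2, c(common, list(aux_head = TRUE,
                                                        aux_weight = 0)))
  without <- build_stage("identity", 2, c(common, list(aux_head = FALSE)))
  cfg <- list(epochs = 3, seed = 6, passport = passport_spec(c(48, 48)))
  ra <- train_stage(with_aux, ds$records, pol, cfg)
  rb <- train_stage(without, ds$records, pol, cfg)
  expect_identical(ra$history, rb$history)
  expect_identical(ra$network$heads$primary$w, rb$network$heads$primary$w)
})

test_that("full-data finetuning is careful by construction", {
  ds <- tiny_dataset(3, 4, size = c(96, 96), seed = 10)
  plan <- split_holdout(ds, 0.25, seed = 1)
  pol <- augmentation_policy(max_rotation = 0, scale_range = c(1, 1),
                             color_strength = 0, jitter = FALSE, color = FALSE)
  roster <- sort(unique(vapply(ds$records, `[[`, "", "identity_id")))
  net <- build_stage("identity", 3,
                     config = list(input_size = c(48, 48), widths = rep(4, 11),
                                   seed = 7, roster = roster))
  run <- train_stage(net, ds$records[plan$train], pol,
                     config = list(epochs = 6, seed = 8,
                                   passport = passport_spec(c(48, 48))))

  # zero extra epochs: parameters unchanged
  same <- finetune_full(run, ds$records, pol, config = list(epochs = 0))
  expect_identical(same$network$layers, run$network$layers)

  # a finetune rate above the main rate draws a warning
  expect_warning(finetune_full(run, ds$records, pol,
                               config = list(epochs = 0, lr = 1)),
                 "smaller")

  # held-out cross-entropy does not get worse after folding the data back
  pspec <- passport_spec(c(48, 48))
  heldout_ce <- function(network) {
    recs <- ds$records[plan$validation]
    passports <- lapply(recs, function(r) {
      unclass(warp_to_passport(r$image, r$keypoints, pspec))
    })
    truth <- truth_set(vapply(recs, `[[`, "", "source_name"),
                       vapply(recs, `[[`, "", "identity_id"))
    logloss(ensemble_predict(list(network), passports, names = truth$names), truth)
  }
  before <- heldout_ce(run$network)
  tuned <- finetune_full(run, ds$records, pol,
                         config = list(epochs = 3,
                                       passport = pspec))
  expect_lte(heldout_ce(tuned$network), before + 1e-8)
  expect_error(finetune_full(list(), ds$records, pol), "checkpoint")
})

test_that("training histories are reproducible under fixed seeds", {
  ds <- tiny_dataset(2, 4, size = c(96, 96), seed = 11)
  pol <- augmentation_policy(max_rotation = 5 * pi / 180, scale_range = c(0.95, 1.05),
                             color_strength = 0)
  mk <- function() build_stage("roi", config = list(input_size = c(32, 32),
                                                    widths = c(4, 4, 8, 8, 8),
                                                    seed = 9))
  cfg <- list(epochs = 3, seed = 13)
  r1 <- train_stage(mk(), ds$records, pol, cfg)
  r2 <- train_stage(mk(), ds$records, pol, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$network$layers, r2$network$layers)
  r3 <- train_stage(mk(), ds$records, pol, list(epochs = 3, seed = 14))
  expect_false(identical(r1$history, r3$history))
})

test_that("diverging training reports the offending epoch", {
  ds <- tiny_dataset(2, 3, size = c(96, 96), seed = 12)
  net <- build_stage("roi", config = list(input_size = c(32, 32),
                                          widths = c(4, 4, 8, 8, 8), seed = 1))
  pol <- augmentation_policy(jitter = FALSE, color = FALSE)
  expect_error(
    train_stage(net, ds$records, pol,
                config = list(epochs = 4, optimizer = "sgd", lr = 1e9, seed = 2)),
    "epoch")
})

test_that("ensembles average member distributions exactly", {
  make_fixed <- function(probs, roster, seed) {
    net <- build_stage("identity", length(roster),
                       config = list(input_size = c(48, 48), widths = rep(4, 11),
                                     seed = seed, roster = roster,
                                     aux_head = FALSE))
    # zero the body's influence and pin the logits to log(probs)
    net$heads$primary$w[] <- 0
    net$heads$primary$b <- log(probs)
    net
  }
  roster <- c("a", "b")
  imgs <- list(array(0.5, c(48, 48, 3)))
  n1 <- make_fixed(c(0.8, 0.2), roster, 1)
  n2 <- make_fixed(c(0.4, 0.6), roster, 2)

  single <- ensemble_predict(list(n1), imgs)
  expect_equal(unname(single$p[1, ]), c(0.8, 0.2), tolerance = 1e-12)

  dup <- ensemble_predict(list(n1, n1, n1), imgs)
  expect_equal(dup$p, single$p, tolerance = 1e-12)

  avg <- ensemble_predict(list(n1, n2), imgs)
  expect_equal(unname(avg$p[1, ]), c(0.6, 0.4), tolerance = 1e-12)
  expect_true(all(abs(rowSums(avg$p) - 1) < 1e-6))

  # convexity: the ensemble never scores worse than its worst member
  tr <- truth_set(avg$names, "a")
  expect_lte(logloss(avg, tr),
             max(logloss(single, tr), logloss(ensemble_predict(list(n2), imgs), tr)))

  n3 <- make_fixed(c(0.5, 0.5), c("a", "c"), 3)
  expect_error(ensemble_predict(list(n1, n3), imgs), "roster")
  kp <- build_stage("keypoint", config = list(input_size = c(64, 64)))
  expect_error(ensemble_predict(list(kp), imgs), "identity-stage")
})
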