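#' Stage-wise training, retraining and ensembling
#'
#' Each stage is trained supervised on the synthetic records: the roi stage
#' regresses the head box in normalized frame coordinates from a downscaled
#' scene, the keypoint stage regresses the bonnet/blowhole positions from
#' the head crop, and the identity stage classifies passport photos with an
#' auxiliary connectivity target. A stratified holdout supports internal
#' validation; after validation the held-out images can be folded back with
#' a careful low-learning-rate finetune. Ensembles average member softmax
#' outputs.
#'
#' @name training
NULL

#' Stratified train/validation split
#'
#' Sets aside a fraction of the images for internal validation, stratified
#' by identity where possible: every identity with at least two images keeps
#' at least one in training (an unstratified split strands underrepresented
#' whales entirely in validation), and single-image identities always train.
#' The validation set has `round(fraction * N)` images whenever the
#' stratification constraints allow.
#'
#' @param dataset A `"whale_dataset"`, a list of `"annotated_image"`
#'   records, or a character vector of identity labels.
#' @param fraction Validation fraction in (0, 1); default 0.10.
#' @param seed Integer seed; the plan is deterministic given it.
#' @return A `"split_plan"`: list with integer `train` and `validation`
#'   indices (disjoint, covering all records), `fraction` and `seed`.
#' @export
split_holdout <- function(dataset, fraction = 0.1, seed = 1L) {
  labels <- dataset_labels(dataset)
  n <- length(labels)
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  goal <- round(fraction * n)
  by_id <- split(seq_len(n), labels)
  plan <- with_seed(seed, {
    shuffled <- lapply(by_id, function(ix) if (length(ix) > 1) sample(ix) else ix)
    k <- vapply(shuffled, function(ix) {
      ni <- length(ix)
      if (ni < 2) 0L else min(as.integer(round(fraction * ni)), ni - 1L)
    }, integer(1))
    # adjust per-identity counts to hit the global target where capacity allows
    diff <- goal - sum(k)
    ord <- order(-vapply(shuffled, length, integer(1)))
    while (diff != 0) {
      moved <- FALSE
      for (j in ord) {
        ni <- length(shuffled[[j]])
        if (diff > 0 && k[j] < ni - 1L) {
          k[j] <- k[j] + 1L; diff <- diff - 1L; moved <- TRUE
        } else if (diff < 0 && k[j] > 0L) {
          k[j] <- k[j] - 1L; diff <- diff + 1L; moved <- TRUE
        }
        if (diff == 0) break
      }
      if (!moved) break
    }
    val <- unlist(Map(function(ix, ki) if (ki > 0) ix[seq_len(ki)] else integer(0),
                      shuffled, as.list(k)), use.names = FALSE)
    sort(as.integer(val))
  })
  structure(list(train = setdiff(seq_len(n), plan), validation = plan,
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

dataset_labels <- function(dataset) {
  if (is.character(dataset)) return(dataset)
  recs <- if (inherits(dataset, "whale_dataset")) dataset$records else dataset
  vapply(recs, function(r) r$identity_id, character(1))
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d train / %d validation (fraction %.2f, seed %d)>\n",
              length(x$train), length(x$validation), x$fraction, x$seed))
  invisible(x)
}

# -- stage example construction ----------------------------------------

# Normalized-coordinate conventions: box edges are expressed as fractions of
# the frame (x / W); point coordinates as pixel-center fractions
# ((x + 0.5) / W), so they survive resizing exactly.

bbox_to_target <- function(bbox, hw) {
  c(bbox$x0 / hw[2], bbox$y0 / hw[1], bbox$x1 / hw[2], bbox$y1 / hw[1])
}

target_to_bbox <- function(t, hw) {
  x0 <- max(0, min(t[1], t[3]) * hw[2]); x1 <- min(hw[2], max(t[1], t[3]) * hw[2])
  y0 <- max(0, min(t[2], t[4]) * hw[1]); y1 <- min(hw[1], max(t[2], t[4]) * hw[1])
  if (x1 - x0 < 2) { x0 <- max(0, x0 - 1); x1 <- min(hw[2], x1 + 2) }
  if (y1 - y0 < 2) { y0 <- max(0, y0 - 1); y1 <- min(hw[1], y1 + 2) }
  bounding_box(x0, y0, x1, y1)
}

point_to_frac <- function(p, origin, chw) (p - origin + 0.5) / rev(chw)

frac_to_point <- function(f, origin, chw) f * rev(chw) - 0.5 + origin

# Crop a record around `bbox` and return the resized input plus the
# keypoint regression target in crop-fraction coordinates.
keypoint_example <- function(record, bbox, input_size) {
  crop <- crop_bbox(record$image, bbox)
  origin <- attr(crop, "origin")
  chw <- image_hw(crop)
  img <- resize_image(crop, input_size)
  tb <- point_to_frac(record$keypoints$bonnet, origin, chw)
  tw <- point_to_frac(record$keypoints$blowhole, origin, chw)
  list(input = img, target = c(tb, tw), origin = origin, chw = chw)
}

# Training-time crop generator for the keypoint stage: perturb the true
# head-axis endpoints with isotropic noise whose scale spans the error of a
# rough region-of-interest estimate down to that of a refined one, then
# build the crop exactly as inference does (kp_crop_box). Keeps the training
# and inference crop distributions identical at every refinement level.
noisy_kp_crop <- function(record, hw) {
  kp <- record$keypoints
  hl <- sqrt(sum((kp$blowhole - kp$bonnet)^2))
  sd_frac <- exp(runif(1, log(0.02), log(0.30)))
  p1 <- kp$bonnet + rnorm(2, 0, sd_frac * hl)
  p2 <- kp$blowhole + rnorm(2, 0, sd_frac * hl)
  kp_crop_box(p1, p2, hw)
}

# Small similarity jitter of an image about its center; returns the image
# and the forward transform (for mapping point targets).
center_jitter <- function(img, policy) {
  hw <- image_hw(img)
  theta <- runif(1, -policy$max_rotation, policy$max_rotation)
  s <- runif(1, policy$scale_range[1], policy$scale_range[2])
  ctr <- c((hw[2] - 1) / 2, (hw[1] - 1) / 2)
  tf <- similarity_transform(s, theta, ctr - s * as.numeric(rot_mat(theta) %*% ctr))
  list(image = warp_similarity(img, tf, hw, pad = 0), tf = tf)
}

# Build one training example for a stage. `aug_seed = NULL` disables
# augmentation (used for evaluation-time inputs).
stage_example <- function(record, stage, net_input, passport, policy, aug_seed) {
  if (stage == "roi") {
    # The head box is regressed through its two axis endpoints (bonnet,
    # blowhole) in frame-fraction coordinates: point targets transform
    # exactly under rotation jitter, where axis-aligned corners would
    # systematically inflate the box at diagonal headings. The box itself
    # is reconstructed geometrically (see endpoints_to_bbox).
    img <- resize_image(record$image, net_input)
    hw <- image_hw(record$image)
    pts <- rbind(record$keypoints$bonnet, record$keypoints$blowhole)
    frac <- sweep(pts + 0.5, 2, c(hw[2], hw[1]), "/")
    if (!is.null(aug_seed) && policy$jitter) {
      with_seed(aug_seed, {
        j <- center_jitter(img, policy)
        img <- j$image
        px <- sweep(frac, 2, c(net_input[2], net_input[1]), "*") - 0.5
        mp <- apply_transform(j$tf, px) + 0.5
        frac <- sweep(mp, 2, c(net_input[2], net_input[1]), "/")
      })
    }
    list(input = img, target = c(frac[1, ], frac[2, ]))
  } else if (stage == "keypoint") {
    if (is.null(aug_seed)) {
      bb <- kp_crop_box(record$keypoints$bonnet, record$keypoints$blowhole,
                        image_hw(record$image))
      ex <- keypoint_example(record, bb, net_input)
      list(input = ex$input, target = ex$target)
    } else {
      with_seed(aug_seed, {
        bb <- noisy_kp_crop(record, image_hw(record$image))
        ex <- keypoint_example(record, bb, net_input)
        img <- ex$input; target <- ex$target
        if (policy$jitter) {
          j <- center_jitter(img, policy)
          pts <- rbind(target[1:2], target[3:4])
          pts <- sweep(pts, 2, c(net_input[2], net_input[1]), "*") - 0.5
          mp <- apply_transform(j$tf, pts) + 0.5
          mp <- sweep(mp, 2, c(net_input[2], net_input[1]), "/")
          img <- j$image; target <- c(mp[1, ], mp[2, ])
        }
        list(input = img, target = target)
      })
    }
  } else { # identity: input is the passport photo, precomputed by caller
    img <- passport$img
    if (!is.null(aug_seed)) {
      with_seed(aug_seed, {
        if (policy$jitter) img <- center_jitter(img, policy)$image
        if (policy$color && policy$color_strength > 0) {
          # principal-component color shift using the passport's cached
          # RGB eigenbasis (the jitter does not change it materially)
          alpha <- rnorm(3, 0, policy$color_strength)
          shift <- as.numeric(passport$eig$vectors %*% (alpha * passport$eig$values))
          for (ch in 1:3) img[, , ch] <- clamp01(img[, , ch] + shift[ch])
        }
      })
    }
    list(input = img, target = NULL)
  }
}

# -- training loop ------------------------------------------------------

#' Train one pipeline stage
#'
#' Runs seeded SGD with momentum over the records. Regression stages (roi,
#' keypoint) minimize mean squared error on normalized coordinates; the
#' identity stage minimizes softmax cross-entropy plus
#' `aux_weight` x binary cross-entropy on the connectivity head. Training
#' augmentation follows `policy` (pose jitter for all stages, color
#' perturbation for the identity stage).
#'
#' @param network A `"whale_network"` from [build_stage()].
#' @param records List of `"annotated_image"` records (or a
#'   `"whale_dataset"`).
#' @param policy An [augmentation_policy()]; use magnitudes of 0 to disable.
#' @param config List: `epochs`, `optimizer` (`"adam"`, the default, or
#'   `"sgd"` with momentum), `lr` (default 2e-3 for Adam), `momentum` (0.9),
#'   `batch_size` (32),
#'   `seed` (1), `passport` (a [passport_spec()], identity stage),
#'   `passports` (optional list of precomputed passport images for the
#'   identity stage, e.g. produced from predicted keypoints),
#'   `checkpoint` (optional RDS path), `verbose`.
#' @return A `"train_run"`: list with the trained `network`, per-epoch
#'   `history` of mean losses, `stage`, `config`.
#' @export
train_stage <- function(network, records, policy = augmentation_policy(),
                        config = list()) {
  stopifnot(inherits(network, "whale_network"))
  if (inherits(records, "whale_dataset")) records <- records$records
  cfg <- list(epochs = config$epochs %||% 20L,
              optimizer = config$optimizer %||% "adam",
              lr = config$lr %||% (if ((config$optimizer %||% "adam") == "adam") 2e-3 else 0.05),
              momentum = config$momentum %||% 0.9,
              batch_size = config$batch_size %||% 32L,
              seed = config$seed %||% 1L,
              passport = config$passport %||% passport_spec(c(96, 96)),
              checkpoint = config$checkpoint, verbose = isTRUE(config$verbose))
  stage <- network$stage
  n <- length(records)
  if (n < 1) stop("no training records", call. = FALSE)
  net_input <- network$spec$input_size

  passports <- NULL
  class_idx <- conn <- NULL
  if (stage == "identity") {
    # Passport inputs: supplied by the caller (e.g. generated from predicted
    # keypoints, so training matches the automatic chain) or computed from
    # the annotated keypoints.
    imgs <- config$passports %||% lapply(records, function(r) {
      unclass(warp_to_passport(r$image, r$keypoints, cfg$passport))
    })
    passports <- lapply(imgs, function(img) {
      list(img = img, eig = eigen(stats::cov(matrix(img, ncol = 3L)),
                                  symmetric = TRUE))
    })
    labels <- dataset_labels(records)
    unknown <- setdiff(labels, network$roster)
    if (length(unknown)) {
      stop("records contain identities outside the network roster: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    class_idx <- match(labels, network$roster)
    conn <- vapply(records, function(r) as.numeric(r$connected), numeric(1))
  }

  opt_state <- if (cfg$optimizer == "adam") init_adam(network)
               else zero_like_grads(network)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    # step decay sharpens the regression stages' final precision
    lr_ep <- cfg$lr * if (ep > 0.85 * cfg$epochs) 0.1
                      else if (ep > 0.6 * cfg$epochs) 0.3 else 1
    ord <- with_seed(mix_seed(cfg$seed, ep), sample.int(n))
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      B <- length(idx)
      inputs <- vector("list", B)
      targets <- matrix(0, 4, B)
      for (bi in seq_len(B)) {
        i <- idx[bi]
        ex <- stage_example(records[[i]], stage, net_input,
                            if (is.null(passports)) NULL else passports[[i]], policy,
                            aug_seed = mix_seed(cfg$seed, ep * 100000L + i))
        inputs[[bi]] <- ex$input
        if (!is.null(ex$target)) targets[, bi] <- ex$target
      }
      x <- normalize_batch(stack_images(inputs))
      fwd <- net_forward_cached(network, x)
      if (stage == "identity") {
        p <- softmax_cols(fwd$head_z$primary)
        yi <- class_idx[idx]
        ll <- -mean(log(pmax(p[cbind(yi, seq_len(B))], 1e-12)))
        Y <- matrix(0, nrow(p), B); Y[cbind(yi, seq_len(B))] <- 1
        d <- list(primary = (p - Y) / B)
        loss <- ll
        if (!is.null(network$heads$connectivity)) {
          a <- sigmoid(fwd$head_z$connectivity)
          yc <- conn[idx]
          bce <- -mean(yc * log(pmax(a, 1e-12)) + (1 - yc) * log(pmax(1 - a, 1e-12)))
          loss <- loss + network$aux_weight * bce
          d$connectivity <- network$aux_weight * (a - matrix(yc, 1, B)) / B
        }
      } else {
        z <- fwd$head_z$primary
        loss <- mean((z - targets)^2)
        d <- list(primary = 2 * (z - targets) / length(z))
      }
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at epoch %d (non-finite loss)", ep),
             call. = FALSE)
      }
      grads <- net_backward(network, fwd, d)
      if (cfg$optimizer == "adam") {
        upd <- adam_update(network, opt_state, grads, lr_ep)
        network <- upd$net; opt_state <- upd$state
      } else {
        upd <- sgd_update(network, opt_state, grads, lr_ep, cfg$momentum)
        network <- upd$net; opt_state <- upd$vel
      }
      ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
    }
    history[ep] <- ep_loss / ep_n
    if (cfg$verbose) {
      message(sprintf("[%s] epoch %d/%d loss %.5f", stage, ep, cfg$epochs, history[ep]))
    }
  }
  if (!is.null(cfg$checkpoint)) saveRDS(network, cfg$checkpoint)
  structure(list(network = network, stage = stage, history = history,
                 epochs = cfg$epochs, config = cfg),
            class = "train_run")
}

#' @export
print.train_run <- function(x, ...) {
  cat(sprintf("<train_run %s: %d epochs, final loss %.5f>\n",
              x$stage, x$epochs, if (x$epochs) x$history[x$epochs] else NA))
  invisible(x)
}

#' Careful full-data retraining
#'
#' After internal validation, the held-out images are folded back and
#' training continues on all records at a much smaller learning rate
#' (default one tenth of the main rate), for a short epoch budget, to pick
#' up underrepresented whales without overfitting.
#'
#' @param run A prior `"train_run"` (or a `"whale_network"` plus `lr` in
#'   `config`).
#' @param records The full record list.
#' @param policy An [augmentation_policy()].
#' @param config Overrides: `epochs` (default 3), `lr` (default
#'   `0.1 * main lr`), others as [train_stage()].
#' @return A `"train_run"` continuing from the prior parameters.
#' @export
finetune_full <- function(run, records, policy = augmentation_policy(),
                          config = list()) {
  if (inherits(run, "whale_network")) {
    run <- structure(list(network = run, stage = run$stage, history = numeric(0),
                          epochs = 0L, config = list(lr = config$main_lr %||% 0.05)),
                     class = "train_run")
  }
  if (!inherits(run, "train_run") || is.null(run$network)) {
    stop("`run` must carry a trained network checkpoint", call. = FALSE)
  }
  main_lr <- run$config$lr %||% 0.05
  cfg <- config
  cfg$epochs <- config$epochs %||% 3L
  cfg$lr <- config$lr %||% (0.1 * main_lr)
  if (cfg$lr > main_lr) {
    warning(sprintf("finetune learning rate %.4g exceeds the main rate %.4g; retraining on all data usually needs a smaller one",
                    cfg$lr, main_lr))
  }
  cfg$passport <- config$passport %||% run$config$passport
  cfg$passports <- config$passports
  cfg$seed <- config$seed %||% mix_seed(run$config$seed %||% 1L, 77L)
  if (cfg$epochs == 0L) {
    out <- run
    out$config <- utils::modifyList(run$config, cfg)
    return(out)
  }
  out <- train_stage(run$network, records, policy, cfg)
  out$history <- c(run$history, out$history)
  out
}

#' Average identity predictions across an ensemble
#'
#' Several similar networks (differing only in their seeds) are queried and
#' their softmax outputs averaged arithmetically; a mean of distributions is
#' again a distribution, so rows still sum to 1.
#'
#' @param networks List of identity-stage `"whale_network"` objects sharing
#'   one roster (a single network is allowed).
#' @param images Passport-photo batch as in [nn_forward()].
#' @param names Optional image names for the resulting prediction set.
#' @return A [prediction_set()] with the averaged probability matrix.
#' @export
ensemble_predict <- function(networks, images, names = NULL) {
  if (inherits(networks, "whale_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1)
  roster <- networks[[1]]$roster
  for (nt in networks) {
    if (!inherits(nt, "whale_network") || nt$stage != "identity") {
      stop("all ensemble members must be identity-stage networks", call. = FALSE)
    }
    if (!identical(nt$roster, roster)) {
      stop("ensemble members disagree on the identity roster", call. = FALSE)
    }
  }
  acc <- NULL
  for (nt in networks) {
    p <- nn_forward(nt, images)$probs
    acc <- if (is.null(acc)) p else acc + p
  }
  p <- acc / length(networks)
  if (is.null(names)) names <- sprintf("img_%04d", seq_len(nrow(p)))
  prediction_set(names, roster, p)
}
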