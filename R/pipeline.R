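#' End-to-end identification pipeline
#'
#' [whale_id_fit()] trains the full chain on an annotated dataset:
#' region-of-interest localization on downscaled scenes, keypoint
#' localization on head crops, passport normalization, and ensemble identity
#' classification with an auxiliary connectivity head. The fitted object
#' predicts identities for raw images with no manual input: predicted box ->
#' crop -> predicted keypoints -> passport photo -> averaged softmax.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Nested configuration for generator, geometry, augmentation, stages and
#' training. Any part can be overridden by passing a partial list to
#' [whale_id_fit()] or by editing the returned list.
#'
#' @param seed Global seed from which all stage seeds derive.
#' @return A nested configuration list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    generator = list(n_ids = 25L, images_per_id = 30L,
                     image_size = c(192L, 192L), noise_level = 0.1),
    passport = list(out_size = c(96L, 96L)),
    augmentation = list(max_rotation_deg = 10, scale_lo = 0.9, scale_hi = 1.1,
                        color_strength = 0.1, jitter = TRUE, color = TRUE),
    split = list(fraction = 0.1),
    roi = list(input_size = c(64L, 64L), widths = stage_default_widths("roi"),
               epochs = 50L, lr = 2e-3, batch_size = 32L, n_members = 1L,
               # whales appear at every heading, so the localization stage
               # jitters over the full circle
               augmentation = list(max_rotation_deg = 180,
                                   scale_lo = 0.85, scale_hi = 1.15)),
    keypoint = list(input_size = c(64L, 64L),
                    widths = stage_default_widths("keypoint"), n_pools = 4L,
                    epochs = 40L, lr = 2e-3, batch_size = 32L, n_members = 2L,
                    refine_passes = 2L,
                    augmentation = list(max_rotation_deg = 12,
                                        scale_lo = 0.9, scale_hi = 1.1)),
    identity = list(widths = stage_default_widths("identity"),
                    epochs = 18L, lr = 2e-3, batch_size = 32L, n_members = 3L,
                    aux_head = TRUE, aux_weight = 0.2,
                    passport_source = "predicted"),
    finetune = list(epochs = 1L, lr_factor = 0.1)
  ), class = "run_config")
}

# Stage policies: the global augmentation block, overridden by any
# per-stage `augmentation` entries; color perturbation only for the
# identity stage.
config_policy <- function(config, stage = NULL) {
  a <- config$augmentation
  if (!is.null(stage) && !is.null(config[[stage]]$augmentation)) {
    a <- utils::modifyList(a, config[[stage]]$augmentation)
  }
  augmentation_policy(max_rotation = a$max_rotation_deg * pi / 180,
                      scale_range = c(a$scale_lo, a$scale_hi),
                      color_strength = a$color_strength,
                      jitter = isTRUE(a$jitter),
                      color = identical(stage, "identity") && isTRUE(a$color))
}

config_passport <- function(config) passport_spec(config$passport$out_size)

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  out <- utils::modifyList(base, override)
  structure(out, class = "run_config")
}

# -- prediction chaining ------------------------------------------------

bbox_iou <- function(a, b) {
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

record_images <- function(newdata) {
  if (inherits(newdata, "whale_dataset")) newdata <- newdata$records
  if (inherits(newdata, "annotated_image")) newdata <- list(newdata)
  lapply(newdata, function(r) if (inherits(r, "annotated_image")) r$image else r)
}

# Reconstruct an axis-aligned head box from predicted head-axis endpoints
# (pixels). `along` expands past each endpoint; `across` covers the head's
# lateral half-width; both are fractions of the endpoint distance and default
# to the generator's head geometry (half-width ~0.58 head lengths, +10%
# margin).
endpoints_to_bbox <- function(p1, p2, hw, along = 0.6, across = 0.677) {
  d <- p1 - p2
  cx <- (p1[1] + p2[1]) / 2; cy <- (p1[2] + p2[2]) / 2
  half_x <- along * abs(d[1]) + across * abs(d[2])
  half_y <- along * abs(d[2]) + across * abs(d[1])
  len <- sqrt(sum(d^2))
  half_x <- max(half_x, 0.2 * len, 2); half_y <- max(half_y, 0.2 * len, 2)
  bounding_box(max(0, cx - half_x), max(0, cy - half_y),
               min(hw[2], cx + half_x), min(hw[1], cy + half_y))
}

# Scene-scale head-axis endpoint estimates (pixels), ensemble-averaged.
roi_endpoints <- function(networks, newdata) {
  if (inherits(networks, "whale_network")) networks <- list(networks)
  imgs <- record_images(newdata)
  input <- networks[[1]]$spec$input_size
  small <- lapply(imgs, resize_image, out_size = input)
  out <- vector("list", length(imgs))
  for (start in seq(1, length(imgs), by = 32L)) {
    idx <- start:min(start + 31L, length(imgs))
    batch <- stack_images(small[idx])
    acc <- 0
    for (nt in networks) acc <- acc + nn_forward(nt, batch)$endpoints
    ep <- acc / length(networks)
    for (k in seq_along(idx)) {
      hw <- image_hw(imgs[[idx[k]]])
      out[[idx[k]]] <- list(p1 = ep[k, 1:2] * c(hw[2], hw[1]) - 0.5,
                            p2 = ep[k, 3:4] * c(hw[2], hw[1]) - 0.5,
                            hw = hw)
    }
  }
  out
}

#' Predict head bounding boxes for full scenes
#'
#' Downscales each scene to the network input, averages the normalized
#' head-axis endpoints across ensemble members, and reconstructs the
#' axis-aligned head box at scene resolution.
#'
#' @param networks One roi-stage network or a list of them.
#' @param newdata Images, annotated records, or a `"whale_dataset"`.
#' @return List of [bounding_box()] objects in scene coordinates.
#' @export
predict_boxes <- function(networks, newdata) {
  eps <- roi_endpoints(networks, newdata)
  lapply(eps, function(e) endpoints_to_bbox(e$p1, e$p2, e$hw))
}

#' Predict head keypoints inside given boxes
#'
#' Crops each scene to its box, resizes the crop to the network input,
#' averages normalized coordinates over members, and maps the points back
#' to scene coordinates.
#'
#' @param networks One keypoint-stage network or a list of them.
#' @param newdata Images, annotated records, or a `"whale_dataset"`.
#' @param boxes List of [bounding_box()] per image (e.g. from
#'   [predict_boxes()]).
#' @return List of [keypoint_pair()] objects in scene coordinates.
#' @export
predict_keypoints <- function(networks, newdata, boxes) {
  if (inherits(networks, "whale_network")) networks <- list(networks)
  imgs <- record_images(newdata)
  stopifnot(length(boxes) == length(imgs))
  input <- networks[[1]]$spec$input_size
  crops <- vector("list", length(imgs))
  meta <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    crop <- crop_bbox(imgs[[i]], boxes[[i]])
    meta[[i]] <- list(origin = attr(crop, "origin"), chw = image_hw(crop))
    crops[[i]] <- resize_image(crop, input)
  }
  out <- vector("list", length(imgs))
  for (start in seq(1, length(imgs), by = 32L)) {
    idx <- start:min(start + 31L, length(imgs))
    batch <- stack_images(crops[idx])
    acc <- 0
    for (nt in networks) acc <- acc + nn_forward(nt, batch)$keypoints
    kp <- acc / length(networks)
    for (k in seq_along(idx)) {
      i <- idx[k]
      bon <- frac_to_point(kp[k, 1:2], meta[[i]]$origin, meta[[i]]$chw)
      blo <- frac_to_point(kp[k, 3:4], meta[[i]]$origin, meta[[i]]$chw)
      if (all(bon == blo)) blo <- blo + c(0, 1e-6)  # degenerate regression output
      out[[i]] <- keypoint_pair(bon, blo)
    }
  }
  out
}

# Crop construction shared by keypoint training and inference: all keypoint
# crops are endpoints_to_bbox(estimated axis) with these factors, so the
# stage always sees the crop distribution it was trained on.
KP_CROP_ALONG <- 0.75
KP_CROP_ACROSS <- 0.85

kp_crop_box <- function(p1, p2, hw) {
  endpoints_to_bbox(p1, p2, hw, along = KP_CROP_ALONG, across = KP_CROP_ACROSS)
}

# Rough scene-scale endpoints -> keypoints on the crop -> iteratively
# re-crop around the estimated head axis and run the keypoint stage again.
# Every pass sees a crop drawn from the same generator as its training
# examples; later passes are much better centered, so they sharpen the
# estimate at the cost of one forward pass each.
chain_predict_keypoints <- function(roi_nets, kp_nets, newdata, boxes = NULL,
                                    passes = 2L) {
  imgs <- record_images(newdata)
  crop <- if (is.null(boxes)) {
    eps <- roi_endpoints(roi_nets, newdata)
    lapply(eps, function(e) kp_crop_box(e$p1, e$p2, e$hw))
  } else {
    boxes
  }
  kps <- predict_keypoints(kp_nets, newdata, crop)
  for (p in seq_len(passes)) {
    crop <- lapply(seq_along(kps), function(i) {
      kp_crop_box(kps[[i]]$bonnet, kps[[i]]$blowhole, image_hw(imgs[[i]]))
    })
    kps <- predict_keypoints(kp_nets, newdata, crop)
  }
  kps
}

passports_from_keypoints <- function(newdata, keypoints, pspec) {
  imgs <- record_images(newdata)
  lapply(seq_along(imgs), function(i) {
    unclass(warp_to_passport(imgs[[i]], keypoints[[i]], pspec))
  })
}

# -- the fitted pipeline object ----------------------------------------

#' Fit the full identification pipeline
#'
#' Trains the three convolutional stages on the training part of a
#' stratified holdout split, then (optionally) folds the held-out images
#' back in with a low-learning-rate finetune of every stage. Identity
#' classification uses an ensemble of `config$identity$n_members` networks
#' differing only in their seeds.
#'
#' @param dataset A `"whale_dataset"` (from [simulate_whale_dataset()] or
#'   [load_dataset()]) or a list of `"annotated_image"` records.
#' @param config A `"run_config"`, or a partial list merged over
#'   [default_run_config()].
#' @param finetune Fold the validation images back with a careful finetune
#'   (default `TRUE`).
#' @param verbose Print per-stage progress.
#' @return An object of class `"whale_id"` with elements `stages` (lists of
#'   trained networks per stage), `roster`, `split`, `passport`, `config`,
#'   `history` and `timings`.
#' @export
whale_id_fit <- function(dataset, config = default_run_config(),
                         finetune = TRUE, verbose = FALSE) {
  config <- merge_config(default_run_config(), unclass(config))
  records <- if (inherits(dataset, "whale_dataset")) dataset$records else dataset
  labels <- dataset_labels(records)
  roster <- sort(unique(labels))
  if (length(roster) < 2) stop("need at least 2 identities to fit", call. = FALSE)
  split <- split_holdout(labels, config$split$fraction, mix_seed(config$seed, 11L))
  train_recs <- records[split$train]
  pspec <- config_passport(config)

  stages <- list()
  history <- list()
  timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))

  train_members <- function(stage, n_members, scfg, policy, base_seed,
                            passports_all = NULL) {
    lapply(seq_len(n_members), function(m) {
      t0 <- proc.time()[3]
      net <- build_stage(stage, n_identities = length(roster),
                         config = list(input_size = scfg$input_size %||%
                                         config$passport$out_size,
                                       widths = scfg$widths,
                                       n_pools = scfg$n_pools,
                                       seed = mix_seed(base_seed, m),
                                       aux_head = scfg$aux_head %||% FALSE,
                                       aux_weight = scfg$aux_weight %||% 0.2,
                                       roster = if (stage == "identity") roster))
      run <- train_stage(net, train_recs, policy,
                         config = list(epochs = scfg$epochs, lr = scfg$lr,
                                       batch_size = scfg$batch_size %||% 32L,
                                       seed = mix_seed(base_seed, 100L + m),
                                       passport = pspec,
                                       passports = passports_all[split$train]))
      if (finetune && config$finetune$epochs > 0) {
        run <- finetune_full(run, records, policy,
                             config = list(epochs = config$finetune$epochs,
                                           lr = scfg$lr * config$finetune$lr_factor,
                                           batch_size = scfg$batch_size %||% 32L,
                                           passport = pspec,
                                           passports = passports_all,
                                           seed = mix_seed(base_seed, 200L + m)))
      }
      say("trained %s member %d/%d in %.1fs (final loss %.5f)", stage, m,
          n_members, proc.time()[3] - t0, run$history[length(run$history)])
      run
    })
  }

  t0 <- proc.time()[3]
  runs <- train_members("roi", config$roi$n_members, config$roi,
                        config_policy(config, "roi"), mix_seed(config$seed, 301L))
  stages$roi <- lapply(runs, `[[`, "network")
  history$roi <- lapply(runs, `[[`, "history")
  timings["roi"] <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  runs <- train_members("keypoint", config$keypoint$n_members, config$keypoint,
                        config_policy(config, "keypoint"), mix_seed(config$seed, 302L))
  stages$keypoint <- lapply(runs, `[[`, "network")
  history$keypoint <- lapply(runs, `[[`, "history")
  timings["keypoint"] <- proc.time()[3] - t0

  # Passports for identity training come from the predicted chain by
  # default, so the classifier is trained on the same alignment errors it
  # will see at prediction time; the annotated keypoints are the fallback.
  passports_all <- NULL
  if ((config$identity$passport_source %||% "predicted") == "predicted") {
    kps <- chain_predict_keypoints(stages$roi, stages$keypoint, records,
                                   passes = config$keypoint$refine_passes %||% 2L)
    passports_all <- passports_from_keypoints(records, kps, pspec)
  }

  t0 <- proc.time()[3]
  runs <- train_members("identity", config$identity$n_members, config$identity,
                        config_policy(config, "identity"), mix_seed(config$seed, 303L),
                        passports_all = passports_all)
  stages$identity <- lapply(runs, `[[`, "network")
  history$identity <- lapply(runs, `[[`, "history")
  timings["identity"] <- proc.time()[3] - t0

  structure(list(stages = stages, roster = roster, split = split,
                 passport = pspec, config = config, history = history,
                 timings = timings, n_train = length(train_recs),
                 n_records = length(records)),
            class = "whale_id")
}

#' @export
print.whale_id <- function(x, ...) {
  cat(sprintf("Whale identification pipeline (%d identities)\n", length(x$roster)))
  cat(sprintf("  stages: roi x%d, keypoint x%d, identity x%d (ensemble)\n",
              length(x$stages$roi), length(x$stages$keypoint),
              length(x$stages$identity)))
  cat(sprintf("  passport: %d x %d, bonnet (%.0f, %.0f), blowhole (%.0f, %.0f)\n",
              x$passport$out_size[1], x$passport$out_size[2],
              x$passport$bonnet[1], x$passport$bonnet[2],
              x$passport$blowhole[1], x$passport$blowhole[2]))
  cat(sprintf("  trained on %d of %d records (%.0f%% holdout)\n", x$n_train,
              x$n_records, 100 * x$split$fraction))
  invisible(x)
}

#' @export
summary.whale_id <- function(object, ...) {
  print(object)
  for (st in names(object$history)) {
    h <- object$history[[st]][[1]]
    cat(sprintf("  %s: %d epochs, loss %.5f -> %.5f\n", st, length(h),
                h[1], h[length(h)]))
  }
  cat(sprintf("  training time: %s\n",
              paste(sprintf("%s %.0fs", names(object$timings), object$timings),
                    collapse = ", ")))
  invisible(object)
}

#' @export
plot.whale_id <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (st in names(x$history)) {
    hs <- x$history[[st]]
    ylim <- range(unlist(hs))
    graphics::plot(hs[[1]], type = "l", log = "y", xlab = "epoch",
                   ylab = "loss", main = st, ylim = ylim)
    if (length(hs) > 1) {
      for (m in 2:length(hs)) graphics::lines(hs[[m]], col = m)
    }
  }
  invisible(x)
}

#' Predict identities for new images
#'
#' Runs the fully automatic chain: predicted head box, predicted keypoints,
#' passport normalization, ensemble-averaged identity probabilities. Ground
#' truth can be injected at either stage boundary to isolate the stages.
#'
#' @param object A fitted `"whale_id"`.
#' @param newdata Images, annotated records, or a `"whale_dataset"`.
#' @param use_gt_boxes,use_gt_keypoints Inject ground-truth annotations
#'   (requires annotated records).
#' @param details Also return the intermediate boxes, keypoints and
#'   passports.
#' @param ... Unused.
#' @return A [prediction_set()] (or, with `details = TRUE`, a list with
#'   `predictions`, `boxes`, `keypoints`, `passports`).
#' @export
predict.whale_id <- function(object, newdata, use_gt_boxes = FALSE,
                             use_gt_keypoints = FALSE, details = FALSE, ...) {
  recs <- if (inherits(newdata, "whale_dataset")) newdata$records else newdata
  if (inherits(recs, "annotated_image")) recs <- list(recs)
  annotated <- all(vapply(recs, inherits, logical(1), "annotated_image"))
  if ((use_gt_boxes || use_gt_keypoints) && !annotated) {
    stop("ground-truth injection requires annotated records", call. = FALSE)
  }
  nms <- if (annotated) vapply(recs, `[[`, "", "source_name")
         else sprintf("img_%04d", seq_along(recs))
  boxes <- if (use_gt_boxes) lapply(recs, `[[`, "bbox")
           else predict_boxes(object$stages$roi, recs)
  if (use_gt_keypoints) {
    kps <- lapply(recs, `[[`, "keypoints")
  } else {
    kps <- chain_predict_keypoints(
      object$stages$roi, object$stages$keypoint, recs,
      boxes = if (use_gt_boxes) boxes,
      passes = object$config$keypoint$refine_passes %||% 2L)
  }
  passports <- passports_from_keypoints(recs, kps, object$passport)
  preds <- NULL
  for (start in seq(1, length(passports), by = 32L)) {
    idx <- start:min(start + 31L, length(passports))
    ps <- ensemble_predict(object$stages$identity, passports[idx], names = nms[idx])
    preds <- if (is.null(preds)) ps$p else rbind(preds, ps$p)
  }
  out <- prediction_set(nms, object$roster, preds)
  if (details) {
    # the pipeline's final head-box estimate derives from the refined
    # head-axis keypoints; the rough roi box is kept for diagnostics
    imgs <- record_images(recs)
    refined <- lapply(seq_along(kps), function(i) {
      endpoints_to_bbox(kps[[i]]$bonnet, kps[[i]]$blowhole, image_hw(imgs[[i]]))
    })
    list(predictions = out, boxes = refined, roi_boxes = boxes,
         keypoints = kps, passports = passports)
  } else {
    out
  }
}

#' Evaluate a fitted pipeline on annotated records
#'
#' Runs the automatic chain and reports identification metrics along with
#' stage-recovery diagnostics against the ground truth.
#'
#' @param fit A `"whale_id"`.
#' @param records Annotated records (e.g. the held-out split).
#' @param ensemble_members Also evaluate each identity member alone.
#' @return List: `report` (an [eval_report()]), `iou` (IoU of the
#'   pipeline's final head-box estimate against ground truth per image),
#'   `iou_roi` (IoU of the rough region-of-interest box),
#'   `kp_error_frac` (keypoint error as a fraction of head length),
#'   `member_logloss` (per-member log loss, when requested).
#' @export
evaluate_pipeline <- function(fit, records, ensemble_members = TRUE) {
  if (inherits(records, "whale_dataset")) records <- records$records
  truth <- truth_set(vapply(records, `[[`, "", "source_name"),
                     dataset_labels(records))
  det <- predict(fit, records, details = TRUE)
  iou <- vapply(seq_along(records), function(i) {
    bbox_iou(det$boxes[[i]], records[[i]]$bbox)
  }, numeric(1))
  iou_roi <- vapply(seq_along(records), function(i) {
    bbox_iou(det$roi_boxes[[i]], records[[i]]$bbox)
  }, numeric(1))
  kp_err <- vapply(seq_along(records), function(i) {
    gt <- records[[i]]$keypoints
    pk <- det$keypoints[[i]]
    head_len <- sqrt(sum((gt$blowhole - gt$bonnet)^2))
    max(sqrt(sum((pk$bonnet - gt$bonnet)^2)),
        sqrt(sum((pk$blowhole - gt$blowhole)^2))) / head_len
  }, numeric(1))
  out <- list(report = eval_report(det$predictions, truth), iou = iou,
              iou_roi = iou_roi, kp_error_frac = kp_err)
  if (ensemble_members && length(fit$stages$identity) > 1) {
    out$member_logloss <- vapply(fit$stages$identity, function(nt) {
      ps <- ensemble_predict(list(nt), det$passports, names = truth$names)
      logloss(ps, truth)
    }, numeric(1))
    out$ensemble_logloss <- logloss(det$predictions, truth)
  }
  out
}

#' Run the desk-scale demonstration pipeline
#'
#' Generates the demonstration dataset (25 identities, 30 images each,
#' 192 x 192 scenes), fits the full pipeline with 96 x 96 passports and a
#' 3-member identity ensemble, and evaluates the automatic chain on the
#' held-out 10% split.
#'
#' @param seed Integer seed controlling generation and training.
#' @param config Optional overrides merged over [default_run_config()].
#' @param verbose Print progress.
#' @return List with `fit`, `eval` (see [evaluate_pipeline()]) and
#'   `dataset`.
#' @export
run_demo_pipeline <- function(seed = 1L, config = list(), verbose = FALSE) {
  config <- merge_config(default_run_config(seed), config)
  g <- config$generator
  ds <- simulate_whale_dataset(g$n_ids, g$images_per_id, g$image_size,
                               g$noise_level, seed = mix_seed(config$seed, 1L))
  fit <- whale_id_fit(ds, config, verbose = verbose)
  ev <- evaluate_pipeline(fit, ds$records[fit$split$validation])
  list(fit = fit, eval = ev, dataset = ds)
}
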