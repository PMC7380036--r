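#' Synthetic right-whale scenes with known ground truth
#'
#' Real right whales are told apart by the callosity pattern on the top of
#' the head: a distinctive white pattern against the otherwise black body.
#' This module emulates that situation procedurally: each synthetic identity
#' owns a fixed arrangement of white blobs along the head axis, rendered on a
#' dark elongated body over textured water, with exact bounding-box and
#' keypoint annotations. Every output is a pure function of its arguments,
#' including the seed.
#'
#' @name synthetic_whales
NULL

# -- callosity patterns -------------------------------------------------

#' Generate a roster of synthetic callosity patterns
#'
#' Each identity receives a distinctive pattern of 2+ white blobs placed in
#' head-axis coordinates (0 = bonnet tip, 1 = blowhole), with blob radii
#' expressed as fractions of head length. A pattern is `connected` when every
#' pair of consecutive blobs overlaps (center distance below the sum of
#' radii). Whenever `n_ids >= 2` the bank contains at least one connected and
#' one non-connected pattern, so the auxiliary connectivity label is never
#' degenerate.
#'
#' @param n_ids Number of identities (>= 1).
#' @param seed Integer seed; the bank is a pure function of `(n_ids, seed)`.
#' @return A list of `"callosity_pattern"` objects, one per identity, with
#'   fields `identity_id`, `blob_centers` (n x 2: along-axis, lateral),
#'   `blob_radii` and `connected`.
#' @export
make_identity_bank <- function(n_ids, seed = 1L) {
  if (!is.numeric(n_ids) || length(n_ids) != 1L || n_ids < 1 || n_ids != round(n_ids)) {
    stop("`n_ids` must be a positive integer", call. = FALSE)
  }
  n_ids <- as.integer(n_ids)
  bank <- lapply(seq_len(n_ids), function(i) {
    make_callosity_pattern(sprintf("whale_%03d", i), mix_seed(seed, i))
  })
  if (n_ids >= 2L) {
    flags <- vapply(bank, function(p) p$connected, logical(1))
    if (all(flags)) {
      bank[[n_ids]] <- make_callosity_pattern(sprintf("whale_%03d", n_ids),
                                              mix_seed(seed, n_ids),
                                              force_connected = FALSE)
    } else if (!any(flags)) {
      bank[[n_ids]] <- make_callosity_pattern(sprintf("whale_%03d", n_ids),
                                              mix_seed(seed, n_ids),
                                              force_connected = TRUE)
    }
  }
  names(bank) <- vapply(bank, function(p) p$identity_id, character(1))
  bank
}

make_callosity_pattern <- function(identity_id, seed, force_connected = NULL) {
  with_seed(seed, {
    connected <- if (is.null(force_connected)) runif(1) < 0.5 else force_connected
    if (connected) {
      n <- sample(3:5, 1)
      radii <- runif(n, 0.08, 0.14)
      gaps <- (head(radii, -1) + radii[-1]) * runif(n - 1, 0.5, 0.8)
    } else {
      n <- sample(2:4, 1)
      radii <- runif(n, 0.05, 0.09)
      gaps <- (head(radii, -1) + radii[-1]) * runif(n - 1, 1.25, 1.6)
    }
    t_pos <- runif(1, 0.08, 0.15) + c(0, cumsum(gaps))
    t_pos <- pmin(t_pos, 0.95)
    lateral <- runif(n, -0.03, 0.03)
    centers <- cbind(along = t_pos, lateral = lateral)
    pat <- structure(
      list(identity_id = identity_id, blob_centers = centers,
           blob_radii = radii, connected = NA),
      class = "callosity_pattern"
    )
    pat$connected <- is_connected_pattern(pat)
    stopifnot(identical(pat$connected, connected))
    pat
  })
}

#' Recompute a pattern's connectivity flag from its blob geometry
#'
#' @param pattern A `"callosity_pattern"`.
#' @return `TRUE` when every pair of consecutive blobs overlaps.
#' @export
is_connected_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "callosity_pattern"))
  ctr <- pattern$blob_centers
  r <- pattern$blob_radii
  n <- nrow(ctr)
  if (n < 2L) return(TRUE)
  d <- sqrt(rowSums((ctr[-1, , drop = FALSE] - ctr[-n, , drop = FALSE])^2))
  all(d < r[-n] + r[-1])
}

#' @export
print.callosity_pattern <- function(x, ...) {
  cat(sprintf("<callosity_pattern %s: %d blobs, %s>\n", x$identity_id,
              nrow(x$blob_centers), if (x$connected) "connected" else "disconnected"))
  invisible(x)
}

# -- poses --------------------------------------------------------------

#' Construct a whale pose
#'
#' @param center `(x, y)` body center in pixels.
#' @param heading Heading in radians, counterclockwise, 0 = toward +x.
#' @param body_length Body length in pixels.
#' @return An object of class `"pose"`.
#' @export
make_pose <- function(center, heading, body_length) {
  stopifnot(length(center) == 2L, is.finite(heading), body_length > 0)
  structure(list(center = as.numeric(center), heading = as.numeric(heading),
                 body_length = as.numeric(body_length)),
            class = "pose")
}

# Anatomy implied by a pose. The head is the front quarter of the body:
# bonnet at the front tip, blowhole at the head/body junction.
pose_anatomy <- function(pose) {
  a <- pose$body_length / 2          # semi-major axis
  b <- pose$body_length / 6          # semi-minor axis
  h <- 0.25 * pose$body_length       # head length
  u <- c(cos(pose$heading), sin(pose$heading))
  nrm <- c(-u[2], u[1])
  bonnet <- pose$center + a * u
  blowhole <- bonnet - h * u
  # body half-width at the blowhole's longitudinal position
  w_head <- b * sqrt(1 - ((a - h) / a)^2)
  list(a = a, b = b, h = h, u = u, nrm = nrm,
       bonnet = bonnet, blowhole = blowhole, w_head = w_head)
}

# Ground-truth head box: the rectangle spanned by bonnet and blowhole with
# the head's lateral extent, expanded by a 10% head-length margin.
pose_head_bbox <- function(pose, margin_frac = 0.1) {
  an <- pose_anatomy(pose)
  m <- margin_frac * an$h
  corners <- rbind(an$bonnet + an$w_head * an$nrm,
                   an$bonnet - an$w_head * an$nrm,
                   an$blowhole + an$w_head * an$nrm,
                   an$blowhole - an$w_head * an$nrm)
  bounding_box(min(corners[, 1]) - m, min(corners[, 2]) - m,
               max(corners[, 1]) + m + 1e-9, max(corners[, 2]) + m + 1e-9)
}

pose_fits <- function(pose, image_size) {
  an <- pose_anatomy(pose)
  phi <- pose$heading
  ex <- sqrt((an$a * cos(phi))^2 + (an$b * sin(phi))^2)
  ey <- sqrt((an$a * sin(phi))^2 + (an$b * cos(phi))^2)
  bb <- pose_head_bbox(pose)
  H <- image_size[1]; W <- image_size[2]
  pose$center[1] - ex >= 0 && pose$center[1] + ex <= W - 1 &&
    pose$center[2] - ey >= 0 && pose$center[2] + ey <= H - 1 &&
    bb$x0 >= 0 && bb$x1 <= W && bb$y0 >= 0 && bb$y1 <= H
}

# Draw a pose that fits the image; bounded rejection sampling (<= 100 tries).
sample_pose <- function(image_size, body_frac = c(0.55, 0.75), max_tries = 100L) {
  image_size <- check_size(image_size)
  side <- min(image_size)
  for (i in seq_len(max_tries)) {
    L <- runif(1, body_frac[1], body_frac[2]) * side
    heading <- runif(1, 0, 2 * pi)
    cx <- runif(1, 0.25 * image_size[2], 0.75 * image_size[2])
    cy <- runif(1, 0.25 * image_size[1], 0.75 * image_size[1])
    pose <- make_pose(c(cx, cy), heading, L)
    if (pose_fits(pose, image_size)) return(pose)
  }
  stop(sprintf("could not place a whale of length ~%.0f px in a %d x %d image",
               mean(body_frac) * side, image_size[1], image_size[2]), call. = FALSE)
}

# -- rendering ----------------------------------------------------------

# Smooth value noise: coarse Gaussian grid, bilinearly upsampled.
value_noise <- function(H, W, cell) {
  nh <- ceiling(H / cell) + 1L
  nw <- ceiling(W / cell) + 1L
  g <- matrix(rnorm(nh * nw), nh, nw)
  ys <- (seq_len(H) - 1) / cell
  xs <- (seq_len(W) - 1) / cell
  y0 <- pmin(floor(ys), nh - 2); fy <- ys - y0
  x0 <- pmin(floor(xs), nw - 2); fx <- xs - x0
  iy <- y0 + 1L; ix <- x0 + 1L
  g00 <- g[iy, ix, drop = FALSE]; g10 <- g[iy + 1L, ix, drop = FALSE]
  g01 <- g[iy, ix + 1L, drop = FALSE]; g11 <- g[iy + 1L, ix + 1L, drop = FALSE]
  FY <- matrix(fy, H, W); FX <- matrix(fx, H, W, byrow = TRUE)
  g00 * (1 - FY) * (1 - FX) + g10 * FY * (1 - FX) +
    g01 * (1 - FY) * FX + g11 * FY * FX
}

#' Render one annotated synthetic scene
#'
#' Draws the dark body ellipse at the given pose on a noisy water background,
#' paints the identity's white callosity blobs between the two head
#' keypoints, applies a seed-determined brightness/glare perturbation, and
#' returns the image together with its exact ground-truth annotations.
#'
#' @param pattern A `"callosity_pattern"` from [make_identity_bank()].
#' @param pose A [make_pose()] object; must fit inside the image.
#' @param image_size `(H, W)` in pixels.
#' @param noise_level Background/perturbation strength in `[0, 1)`.
#' @param seed Integer seed; the scene is a pure function of its arguments.
#' @param source_name File-stem-style record name.
#' @return An `"annotated_image"`: list with `image` (`H x W x 3` in
#'   `[0, 1]`), `identity_id`, `bbox`, `keypoints`, `connected`,
#'   `source_name` and `pose`.
#' @export
render_scene <- function(pattern, pose, image_size = c(192, 192),
                         noise_level = 0.1, seed = 1L,
                         source_name = paste0(pattern$identity_id, "_scene")) {
  stopifnot(inherits(pattern, "callosity_pattern"), inherits(pose, "pose"))
  image_size <- check_size(image_size)
  if (noise_level < 0 || noise_level >= 1) {
    stop("`noise_level` must be in [0, 1)", call. = FALSE)
  }
  if (!pose_fits(pose, image_size)) {
    stop(sprintf(paste0("whale does not fit: pose center (%.1f, %.1f), heading %.2f rad, ",
                        "body length %.1f px exceeds a %d x %d image"),
                 pose$center[1], pose$center[2], pose$heading, pose$body_length,
                 image_size[1], image_size[2]), call. = FALSE)
  }
  H <- image_size[1]; W <- image_size[2]
  an <- pose_anatomy(pose)

  img <- with_seed(seed, {
    X <- matrix(rep(0:(W - 1), each = H), H, W)
    Y <- matrix(rep(0:(H - 1), times = W), H, W)

    # water: bluish base plus coarse swell and fine chop
    swell <- value_noise(H, W, cell = max(8L, round(min(H, W) / 12)))
    chop <- value_noise(H, W, cell = 3L)
    water <- 0.45 + noise_level * (0.6 * swell + 0.35 * chop)

    # body ellipse in pose-aligned coordinates, softened edge
    dx <- X - pose$center[1]; dy <- Y - pose$center[2]
    qx <- dx * an$u[1] + dy * an$u[2]
    qy <- -dx * an$u[2] + dy * an$u[1]
    e <- (qx / an$a)^2 + (qy / an$b)^2
    w_body <- clamp01((1 - e) / 0.08)
    mottle <- value_noise(H, W, cell = 5L)
    body <- 0.10 + 0.03 * mottle

    # callosities: soft white disks fixed to the head axis
    cal <- matrix(0, H, W)
    axis_vec <- an$blowhole - an$bonnet
    for (k in seq_along(pattern$blob_radii)) {
      ck <- an$bonnet + pattern$blob_centers[k, 1] * axis_vec +
        pattern$blob_centers[k, 2] * an$h * an$nrm
      rho <- pattern$blob_radii[k] * an$h
      d <- sqrt((X - ck[1])^2 + (Y - ck[2])^2)
      cal <- pmax(cal, clamp01((rho - d) / max(1, 0.3 * rho)))
    }
    cal <- cal * w_body

    base <- water * (1 - w_body) + body * w_body
    base <- base * (1 - cal) + 0.92 * cal

    # global brightness and a localized glare spot
    gain <- 1 + noise_level * runif(1, -0.3, 0.3)
    gx <- runif(1, 0, W - 1); gy <- runif(1, 0, H - 1)
    gs <- 0.25 * min(H, W)
    glare <- noise_level * 0.6 * exp(-((X - gx)^2 + (Y - gy)^2) / (2 * gs^2))

    chan_tint <- c(0.92, 1.0, 1.08)   # slight blue cast in the water
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      tint <- (1 - w_body) * chan_tint[ch] + w_body
      grain <- matrix(rnorm(H * W, sd = noise_level * 0.06), H, W)
      img[, , ch] <- clamp01(base * tint * gain + glare + grain)
    }
    img
  })

  structure(
    list(image = img,
         identity_id = pattern$identity_id,
         bbox = pose_head_bbox(pose),
         keypoints = keypoint_pair(an$bonnet, an$blowhole),
         connected = pattern$connected,
         source_name = source_name,
         pose = pose),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  hw <- image_hw(x$image)
  cat(sprintf("<annotated_image %s: %s, %d x %d, %s>\n", x$source_name,
              x$identity_id, hw[1], hw[2],
              if (x$connected) "connected" else "disconnected"))
  invisible(x)
}

# -- datasets -----------------------------------------------------------

#' Draw a heavy-tailed images-per-identity distribution
#'
#' Real photo-identification catalogs are strongly imbalanced: a few
#' individuals are photographed dozens of times while others appear once.
#' Counts are drawn log-uniformly between `min` and `max`; when
#' `n_ids >= 2`, one identity is pinned at `min` and one at `max` so the
#' requested extremes are always realized.
#'
#' @param n_ids Number of identities.
#' @param min,max Smallest and largest per-identity image counts.
#' @param seed Integer seed.
#' @return Integer vector of length `n_ids`.
#' @export
sample_image_counts <- function(n_ids, min = 1L, max = 82L, seed = 1L) {
  stopifnot(n_ids >= 1, min >= 1, max >= min)
  with_seed(seed, {
    counts <- round(exp(runif(n_ids, log(min), log(max + 0.49))))
    counts <- pmin(pmax(counts, min), max)
    if (n_ids >= 2L) {
      counts[1L] <- max
      counts[n_ids] <- min
    }
    as.integer(counts)
  })
}

#' Simulate an in-memory annotated dataset
#'
#' @param n_ids Number of identities.
#' @param images_per_id Single count or vector of length `n_ids`.
#' @param image_size `(H, W)` scene size.
#' @param noise_level Scene noise strength, `[0, 1)`.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param body_frac Range of body length as a fraction of the short image side.
#' @return A list of class `"whale_dataset"` with `records` (list of
#'   `"annotated_image"`), `bank` and `config`.
#' @export
simulate_whale_dataset <- function(n_ids, images_per_id = 10L,
                                   image_size = c(192, 192),
                                   noise_level = 0.1, seed = 1L,
                                   body_frac = c(0.55, 0.75)) {
  image_size <- check_size(image_size)
  counts <- if (length(images_per_id) == 1L) rep(as.integer(images_per_id), n_ids)
            else as.integer(images_per_id)
  if (length(counts) != n_ids || any(counts < 1)) {
    stop("`images_per_id` must be a positive count or one count per identity",
         call. = FALSE)
  }
  bank <- make_identity_bank(n_ids, seed)
  records <- vector("list", sum(counts))
  r <- 0L
  for (i in seq_len(n_ids)) {
    for (j in seq_len(counts[i])) {
      r <- r + 1L
      rec_seed <- mix_seed(seed, 1000L + r)
      pose <- with_seed(rec_seed, sample_pose(image_size, body_frac))
      records[[r]] <- render_scene(
        bank[[i]], pose, image_size, noise_level, seed = mix_seed(rec_seed, 1L),
        source_name = sprintf("%s_img%03d", bank[[i]]$identity_id, j)
      )
    }
  }
  structure(
    list(records = records, bank = bank,
         config = list(n_ids = n_ids, images_per_id = counts,
                       image_size = image_size, noise_level = noise_level,
                       seed = seed, body_frac = body_frac)),
    class = "whale_dataset"
  )
}

#' @export
print.whale_dataset <- function(x, ...) {
  cat(sprintf("<whale_dataset: %d images, %d identities, %d x %d scenes>\n",
              length(x$records), x$config$n_ids,
              x$config$image_size[1], x$config$image_size[2]))
  invisible(x)
}

annotations_table <- function(records) {
  do.call(rbind, lapply(records, function(rec) {
    data.frame(source_name = rec$source_name,
               identity_id = rec$identity_id,
               bbox_x0 = rec$bbox$x0, bbox_y0 = rec$bbox$y0,
               bbox_x1 = rec$bbox$x1, bbox_y1 = rec$bbox$y1,
               bonnet_x = rec$keypoints$bonnet[1], bonnet_y = rec$keypoints$bonnet[2],
               blowhole_x = rec$keypoints$blowhole[1], blowhole_y = rec$keypoints$blowhole[2],
               connected = as.integer(rec$connected),
               stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic dataset on disk
#'
#' Renders the configured dataset and writes one 8-bit RGB PNG per record, an
#' `annotations.csv` table covering every record (0-based pixel coordinates,
#' half-open boxes, `connected` in `{0, 1}`) and a `manifest.json` recording
#' the files and the generator configuration. Re-running with the same
#' configuration reproduces identical files.
#'
#' @param config Generator settings: a list with `n_ids`, `images_per_id`,
#'   `image_size`, `noise_level`, `seed` (see [simulate_whale_dataset()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list (`files`, `annotations`, `config`).
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    stop(sprintf("output directory '%s' is not writable", dir), call. = FALSE)
  }
  ds <- do.call(simulate_whale_dataset, config)
  files <- character(length(ds$records))
  for (i in seq_along(ds$records)) {
    rec <- ds$records[[i]]
    files[i] <- paste0(rec$source_name, ".png")
    png::writePNG(rec$image, file.path(dir, files[i]))
  }
  ann <- annotations_table(ds$records)
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(files = files, annotations = "annotations.csv",
                   config = ds$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read an annotations table written by [generate_dataset()]
#'
#' @param path Path to `annotations.csv`.
#' @return A data frame with one row per image.
#' @export
read_annotations <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_name", "identity_id", "bbox_x0", "bbox_y0", "bbox_x1",
            "bbox_y1", "bonnet_x", "bonnet_y", "blowhole_x", "blowhole_y",
            "connected")
  missing <- setdiff(need, names(ann))
  if (length(missing)) {
    stop("annotations file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Load a generated dataset from disk into annotated records
#'
#' @param dir Directory written by [generate_dataset()].
#' @return A `"whale_dataset"` (without the pattern bank).
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ann <- read_annotations(file.path(dir, manifest$annotations))
  records <- lapply(seq_len(nrow(ann)), function(i) {
    row <- ann[i, ]
    img <- png::readPNG(file.path(dir, paste0(row$source_name, ".png")))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    structure(
      list(image = img[, , 1:3, drop = FALSE],
           identity_id = row$identity_id,
           bbox = bounding_box(row$bbox_x0, row$bbox_y0, row$bbox_x1, row$bbox_y1),
           keypoints = keypoint_pair(c(row$bonnet_x, row$bonnet_y),
                                     c(row$blowhole_x, row$blowhole_y)),
           connected = row$connected == 1,
           source_name = row$source_name,
           pose = NULL),
      class = "annotated_image"
    )
  })
  structure(list(records = records, bank = NULL, config = manifest$config),
            class = "whale_dataset")
}
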