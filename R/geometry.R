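#' Coordinate conventions and passport-photo geometry
#'
#' All coordinates are 0-based pixels; `(x, y)` addresses the center of pixel
#' column `x`, row `y`. Bounding boxes are half-open: `[x0, x1) x [y0, y1)`.
#' Sizes are given as `(H, W)`.
#'
#' @name geometry
NULL

#' Construct a bounding box
#'
#' @param x0,y0,x1,y1 Box corners in pixels, 0-based, half-open
#'   (`[x0, x1) x [y0, y1)`). Requires `x0 < x1` and `y0 < y1`.
#' @return An object of class `"bounding_box"`.
#' @export
bounding_box <- function(x0, y0, x1, y1) {
  v <- c(x0 = as.numeric(x0), y0 = as.numeric(y0),
         x1 = as.numeric(x1), y1 = as.numeric(y1))
  if (any(!is.finite(v))) stop("bounding box corners must be finite", call. = FALSE)
  if (v["x0"] >= v["x1"] || v["y0"] >= v["y1"]) {
    stop("degenerate bounding box: need x0 < x1 and y0 < y1", call. = FALSE)
  }
  structure(as.list(v), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box [%.2f, %.2f) x [%.2f, %.2f)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

#' Construct a bonnet/blowhole keypoint pair
#'
#' The two alignment keypoints are the tip of the bonnet and a point just
#' below the blowholes; they must be distinct.
#'
#' @param bonnet,blowhole Length-2 `(x, y)` continuous pixel coordinates.
#' @return An object of class `"keypoint_pair"`.
#' @export
keypoint_pair <- function(bonnet, blowhole) {
  bonnet <- as.numeric(bonnet); blowhole <- as.numeric(blowhole)
  if (length(bonnet) != 2L || length(blowhole) != 2L ||
      any(!is.finite(c(bonnet, blowhole)))) {
    stop("keypoints must be finite (x, y) pairs", call. = FALSE)
  }
  if (all(bonnet == blowhole)) {
    stop("degenerate keypoints: bonnet and blowhole coincide", call. = FALSE)
  }
  structure(list(bonnet = bonnet, blowhole = blowhole), class = "keypoint_pair")
}

#' Rescale a bounding box between image resolutions
#'
#' Maps a box annotated on an image of size `from_size` onto an image of size
#' `to_size` by multiplying each corner by the per-axis size ratio, then clips
#' the result to the target bounds. Used to back-project a region of interest
#' predicted on a downscaled image onto the full-resolution photograph.
#'
#' @param bbox A [bounding_box()].
#' @param from_size,to_size `(H, W)` image sizes in pixels.
#' @return A [bounding_box()] in `to_size` coordinates.
#' @export
scale_bbox <- function(bbox, from_size, to_size) {
  stopifnot(inherits(bbox, "bounding_box"))
  from_size <- check_size(from_size, "from_size")
  to_size <- check_size(to_size, "to_size")
  rx <- to_size[2] / from_size[2]
  ry <- to_size[1] / from_size[1]
  x0 <- max(0, bbox$x0 * rx); x1 <- min(to_size[2], bbox$x1 * rx)
  y0 <- max(0, bbox$y0 * ry); y1 <- min(to_size[1], bbox$y1 * ry)
  if (x0 >= x1 || y0 >= y1) {
    stop("bounding box degenerate after rescaling/clipping", call. = FALSE)
  }
  bounding_box(x0, y0, x1, y1)
}

#' Similarity transform (rotation + uniform scale + translation)
#'
#' Acts on a point `p` as `scale * R(rotation) %*% p + translation`, with
#' `R` the counterclockwise rotation matrix in `(x, y)` coordinates.
#'
#' @param scale Positive scale factor.
#' @param rotation Rotation angle in radians.
#' @param translation Length-2 `(tx, ty)` in pixels.
#' @return An object of class `"similarity_transform"`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity: scale %.4f, rotation %.4f rad, translation (%.2f, %.2f)>\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Apply a similarity transform to points
#'
#' @param tf A [similarity_transform()].
#' @param pts A length-2 `(x, y)` vector, an `n x 2` matrix of points, or a
#'   [keypoint_pair()].
#' @return Points of the same shape/class as the input.
#' @export
apply_transform <- function(tf, pts) {
  stopifnot(inherits(tf, "similarity_transform"))
  if (inherits(pts, "keypoint_pair")) {
    return(keypoint_pair(apply_transform(tf, pts$bonnet),
                         apply_transform(tf, pts$blowhole)))
  }
  single <- is.null(dim(pts))
  p <- if (single) matrix(pts, 1, 2) else as.matrix(pts)
  out <- tf$scale * (p %*% t(rot_mat(tf$rotation)))
  out[, 1] <- out[, 1] + tf$translation[1]
  out[, 2] <- out[, 2] + tf$translation[2]
  if (single) as.numeric(out) else out
}

#' Invert a similarity transform
#' @param tf A [similarity_transform()].
#' @return The inverse [similarity_transform()].
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  Rinv <- rot_mat(-tf$rotation)
  similarity_transform(1 / tf$scale, -tf$rotation,
                       -as.numeric(Rinv %*% tf$translation) / tf$scale)
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [similarity_transform()] objects.
#' @return A [similarity_transform()].
#' @export
compose_transform <- function(second, first) {
  stopifnot(inherits(second, "similarity_transform"),
            inherits(first, "similarity_transform"))
  similarity_transform(
    scale = second$scale * first$scale,
    rotation = second$rotation + first$rotation,
    translation = apply_transform(second, first$translation)
  )
}

#' Solve the similarity transform defined by two keypoint correspondences
#'
#' Returns the unique reflection-free similarity mapping `src$bonnet` onto
#' `dst$bonnet` and `src$blowhole` onto `dst$blowhole`: the scale is the
#' ratio of the bonnet-to-blowhole distances, the rotation the angle between
#' the two bonnet-to-blowhole vectors, and the translation makes the bonnet
#' correspondence exact.
#'
#' @param src,dst [keypoint_pair()] objects in source and destination frames.
#' @return A [similarity_transform()].
#' @export
similarity_from_keypoints <- function(src, dst) {
  stopifnot(inherits(src, "keypoint_pair"), inherits(dst, "keypoint_pair"))
  vs <- src$blowhole - src$bonnet
  vd <- dst$blowhole - dst$bonnet
  ns <- sqrt(sum(vs^2)); nd <- sqrt(sum(vd^2))
  if (ns == 0 || nd == 0) {
    stop("degenerate keypoints: bonnet and blowhole coincide", call. = FALSE)
  }
  s <- nd / ns
  theta <- atan2(vd[2], vd[1]) - atan2(vs[2], vs[1])
  t <- dst$bonnet - s * as.numeric(rot_mat(theta) %*% src$bonnet)
  similarity_transform(s, theta, t)
}

#' Canonical passport-photo geometry
#'
#' Defines the output size of the standardized head image and the canonical
#' positions the two keypoints are mapped to: the head is vertical and
#' centered, bonnet near the top, blowhole near the bottom (by default at
#' 18.75% and 81.25% of the output height, so the head spans ~62% of the
#' frame).
#'
#' @param out_size `(H, W)` output size in pixels (default `c(256, 256)`).
#' @param bonnet,blowhole Canonical `(x, y)` positions; defaults are derived
#'   from `out_size` as described above.
#' @return An object of class `"passport_spec"`.
#' @export
passport_spec <- function(out_size = c(256, 256),
                          bonnet = c(out_size[2] / 2, 0.1875 * out_size[1]),
                          blowhole = c(out_size[2] / 2, 0.8125 * out_size[1])) {
  out_size <- check_size(out_size, "out_size")
  kp <- keypoint_pair(bonnet, blowhole)  # validates distinctness
  inside <- function(p) p[1] >= 0 && p[1] < out_size[2] && p[2] >= 0 && p[2] < out_size[1]
  if (!inside(kp$bonnet) || !inside(kp$blowhole)) {
    stop("canonical keypoints must lie inside the output frame", call. = FALSE)
  }
  structure(list(out_size = out_size, bonnet = kp$bonnet, blowhole = kp$blowhole),
            class = "passport_spec")
}

canonical_keypoints <- function(spec) keypoint_pair(spec$bonnet, spec$blowhole)

#' Warp an image into a standardized passport photo
#'
#' Computes the similarity transform that carries the image's two head
#' keypoints onto the canonical positions of `spec` and resamples the image
#' accordingly, producing a head photograph of uniform size and orientation.
#' Samples falling outside the source image are filled with `pad`.
#'
#' @param image An `H x W x 3` array with intensities in `[0, 1]`.
#' @param keypoints A [keypoint_pair()] in image coordinates.
#' @param spec A [passport_spec()].
#' @param pad Constant fill value for out-of-bounds samples (default 0, black).
#' @param interp `"bilinear"` (default) or `"nearest"` resampling.
#' @return An `out_size` image array of class `"passport_photo"` with
#'   attributes `pad`, `spec` and `transform` (the similarity used).
#' @export
warp_to_passport <- function(image, keypoints, spec = passport_spec(),
                             pad = 0, interp = c("bilinear", "nearest")) {
  assert_image(image)
  stopifnot(inherits(keypoints, "keypoint_pair"), inherits(spec, "passport_spec"))
  interp <- match.arg(interp)
  tf <- similarity_from_keypoints(keypoints, canonical_keypoints(spec))
  out <- warp_similarity(image, tf, spec$out_size, pad = pad, interp = interp)
  structure(out, class = "passport_photo", pad = pad, spec = spec, transform = tf)
}

# Resample `image` under a forward similarity `tf` (output pixel p_out reads
# the input at tf^{-1}(p_out)).
warp_similarity <- function(image, tf, out_size, pad = 0,
                            interp = c("bilinear", "nearest")) {
  assert_image(image)
  interp <- match.arg(interp)
  out_size <- check_size(out_size, "out_size")
  inv <- invert_transform(tf)
  A <- inv$scale * rot_mat(inv$rotation)
  .cpp_affine_sample(image, A, inv$translation, out_size[1], out_size[2],
                     pad, if (interp == "nearest") 0L else 1L)
}

#' Resize an image by independent axis scaling
#'
#' @param image `H x W x 3` array.
#' @param out_size Target `(H, W)`.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return The resized array.
#' @export
resize_image <- function(image, out_size, interp = c("bilinear", "nearest")) {
  assert_image(image)
  interp <- match.arg(interp)
  out_size <- check_size(out_size, "out_size")
  hw <- image_hw(image)
  sx <- hw[2] / out_size[2]
  sy <- hw[1] / out_size[1]
  A <- matrix(c(sx, 0, 0, sy), 2, 2)
  off <- c(0.5 * sx - 0.5, 0.5 * sy - 0.5)
  .cpp_affine_sample(image, A, off, out_size[1], out_size[2], 0,
                     if (interp == "nearest") 0L else 1L)
}

# Integer pixel index ranges covered by a half-open box.
bbox_pixel_range <- function(bbox) {
  list(x = seq.int(ceiling(bbox$x0), ceiling(bbox$x1) - 1L),
       y = seq.int(ceiling(bbox$y0), ceiling(bbox$y1) - 1L))
}

#' Crop the pixels covered by a bounding box
#'
#' @param image `H x W x 3` array.
#' @param bbox A [bounding_box()]; pixels with integer coordinates inside the
#'   half-open box are extracted.
#' @return The cropped array, with attribute `origin` = `(x, y)` of its
#'   first pixel in the source frame.
#' @export
crop_bbox <- function(image, bbox) {
  assert_image(image)
  stopifnot(inherits(bbox, "bounding_box"))
  rng <- bbox_pixel_range(bbox)
  hw <- image_hw(image)
  rng$x <- rng$x[rng$x >= 0 & rng$x < hw[2]]
  rng$y <- rng$y[rng$y >= 0 & rng$y < hw[1]]
  if (!length(rng$x) || !length(rng$y)) {
    stop("bounding box covers no pixels of the image", call. = FALSE)
  }
  out <- image[rng$y + 1L, rng$x + 1L, , drop = FALSE]
  attr(out, "origin") <- c(rng$x[1], rng$y[1])
  out
}
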