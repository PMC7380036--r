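#' Training-time augmentation
#'
#' Passport normalization is never perfect on real photographs: slight
#' misalignments in scale and rotation survive, and lighting varies with
#' weather, sun angle and camera. Training therefore adds very slightly
#' rotated and rescaled copies of each image and random color-space
#' perturbations, with annotations mapped through the same transform.
#'
#' @name augmentation
NULL

#' Construct an augmentation policy
#'
#' @param max_rotation Largest jitter rotation in radians (default 10
#'   degrees).
#' @param scale_range `(lo, hi)` multiplicative scale jitter with
#'   `lo <= 1 <= hi` (default `c(0.9, 1.1)`).
#' @param color_strength Standard deviation of the principal-component color
#'   perturbation coefficients (default 0.1, in intensity units).
#' @param jitter,color Logical switches for the two transforms.
#' @return An object of class `"augmentation_policy"`.
#' @export
augmentation_policy <- function(max_rotation = 10 * pi / 180,
                                scale_range = c(0.9, 1.1),
                                color_strength = 0.1,
                                jitter = TRUE, color = TRUE) {
  if (max_rotation < 0) stop("`max_rotation` must be >= 0", call. = FALSE)
  if (length(scale_range) != 2L || scale_range[1] > 1 || scale_range[2] < 1) {
    stop("`scale_range` must be (lo, hi) with lo <= 1 <= hi", call. = FALSE)
  }
  if (color_strength < 0) stop("`color_strength` must be >= 0", call. = FALSE)
  structure(list(max_rotation = max_rotation, scale_range = as.numeric(scale_range),
                 color_strength = color_strength, jitter = isTRUE(jitter),
                 color = isTRUE(color)),
            class = "augmentation_policy")
}

# Signalled when a jittered bounding box leaves the frame entirely; callers
# catch this condition and skip the sample.
augmentation_rejected <- function(msg) {
  structure(class = c("augmentation_rejected", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Apply a small random pose jitter to an annotated record
#'
#' Resamples the image under a random similarity about the image center
#' (rotation within `max_rotation`, scale within `scale_range`) and maps the
#' keypoints and bounding box through the same transform; the box is
#' re-axis-aligned as the bounding box of its mapped corners and clipped to
#' the frame. Identity and connectivity labels are untouched.
#'
#' @param record An `"annotated_image"`.
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed; output is deterministic given it.
#' @param interp `"bilinear"` (default) or `"nearest"` resampling.
#' @return A jittered `"annotated_image"`. Signals a condition of class
#'   `"augmentation_rejected"` if the transformed box lies fully outside the
#'   frame.
#' @export
jitter_pose <- function(record, policy, seed = 1L,
                        interp = c("bilinear", "nearest")) {
  stopifnot(inherits(record, "annotated_image"),
            inherits(policy, "augmentation_policy"))
  interp <- match.arg(interp)
  if (!policy$jitter ||
      (policy$max_rotation == 0 && all(policy$scale_range == 1))) {
    return(record)
  }
  hw <- image_hw(record$image)
  draw <- with_seed(seed, {
    list(theta = runif(1, -policy$max_rotation, policy$max_rotation),
         s = runif(1, policy$scale_range[1], policy$scale_range[2]))
  })
  ctr <- c((hw[2] - 1) / 2, (hw[1] - 1) / 2)
  tf <- similarity_transform(draw$s, draw$theta,
                             ctr - draw$s * as.numeric(rot_mat(draw$theta) %*% ctr))
  img <- warp_similarity(record$image, tf, hw, pad = 0, interp = interp)
  corners <- rbind(c(record$bbox$x0, record$bbox$y0),
                   c(record$bbox$x1, record$bbox$y0),
                   c(record$bbox$x0, record$bbox$y1),
                   c(record$bbox$x1, record$bbox$y1))
  mc <- apply_transform(tf, corners)
  x0 <- max(0, min(mc[, 1])); x1 <- min(hw[2], max(mc[, 1]))
  y0 <- max(0, min(mc[, 2])); y1 <- min(hw[1], max(mc[, 2]))
  if (x0 >= x1 || y0 >= y1) {
    stop(augmentation_rejected(sprintf(
      "jittered bounding box of '%s' left the frame", record$source_name)))
  }
  out <- record
  out$image <- img
  out$bbox <- bounding_box(x0, y0, x1, y1)
  out$keypoints <- apply_transform(tf, record$keypoints)
  attr(out, "jitter_transform") <- tf
  out
}

#' Principal-component color perturbation
#'
#' Adds to every pixel the same random 3-vector `sum_k alpha_k lambda_k v_k`,
#' where `(lambda_k, v_k)` are the eigenvalues/eigenvectors of the image's
#' 3 x 3 RGB covariance and `alpha_k ~ Normal(0, strength^2)` are drawn once
#' per call. The perturbation is computed per image, so the operation is
#' stateless. Output is clamped to `[0, 1]`. A constant-color image (zero
#' covariance) and `strength = 0` both return the input unchanged.
#'
#' @param image `H x W x 3` array with intensities in `[0, 1]`.
#' @param strength Nonnegative coefficient standard deviation.
#' @param seed Integer seed.
#' @return The perturbed image.
#' @export
perturb_color <- function(image, strength = 0.1, seed = 1L) {
  assert_image(image)
  if (strength < 0) stop("`strength` must be >= 0", call. = FALSE)
  if (strength == 0) return(image)
  px <- matrix(image, ncol = 3L)
  cv <- stats::cov(px)
  eg <- eigen(cv, symmetric = TRUE)
  alpha <- with_seed(seed, rnorm(3, 0, strength))
  shift <- as.numeric(eg$vectors %*% (alpha * eg$values))
  if (all(shift == 0)) return(image)
  out <- image
  for (ch in 1:3) out[, , ch] <- clamp01(image[, , ch] + shift[ch])
  out
}
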