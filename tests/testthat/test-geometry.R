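test_that("scale_bbox applies per-axis ratios and survives round trips", {
  bb <- bounding_box(10, 20, 50, 60)
  expect_identical(scale_bbox(bb, c(256, 256), c(256, 256)), bb)

  up <- scale_bbox(bb, c(256, 256), c(1024, 1024))
  expect_equal(unlist(up[c("x0", "y0", "x1", "y1")]),
               c(x0 = 40, y0 = 80, x1 = 200, y1 = 240))

  set.seed(10)
  for (i in 1:1000) {
    from <- c(sample(64:512, 1), sample(64:512, 1))
    to <- c(sample(64:2048, 1), sample(64:2048, 1))
    x0 <- runif(1, 0, from[2] - 2); x1 <- runif(1, x0 + 1, from[2])
    y0 <- runif(1, 0, from[1] - 2); y1 <- runif(1, y0 + 1, from[1])
    b <- bounding_box(x0, y0, x1, y1)
    rt <- scale_bbox(scale_bbox(b, from, to), to, from)
    expect_lt(max(abs(unlist(rt) - unlist(b))), 1)
  }

  expect_error(bounding_box(5, 5, 5, 10), "degenerate")
})

test_that("the two-point similarity is the exact, unique solution", {
  kp <- keypoint_pair(c(3, 4), c(10, -2))
  id <- similarity_from_keypoints(kp, kp)
  expect_equal(id$scale, 1)
  expect_equal(id$rotation, 0)
  expect_equal(id$translation, c(0, 0))

  tf <- similarity_from_keypoints(keypoint_pair(c(0, 0), c(2, 0)),
                                  keypoint_pair(c(0, 0), c(0, 4)))
  expect_equal(tf$scale, 2)
  expect_equal(tf$rotation, pi / 2)
  expect_equal(tf$translation, c(0, 0))

  set.seed(11)
  for (i in 1:1000) {
    src <- keypoint_pair(runif(2, -50, 50), runif(2, -50, 50))
    dst <- keypoint_pair(runif(2, -50, 50), runif(2, -50, 50))
    t1 <- similarity_from_keypoints(src, dst)
    expect_lt(max(abs(apply_transform(t1, src$bonnet) - dst$bonnet)), 1e-9)
    expect_lt(max(abs(apply_transform(t1, src$blowhole) - dst$blowhole)), 1e-9)
  }

  expect_error(keypoint_pair(c(1, 1), c(1, 1)), "degenerate")
})

test_that("similarity transforms compose and invert consistently", {
  set.seed(12)
  for (i in 1:200) {
    src <- keypoint_pair(runif(2, -20, 20), runif(2, -20, 20))
    mid <- keypoint_pair(runif(2, -20, 20), runif(2, -20, 20))
    dst <- keypoint_pair(runif(2, -20, 20), runif(2, -20, 20))
    ab <- similarity_from_keypoints(src, mid)
    bc <- similarity_from_keypoints(mid, dst)
    comp <- compose_transform(bc, ab)
    expect_lt(max(abs(apply_transform(comp, src$bonnet) - dst$bonnet)), 1e-9)
    expect_lt(max(abs(apply_transform(comp, src$blowhole) - dst$blowhole)), 1e-9)

    inv <- invert_transform(ab)
    back <- apply_transform(inv, apply_transform(ab, src$bonnet))
    expect_lt(max(abs(back - src$bonnet)), 1e-9)
  }
})

test_that("an identity warp reproduces the image to interpolation precision", {
  set.seed(13)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  spec <- passport_spec(c(32, 32))
  pp <- warp_to_passport(img, keypoint_pair(spec$bonnet, spec$blowhole), spec)
  expect_lt(max(abs(unclass(pp) - img)), 1e-6)
})

test_that("ground-truth keypoints land on the canonical positions", {
  ds <- tiny_dataset(3, 2)
  spec <- passport_spec(c(96, 96))
  for (rec in ds$records) {
    pp <- warp_to_passport(rec$image, rec$keypoints, spec)
    tf <- attr(pp, "transform")
    expect_lt(max(abs(apply_transform(tf, rec$keypoints$bonnet) - spec$bonnet)), 0.5)
    expect_lt(max(abs(apply_transform(tf, rec$keypoints$blowhole) - spec$blowhole)), 0.5)
  }
})

test_that("passport normalization is idempotent", {
  ds <- tiny_dataset(2, 1)
  spec <- passport_spec(c(96, 96))
  rec <- ds$records[[1]]
  pp <- unclass(warp_to_passport(rec$image, rec$keypoints, spec))
  pp2 <- unclass(warp_to_passport(pp, keypoint_pair(spec$bonnet, spec$blowhole), spec))
  expect_lt(max(abs(pp2 - pp)), 2 / 255)
})

test_that("passports are invariant to global rotation and rescaling", {
  bank <- make_identity_bank(2, seed = 2)
  pose <- make_pose(c(70, 70), 0.7, 110)
  rec <- render_scene(bank[[1]], pose, c(192, 192), 0.1, seed = 11)
  spec <- passport_spec(c(96, 96))
  base <- unclass(warp_to_passport(rec$image, rec$keypoints, spec))
  H <- 192; W <- 192

  # quarter-turn rotations are exact pixel permutations
  rot_img <- function(img) aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  rot_pt <- function(p, w) c(p[2], w - 1 - p[1])
  img <- rec$image
  kp <- rec$keypoints
  for (turn in 1:3) {
    w <- dim(img)[2]
    img <- rot_img(img)
    kp <- keypoint_pair(rot_pt(kp$bonnet, w), rot_pt(kp$blowhole, w))
    pp <- unclass(warp_to_passport(img, kp, spec))
    expect_lt(max(abs(pp - base)), 2 / 255)
  }

  # uniform x3 rescale by pixel replication (exact under nearest sampling)
  k <- 3
  up <- rec$image[rep(seq_len(H), each = k), rep(seq_len(W), each = k), , drop = FALSE]
  kp_up <- keypoint_pair(k * rec$keypoints$bonnet + (k - 1) / 2,
                         k * rec$keypoints$blowhole + (k - 1) / 2)
  pn <- unclass(warp_to_passport(rec$image, rec$keypoints, spec, interp = "nearest"))
  pu <- unclass(warp_to_passport(up, kp_up, spec, interp = "nearest"))
  expect_lt(max(abs(pu - pn)), 2 / 255)
})

test_that("cropping respects the half-open box convention", {
  img <- array(seq(0, 1, length.out = 10 * 8 * 3), c(10, 8, 3))
  crop <- crop_bbox(img, bounding_box(2, 3, 5, 7))
  expect_equal(dim(crop), c(4, 3, 3))
  expect_equal(attr(crop, "origin"), c(2, 3))
  expect_equal(crop[1, 1, ], img[4, 3, ])
  expect_error(crop_bbox(img, bounding_box(20, 20, 30, 30)), "no pixels")
})
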