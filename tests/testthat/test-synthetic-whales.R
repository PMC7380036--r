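test_that("identity banks are deterministic and distinct", {
  expect_identical(make_identity_bank(1, seed = 7), make_identity_bank(1, seed = 7))
  bank <- make_identity_bank(25, seed = 1)
  ids <- vapply(bank, `[[`, "", "identity_id")
  expect_length(unique(ids), 25)

  # two identities differ in blob layout
  b2 <- make_identity_bank(2, seed = 3)
  ca <- b2[[1]]$blob_centers; cb <- b2[[2]]$blob_centers
  n <- min(nrow(ca), nrow(cb))
  expect_gt(max(abs(ca[seq_len(n), ] - cb[seq_len(n), ])) +
              abs(nrow(ca) - nrow(cb)), 0)

  expect_error(make_identity_bank(0), "positive integer")
})

test_that("banks carry a non-degenerate connectivity label", {
  for (seed in 1:5) {
    flags <- vapply(make_identity_bank(5, seed = seed), `[[`, TRUE, "connected")
    expect_true(any(flags) && !all(flags))
  }
})

test_that("stored connectivity equals blob-overlap recomputation", {
  bank <- make_identity_bank(25, seed = 9)
  for (pat in bank) {
    expect_gte(nrow(pat$blob_centers), 2)
    expect_true(all(pat$blob_centers[, 1] >= 0 & pat$blob_centers[, 1] <= 1))
    expect_identical(pat$connected, is_connected_pattern(pat))
  }
})

test_that("rendering is a pure function of its arguments", {
  bank <- make_identity_bank(2, seed = 4)
  pose <- make_pose(c(48, 48), 1.1, 60)
  a <- render_scene(bank[[1]], pose, c(96, 96), 0.1, seed = 5)
  b <- render_scene(bank[[1]], pose, c(96, 96), 0.1, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$bbox, b$bbox)

  # different patterns at the same pose/seed differ inside the head box
  c1 <- render_scene(bank[[2]], pose, c(96, 96), 0.1, seed = 5)
  rng <- whalepassport:::bbox_pixel_range(a$bbox)
  d <- abs(a$image[rng$y + 1, rng$x + 1, ] - c1$image[rng$y + 1, rng$x + 1, ])
  expect_gt(mean(d), 0)
})

test_that("every generated record satisfies the annotation geometry", {
  ds <- tiny_dataset(5, 4)
  expect_length(ds$records, 20)
  for (rec in ds$records) {
    bb <- rec$bbox
    hw <- dim(rec$image)[1:2]
    expect_true(bb$x0 >= 0 && bb$y0 >= 0 && bb$x1 <= hw[2] && bb$y1 <= hw[1])
    for (p in list(rec$keypoints$bonnet, rec$keypoints$blowhole)) {
      expect_true(p[1] > bb$x0 && p[1] < bb$x1 && p[2] > bb$y0 && p[2] < bb$y1)
    }
    expect_true(all(rec$image >= 0 & rec$image <= 1))
  }
})

test_that("rendered heads are separable across all identity pairs", {
  bank <- make_identity_bank(8, seed = 21)
  pose <- make_pose(c(48, 48), 0.4, 62)
  scenes <- lapply(bank, render_scene, pose = pose, image_size = c(96, 96),
                   noise_level = 0.05, seed = 33)
  rng <- whalepassport:::bbox_pixel_range(scenes[[1]]$bbox)
  for (i in seq_along(scenes)) {
    for (j in seq_len(i - 1)) {
      d <- abs(scenes[[i]]$image[rng$y + 1, rng$x + 1, ] -
                 scenes[[j]]$image[rng$y + 1, rng$x + 1, ])
      expect_gt(mean(d), 0)
    }
  }
})

test_that("ill-posed scenes are rejected with informative errors", {
  bank <- make_identity_bank(1, seed = 2)
  big <- make_pose(c(20, 20), 0, 300)
  expect_error(render_scene(bank[[1]], big, c(96, 96), 0.1, seed = 1),
               "does not fit")
  pose <- make_pose(c(48, 48), 0, 60)
  expect_error(render_scene(bank[[1]], pose, c(96, 96), noise_level = 1),
               "noise_level")
})

test_that("images-per-identity counts realize the requested extremes", {
  counts <- sample_image_counts(40, min = 1, max = 82, seed = 6)
  expect_equal(min(counts), 1)
  expect_equal(max(counts), 82)
  expect_true(all(counts >= 1 & counts <= 82))
  expect_identical(counts, sample_image_counts(40, min = 1, max = 82, seed = 6))
})

test_that("generate_dataset writes a complete, reproducible dataset", {
  cfg <- list(n_ids = 3, images_per_id = c(1, 2, 3), image_size = c(64, 64),
              noise_level = 0.1, seed = 11)
  d1 <- file.path(tempdir(), "wds1"); d2 <- file.path(tempdir(), "wds2")
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_length(m1$files, 6)
  expect_identical(m1$files, m2$files)

  ann <- read_annotations(file.path(d1, "annotations.csv"))
  expect_equal(nrow(ann), 6)
  expect_identical(unname(tools::md5sum(file.path(d1, m1$files))),
                   unname(tools::md5sum(file.path(d2, m2$files))))

  # loading reproduces the records up to 8-bit quantization
  ds <- load_dataset(d1)
  expect_length(ds$records, 6)
  expect_s3_class(ds$records[[1]]$bbox, "bounding_box")

  unlink(c(d1, d2), recursive = TRUE)
})
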