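test_that("phantom generation is deterministic and honours the lesion contract", {
  spec <- phantom_spec(n_lesions = 2, spacing = 0.25, seed = 7)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(lapply(a$lesion_masks, `[[`, "pixels"),
                   lapply(b$lesion_masks, `[[`, "pixels"))

  expect_length(a$lesion_masks, 2)
  # forced area definition: pixel count x spacing^2 (0.25^2 = 0.0625)
  for (i in seq_along(a$lesion_masks))
    expect_equal(a$true_areas[i], sum(a$lesion_masks[[i]]$pixels) * 0.0625)

  none <- generate_phantom(phantom_spec(n_lesions = 0, seed = 1))
  expect_length(none$lesion_masks, 0)
  expect_length(none$true_areas, 0)
})

test_that("lesions are disjoint from bone, near it, and mutually separated", {
  for (seed in 1:12) {
    p <- generate_phantom(phantom_spec(seed = seed, n_lesions = 3))
    bone <- p$bone_mask$pixels
    near1 <- dilate_mask(bone, 1)
    near2 <- dilate_mask(bone, 2)
    all_lesions <- matrix(FALSE, nrow(bone), ncol(bone))
    for (lm in p$lesion_masks) {
      expect_false(any(lm$pixels & bone))
      expect_false(any(lm$pixels & near1))   # survives a 1-px exclusion margin
      expect_true(any(lm$pixels & near2))    # but sits within 2 px of bone
      # each lesion is a single 8-connected blob
      expect_equal(max(label_components(lm$pixels, 8)), 1L)
      expect_false(any(lm$pixels & dilate_mask(all_lesions, 1)))
      all_lesions <- all_lesions | lm$pixels
    }
    # exactly n_phalanges separate bone segments
    expect_equal(max(label_components(bone, 8)), p$spec$n_phalanges)
  }
})

test_that("truncated phantoms clip a phalanx at the border; intact ones do not", {
  tr <- generate_phantom(phantom_spec(seed = 3, truncate_phalanges = TRUE))
  expect_true(any(tr$bone_mask$pixels[1, ]))
  ok <- generate_phantom(phantom_spec(seed = 3))
  border <- c(ok$bone_mask$pixels[c(1, 64), ], ok$bone_mask$pixels[, c(1, 64)])
  expect_false(any(border))
})

test_that("impossible lesion placement raises a placement-failure error", {
  spec <- phantom_spec(seed = 1, n_lesions = 3, lesion_radius_range = c(12, 14))
  expect_error(generate_phantom(spec, max_attempts = 10), "placement failed")
})

test_that("rotation augmentation obeys the count law and rotates pairs jointly", {
  pairs <- make_pairs(1:30, n_lesions = 1)
  aug <- rotate_augment(pairs, 3)
  expect_length(aug, 120)                       # 30 x (1 + 3)
  expect_length(aug, length(pairs) + 90)        # 90 additional images

  for (n_img in c(1, 4)) for (n_rot in 0:3) {
    out <- rotate_augment(pairs[seq_len(n_img)], n_rot)
    expect_length(out, n_img * (1 + n_rot))
  }
  expect_identical(rotate_augment(pairs, 0), pairs)

  # originals at the head; image and mask rotated identically (90 degrees)
  expect_identical(aug[[2]]$mask$pixels, pairs[[2]]$mask$pixels)
  im <- pairs[[1]]$image$pixels
  rot90 <- t(im)[ncol(im):1, ]
  expect_identical(aug[[31]]$image$pixels, rot90)
  mk <- pairs[[1]]$mask$pixels
  expect_identical(aug[[31]]$mask$pixels, t(mk)[ncol(mk):1, ])

  # arbitrary-angle mode keeps masks binary and pairs aligned
  arb <- rotate_augment(pairs[1:2], 5, method = "arbitrary")
  expect_length(arb, 12)
  expect_type(arb[[5]]$mask$pixels, "logical")
})

test_that("window/level mapping is linear, clamped and monotone", {
  expect_equal(apply_window(matrix(-300, 16, 16), 1500, 450)[1, 1], 0)
  expect_equal(apply_window(matrix(1200, 16, 16), 1500, 450)[1, 1], 1)
  expect_equal(apply_window(matrix(450, 16, 16), 1500, 450)[1, 1], 0.5)
  expect_error(apply_window(matrix(0, 16, 16), window = 0), "positive")

  set.seed(4)
  vals <- sort(runif(256, -1000, 2500))
  out <- apply_window(matrix(vals, 16, 16), 1500, 450)
  expect_true(all(diff(as.vector(out)) >= 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("phantom spec validation rejects inconsistent parameters", {
  expect_error(phantom_spec(lesion_intensity = 10, background_intensity = 50),
               "lesion_intensity")
  expect_error(phantom_spec(lesion_radius_range = c(2, 1)), "radius_range")
  expect_error(phantom_spec(lesion_irregularity = 1.5), "irregularity")
  expect_error(phantom_spec(n_lesions = 4))
})
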