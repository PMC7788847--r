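test_that("dice coefficient matches its definition and properties", {
  a <- matrix(FALSE, 16, 16); a[2:3, 2:3] <- TRUE        # |a| = 4
  b <- matrix(FALSE, 16, 16); b[3:4, 2:3] <- TRUE        # |b| = 4, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  d <- matrix(FALSE, 16, 16); d[10, 10] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_equal(dice(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)
  expect_error(dice(a, matrix(FALSE, 8, 8)), "shapes differ")

  set.seed(9)
  for (i in 1:20) {
    x <- matrix(runif(64) > 0.5, 8, 8)
    y <- matrix(runif(64) > 0.5, 8, 8)
    expect_equal(dice(x, y), dice(y, x))
    expect_gte(dice(x, y), 0); expect_lte(dice(x, y), 1)
    if (sum(x) > 0 && dice(x, y) == 1) expect_identical(x, y)
  }
})

test_that("classical segmentation recovers ground truth on separable phantoms", {
  # lesion intensity well below the threshold, no noise: bone is the only
  # structure above threshold, so thresholding must reproduce it exactly
  p <- generate_phantom(phantom_spec(seed = 5, noise_sd = 0,
                                     lesion_intensity = 300, n_lesions = 2))
  got <- classical_segment_bone(p$image, intensity_threshold = 500)
  expect_identical(got$pixels, p$bone_mask$pixels)

  flat <- image_grid(matrix(10, 32, 32), 1)
  expect_equal(sum(classical_segment_bone(flat, 100)$pixels), 0)
  # filter dominance: min_region_px above every component size empties the mask
  all_small <- classical_segment_bone(p$image, 500, min_region_px = 1e6)
  expect_equal(sum(all_small$pixels), 0)
  expect_error(classical_segment_bone(flat, 100, min_region_px = 0), "min_region_px")
})

test_that("training runs, reports a held-out Dice, and handles degenerate splits", {
  pairs <- make_pairs(1:6, size = 32)
  m <- train_segmenter(pairs, tiny_train_config(epochs = 2))
  expect_s3_class(m, "calci_segmenter")
  expect_equal(m$provenance$n_val, 2)
  expect_true(is.finite(m$provenance$validation_dice))

  one <- train_segmenter(pairs[1], tiny_train_config(epochs = 1))
  expect_true(is.na(one$provenance$validation_dice))
  expect_error(train_segmenter(list(), tiny_train_config()), "empty")
})

test_that("training is reproducible for identical data, config and seed", {
  pairs <- make_pairs(1:6, size = 32)
  m1 <- train_segmenter(pairs, tiny_train_config(epochs = 2, seed = 3))
  m2 <- train_segmenter(pairs, tiny_train_config(epochs = 2, seed = 3))
  expect_identical(m1$provenance$validation_dice, m2$provenance$validation_dice)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("predicted masks shrink monotonically with the threshold", {
  pairs <- make_pairs(1:6, size = 32)
  m <- train_segmenter(pairs, tiny_train_config(epochs = 3))
  img <- pairs[[1]]$image
  lo <- predict(m, img, "mask", threshold = 0.3)$pixels
  mid <- predict(m, img, "mask", threshold = 0.5)$pixels
  hi <- predict(m, img, "mask", threshold = 0.999999)$pixels
  expect_true(all(mid <= lo))
  expect_true(all(hi <= mid))
  expect_error(predict(m, img, "mask", threshold = 1.2), "threshold")
})

test_that("a segmenter round-trips through its checkpoint with identical output", {
  pairs <- make_pairs(1:4, size = 32, n_lesions = 1)
  m <- train_segmenter(pairs, tiny_train_config(epochs = 1))
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_segmenter(m, f)
  m2 <- load_segmenter(f)
  expect_identical(predict(m, pairs[[1]]$image), predict(m2, pairs[[1]]$image))
  expect_true(file.exists(paste0(f, ".json")))
})

test_that("epoch sweep tabulates the grid and recommends the plateau start", {
  pairs <- make_pairs(1:6, size = 32)
  sw <- epoch_sweep(pairs, tiny_train_config(), epoch_grid = 2)
  expect_equal(nrow(sw$table), 1)
  expect_equal(sw$recommended, 2)
  expect_error(epoch_sweep(pairs, tiny_train_config(), integer(0)), "non-empty")
  expect_error(epoch_sweep(pairs, tiny_train_config(), c(5, 3)), "ascending")

  sw2 <- epoch_sweep(pairs, tiny_train_config(), epoch_grid = c(1, 6))
  expect_equal(nrow(sw2$table), 2)
  expect_true(all(sw2$table$val_dice >= 0 & sw2$table$val_dice <= 1))
  expect_true(sw2$recommended %in% c(1, 6))
  # the recommendation is the cheapest point on the plateau
  best <- max(sw2$table$val_dice)
  expect_equal(sw2$recommended,
               min(sw2$table$epochs[sw2$table$val_dice >= best - 0.005]))
})

test_that("visibility check flags truncated or empty masks and passes intact ones", {
  ok <- generate_phantom(phantom_spec(seed = 4))
  r1 <- check_visibility(ok$bone_mask, expected_components = 3)
  expect_true(r1$complete)
  expect_equal(r1$n_components, 3)

  tr <- generate_phantom(phantom_spec(seed = 4, truncate_phalanges = TRUE))
  r2 <- check_visibility(tr$bone_mask, expected_components = 3)
  expect_false(r2$complete)
  expect_gte(r2$components_touching_border, 1)

  r3 <- check_visibility(matrix(FALSE, 32, 32))
  expect_equal(r3$n_components, 0)
  expect_false(r3$complete)
  expect_error(check_visibility(ok$bone_mask, expected_components = 0),
               "expected_components")
})

test_that("component labelling agrees with the union-find oracle", {
  set.seed(11)
  for (i in 1:25) {
    m <- matrix(runif(16 * 16) > 0.6, 16, 16)
    for (conn in c(4, 8)) {
      got <- label_components(m, conn)
      want <- oracle_label(m, conn)
      expect_equal(max(got), max(want))
      # same partition: every label pair maps one-to-one
      if (max(got) > 0)
        expect_equal(length(unique(paste(got[m], want[m]))), max(want))
    }
  }
})
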