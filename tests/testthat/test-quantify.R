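test_that("bone subtraction floors masked pixels and leaves the rest untouched", {
  p <- generate_phantom(phantom_spec(seed = 8, n_lesions = 1))
  res <- subtract_bone(p$image, p$bone_mask, dilation_px = 0)
  floor_val <- min(p$image$pixels)
  expect_true(all(res$pixels[p$bone_mask$pixels] == floor_val))
  expect_identical(res$pixels[!p$bone_mask$pixels],
                   p$image$pixels[!p$bone_mask$pixels])
  # lesion pixels specifically are unchanged
  lp <- p$lesion_masks[[1]]$pixels
  expect_identical(res$pixels[lp], p$image$pixels[lp])

  empty <- binary_mask(matrix(FALSE, 64, 64), p$image$spacing)
  expect_identical(subtract_bone(p$image, empty)$pixels, p$image$pixels)
  full <- binary_mask(matrix(TRUE, 64, 64), p$image$spacing)
  expect_true(all(subtract_bone(p$image, full)$pixels == floor_val))
  expect_error(subtract_bone(p$image, matrix(FALSE, 8, 8)), "not aligned")
})

test_that("region growing delineates uniform blobs exactly", {
  resid <- matrix(0, 32, 32)
  resid[10:14, 10:14] <- 800                     # one 25-px uniform blob
  out <- region_grow(resid, region_grow_params())
  expect_length(out, 1)
  expect_equal(sum(out[[1]]$pixels), 25)
  expect_true(all(out[[1]]$pixels[10:14, 10:14]))

  expect_length(region_grow(matrix(100, 32, 32), region_grow_params()), 0)

  resid[20:23, 20:24] <- 700                     # second blob, separated
  out2 <- region_grow(resid, region_grow_params())
  lab <- oracle_label(resid >= 400, 8)
  sizes <- sort(tabulate(lab[lab > 0]))
  expect_equal(sort(vapply(out2, function(m) sum(m$pixels), 0L)), sizes)
})

test_that("with infinite tolerance region growing equals component labelling", {
  set.seed(21)
  params <- region_grow_params(intensity_threshold = 0.5, tolerance = Inf,
                               min_lesion_px = 1)
  for (i in 1:60) {
    m <- matrix(runif(16 * 16), 16, 16)
    got <- region_grow(m, params)
    lab <- oracle_label(m >= 0.5, 8)
    expect_length(got, max(lab))
    union <- Reduce(`|`, lapply(got, `[[`, "pixels"), matrix(FALSE, 16, 16))
    expect_identical(union, m >= 0.5)
    for (mk in got) {
      ids <- unique(lab[mk$pixels])
      expect_length(ids, 1)                       # each mask is one component
      expect_equal(sum(mk$pixels), sum(lab == ids))
    }
  }
})

test_that("region masks are disjoint, connected and ordered by size", {
  p <- generate_phantom(phantom_spec(seed = 13, n_lesions = 3))
  resid <- subtract_bone(p$image, p$bone_mask, 1)
  out <- region_grow(resid, region_grow_params(), exclude = p$bone_mask)
  expect_gte(length(out), 2)
  acc <- matrix(FALSE, 64, 64)
  sizes <- vapply(out, function(m) sum(m$pixels), 0L)
  expect_false(is.unsorted(rev(sizes)))
  for (mk in out) {
    expect_false(any(acc & mk$pixels))
    acc <- acc | mk$pixels
    expect_equal(max(label_components(mk$pixels, 8)), 1L)
  }
})

test_that("lesion area follows pixel count x spacing^2 and is additive", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(lesion_area(binary_mask(m, 0.25)), 6.25)
  expect_equal(lesion_area(binary_mask(matrix(FALSE, 4, 4), 0.25)), 0)
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_equal(lesion_area(binary_mask(one, 1)), 1)

  a <- matrix(FALSE, 10, 10); a[1:3, 1:3] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(lesion_area(binary_mask(a | b, 0.5)),
               lesion_area(binary_mask(a, 0.5)) + lesion_area(binary_mask(b, 0.5)))
})

test_that("axis measurement handles degenerate and canonical shapes", {
  row11 <- matrix(FALSE, 16, 16); row11[8, 3:13] <- TRUE
  ax <- measure_axes(binary_mask(row11, 1))
  expect_equal(ax$long_axis_mm, 10)
  expect_equal(ax$short_axis_mm, 0)
  expect_true(ax$degenerate)

  single <- matrix(FALSE, 16, 16); single[4, 4] <- TRUE
  ax1 <- measure_axes(binary_mask(single, 1))
  expect_equal(ax1$long_axis_mm, 0)
  expect_true(ax1$degenerate)

  disk <- matrix(FALSE, 25, 25)
  for (r in 1:25) for (cc in 1:25)
    if ((r - 13)^2 + (cc - 13)^2 <= 100) disk[r, cc] <- TRUE
  axd <- measure_axes(binary_mask(disk, 1))
  expect_gte(axd$long_axis_mm, 18); expect_lte(axd$long_axis_mm, 20)
  expect_lte(abs(axd$long_axis_mm - axd$short_axis_mm), 1)

  expect_error(measure_axes(binary_mask(matrix(FALSE, 4, 4), 1)), "empty")
})

test_that("axis measurement equals the exhaustive pairwise oracle", {
  set.seed(31)
  masks <- list()
  for (i in 1:6) {
    p <- generate_phantom(phantom_spec(seed = 40 + i, n_lesions = 2))
    masks <- c(masks, lapply(p$lesion_masks, `[[`, "pixels"))
  }
  for (i in 1:10) {                               # random scatter masks too
    m <- matrix(runif(400) > 0.8, 20, 20)
    if (any(m)) masks <- c(masks, list(m))
  }
  for (m in masks) {
    got <- measure_axes(binary_mask(m, 0.25))
    want <- oracle_axes(m, 0.25)
    expect_equal(got$long_axis_mm, want$long)
    expect_equal(got$short_axis_mm, want$short)
  }
})

test_that("ellipse area and ellipsoid volume follow the clinical formulas", {
  expect_equal(ellipse_area(10, 4), 10 * pi)
  expect_equal(ellipse_area(6, 6), pi * 3^2)      # circle limit
  expect_equal(ellipse_area(5, 0), 0)
  expect_error(ellipse_area(3, 5), "long axis")
  expect_error(ellipse_area(-1, -2), ">= 0")

  expect_equal(round(pi / 6, 2), 0.52)
  expect_equal(ellipsoid_volume(4, 4, 4), (4 / 3) * pi * 2^3)  # sphere limit
  expect_equal(ellipsoid_volume(3, 5, 0), 0)
  expect_error(ellipsoid_volume(-1, 2, 2), ">= 0")

  # for rasterized elliptical lesions the ellipse estimate tracks pixel area
  th <- seq(0, 2 * pi, length.out = 200)
  for (ab in list(c(10, 6), c(12, 5), c(8, 8))) {
    m <- matrix(FALSE, 31, 31)
    for (r in 1:31) for (cc in 1:31)
      if (((r - 16) / ab[2])^2 + ((cc - 16) / ab[1])^2 <= 1) m[r, cc] <- TRUE
    ax <- measure_axes(binary_mask(m, 1))
    est <- ellipse_area(ax$long_axis_mm, ax$short_axis_mm)
    expect_lt(abs(est - sum(m)) / sum(m), 0.15)
  }
})

test_that("per-image quantification gates on visibility and measures lesions", {
  tr <- generate_phantom(phantom_spec(seed = 9, truncate_phalanges = TRUE))
  q <- quantify_image(tr$image, tr$bone_mask)
  expect_s3_class(q, "visibility_failure")

  p <- generate_phantom(phantom_spec(seed = 17, n_lesions = 2))
  q2 <- quantify_image(p$image, p$bone_mask)
  expect_s3_class(q2, "lesion_measurements")
  expect_equal(nrow(q2), 2)
  expect_equal(sort(q2$area_mm2), sort(as.numeric(p$true_areas)), tolerance = 0.1)
  expect_true(all(q2$long_axis_mm >= q2$short_axis_mm))
  expect_equal(q2$ellipse_area_mm2,
               (q2$long_axis_mm / 2) * (q2$short_axis_mm / 2) * pi)
  expect_equal(q2$area_mm2, q2$pixel_count * p$image$spacing^2)

  none <- generate_phantom(phantom_spec(seed = 18, n_lesions = 0))
  q3 <- quantify_image(none$image, none$bone_mask)
  expect_equal(nrow(q3), 0)
})

test_that("pipeline lesion areas recover ground truth on seeded phantoms", {
  errs <- c()
  for (seed in 101:110) {
    p <- generate_phantom(phantom_spec(seed = seed, n_lesions = 2))
    q <- quantify_image(p$image, p$bone_mask)
    expect_s3_class(q, "lesion_measurements")
    for (i in seq_along(p$lesion_masks)) {
      truth <- p$lesion_masks[[i]]$pixels
      if (sum(truth) < 20) next
      ov <- vapply(attr(q, "masks"), function(m) sum(m$pixels & truth), 0L)
      expect_gt(max(ov), 0)
      got <- q$area_mm2[which.max(ov)]
      errs <- c(errs, abs(got - p$true_areas[i]) / p$true_areas[i])
    }
  }
  expect_gt(length(errs), 5)
  expect_lt(max(errs), 0.10)
  expect_lt(median(errs), 0.05)
})
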