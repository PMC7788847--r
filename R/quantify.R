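#' Region-growing parameters
#'
#' Controls delineation of residual calcified lesions after bone subtraction.
#' Seeds are intensity local maxima at or above `intensity_threshold`; a
#' region admits a neighbouring pixel (4- or 8-connected) when the pixel is
#' itself at or above `intensity_threshold` and within `tolerance` of the
#' current region mean (the mean is updated incrementally as pixels join).
#' Regions smaller than `min_lesion_px` are discarded as noise specks.
#' `bone_dilation_px` is the exclusion margin grown around the bone mask so
#' that the partial-intensity rim at the bone boundary can neither seed nor
#' join a lesion.
#'
#' The defaults suit the phantom intensity scale (background ~50, mineralised
#' tissue ~800, noise sd ~30): a threshold of 400 sits halfway, and a
#' tolerance of 150 (5 noise sd) keeps noisy lesion pixels in while excluding
#' background.
#'
#' @param intensity_threshold minimum intensity for seed/member candidacy.
#' @param tolerance admission band around the running region mean (>= 0;
#'   `Inf` reduces region growing to connected-component labelling of the
#'   thresholded raster).
#' @param connectivity 4 or 8 (default 8).
#' @param min_lesion_px minimum region size in pixels (>= 1).
#' @param bone_dilation_px exclusion margin around bone, in pixels (>= 0).
#' @return an object of class `region_grow_params`.
#' @export
region_grow_params <- function(intensity_threshold = 400, tolerance = 150,
                               connectivity = 8, min_lesion_px = 3,
                               bone_dilation_px = 1) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (min_lesion_px < 1) stop("min_lesion_px must be >= 1")
  if (bone_dilation_px < 0) stop("bone_dilation_px must be >= 0")
  structure(list(intensity_threshold = intensity_threshold,
                 tolerance = tolerance,
                 connectivity = as.integer(connectivity),
                 min_lesion_px = as.integer(min_lesion_px),
                 bone_dilation_px = as.integer(bone_dilation_px)),
            class = "region_grow_params")
}

#' Subtract segmented bone from an image
#'
#' Sets every pixel inside the bone mask, grown by `dilation_px`, to the
#' background floor (the image minimum by default); all other pixels pass
#' through unchanged. This is the arithmetic phalanx-removal step between
#' segmentation and lesion delineation.
#'
#' @param image a `calci_image` (or matrix).
#' @param bone_mask aligned `calci_mask` (or logical matrix).
#' @param dilation_px exclusion margin in pixels.
#' @param floor replacement intensity; defaults to `min(image)`.
#' @return same type as `image`.
#' @export
subtract_bone <- function(image, bone_mask, dilation_px = 1, floor = NULL) {
  check_aligned(image, bone_mask)
  m <- as_image_matrix(image)
  b <- dilate_mask(as_mask_matrix(bone_mask), dilation_px)
  if (is.null(floor)) floor <- min(m)
  out <- m
  out[b] <- floor
  if (inherits(image, "calci_image")) image_grid(out, image$spacing) else out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L) cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, , drop = FALSE]
}

# local maxima: pixel >= every (8-)neighbour, plateaus included
local_maxima <- function(m, connectivity = 8L) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  is_max <- matrix(TRUE, h, w)
  off <- neighbour_offsets(connectivity)
  for (k in seq_len(nrow(off))) {
    nb <- pad[(2:(h + 1L)) + off[k, 1L], (2:(w + 1L)) + off[k, 2L], drop = FALSE]
    is_max <- is_max & (m >= nb)
  }
  is_max
}

#' Delineate lesions by seeded region growing
#'
#' Seeds are local intensity maxima at or above the candidacy threshold and
#' outside the excluded zone; they are processed in descending intensity
#' (ties broken in raster order), and each grows a region by repeatedly
#' admitting neighbouring candidate pixels whose intensity lies within
#' `tolerance` of the running region mean. Pixels claimed by an earlier
#' region are never re-used, so the returned masks are pairwise disjoint.
#' Output ordering is descending pixel count, ties by centroid (row, col).
#'
#' @param residual a `calci_image` (or matrix), typically the output of
#'   [subtract_bone()].
#' @param params a [region_grow_params()].
#' @param exclude optional mask of pixels that may neither seed nor join a
#'   region (e.g. dilated bone). When `params$bone_dilation_px > 0` the
#'   exclusion mask is grown by that margin.
#' @return list of `calci_mask` objects, one per lesion (possibly empty).
#' @export
region_grow <- function(residual, params = region_grow_params(), exclude = NULL) {
  stopifnot(inherits(params, "region_grow_params"))
  m <- as_image_matrix(residual)
  sp <- spacing_of(residual)
  h <- nrow(m); w <- ncol(m)
  excl <- matrix(FALSE, h, w)
  if (!is.null(exclude)) {
    check_aligned(residual, exclude)
    excl <- dilate_mask(as_mask_matrix(exclude), params$bone_dilation_px)
  }
  candidate <- (m >= params$intensity_threshold) & !excl
  seeds <- which(local_maxima(m, params$connectivity) & candidate)
  if (!length(seeds)) return(list())
  seeds <- seeds[order(-m[seeds], seeds)]
  off <- neighbour_offsets(params$connectivity)
  claimed <- matrix(FALSE, h, w)
  regions <- list()
  for (s in seeds) {
    if (claimed[s]) next
    region <- integer(0)
    rsum <- 0
    frontier <- s
    in_front <- matrix(FALSE, h, w)
    in_front[s] <- TRUE
    while (length(frontier)) {
      q <- frontier[1L]
      frontier <- frontier[-1L]
      if (claimed[q]) next
      n_in <- length(region)
      mean_now <- if (n_in == 0L) m[q] else rsum / n_in
      if (abs(m[q] - mean_now) > params$tolerance) next
      claimed[q] <- TRUE
      region <- c(region, q)
      rsum <- rsum + m[q]
      r <- ((q - 1L) %% h) + 1L; cc <- ((q - 1L) %/% h) + 1L
      nr <- r + off[, 1L]; nc <- cc + off[, 2L]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- (nc[ok] - 1L) * h + nr[ok]
      nb <- nb[candidate[nb] & !claimed[nb] & !in_front[nb]]
      if (length(nb)) {
        in_front[nb] <- TRUE
        frontier <- c(frontier, nb)
      }
    }
    if (length(region) >= params$min_lesion_px) {
      mask <- matrix(FALSE, h, w)
      mask[region] <- TRUE
      regions[[length(regions) + 1L]] <- mask
    }
  }
  if (!length(regions)) return(list())
  sizes <- vapply(regions, sum, 0L)
  cents <- t(vapply(regions, function(mk) {
    idx <- which(mk)
    c(mean((idx - 1L) %% h), mean((idx - 1L) %/% h))
  }, c(0, 0)))
  ord <- order(-sizes, cents[, 1L], cents[, 2L])
  lapply(regions[ord], binary_mask, spacing = sp)
}

#' Lesion area in mm^2
#'
#' Pixel count times spacing squared.
#'
#' @param mask a `calci_mask` (or logical matrix with `spacing` supplied).
#' @param spacing mm/pixel; taken from the mask when it carries one.
#' @return area in mm^2.
#' @export
lesion_area <- function(mask, spacing = NULL) {
  sp <- if (inherits(mask, "calci_mask")) mask$spacing else spacing
  if (is.null(sp)) stop("mask carries no spacing; supply `spacing`")
  sum(as_mask_matrix(mask)) * sp^2
}

#' Maximal long axis and perpendicular short axis of a lesion
#'
#' The long axis is the maximum Feret diameter over foreground pixel centers
#' (maximal pairwise distance, in mm). The short axis is the extent of the
#' projection of all foreground pixel centers onto the direction
#' perpendicular to the long axis, in mm. When several pixel pairs tie for
#' the maximal distance, the lexicographically smallest pair (pixels ordered
#' by 0-based row, then column) defines the direction. A zero short axis
#' (collinear pixels) is flagged as degenerate rather than floored.
#'
#' Internally the search is restricted to the convex hull of the pixel
#' centers (the maximal pair always lies on the hull), which keeps the
#' computation fast for large lesions; the result is identical to the
#' exhaustive pairwise scan.
#'
#' @param mask non-empty `calci_mask` (or logical matrix plus `spacing`).
#' @param spacing mm/pixel; taken from the mask when it carries one.
#' @return list with `long_axis_mm`, `short_axis_mm`, `degenerate`.
#' @export
measure_axes <- function(mask, spacing = NULL) {
  sp <- if (inherits(mask, "calci_mask")) mask$spacing else spacing
  if (is.null(sp)) stop("mask carries no spacing; supply `spacing`")
  m <- as_mask_matrix(mask)
  idx <- which(m)
  if (!length(idx)) stop("cannot measure axes of an empty mask")
  h <- nrow(m)
  pts <- cbind(row = (idx - 1L) %% h, col = (idx - 1L) %/% h)  # 0-based centers
  pts <- pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE]
  if (nrow(pts) == 1L)
    return(list(long_axis_mm = 0, short_axis_mm = 0, degenerate = TRUE))
  cand <- pts
  if (nrow(pts) > 3L) {
    hull <- grDevices::chull(pts[, 2L], pts[, 1L])  # (x, y) = (col, row)
    cand <- pts[sort(hull), , drop = FALSE]
    if (nrow(cand) < 2L) cand <- pts
  }
  best <- best_pair(cand)
  d2max <- best$d2
  if (d2max == 0)
    return(list(long_axis_mm = 0, short_axis_mm = 0, degenerate = TRUE))
  v <- c(best$p2[1L] - best$p1[1L], best$p2[2L] - best$p1[2L])
  v <- v / sqrt(sum(v^2))
  perp <- c(-v[2L], v[1L])
  proj <- pts[, 1L] * perp[1L] + pts[, 2L] * perp[2L]
  long <- unname(sqrt(d2max) * sp)
  # the perpendicular extent cannot exceed the Feret diameter; min() guards
  # the floating-point tie when both are attained by the same point pair
  short <- min(unname((max(proj) - min(proj)) * sp), long)
  list(long_axis_mm = long, short_axis_mm = short, degenerate = short == 0)
}

# first pair (in lexicographic enumeration) attaining the maximal squared
# distance; pts must already be sorted by (row, col)
best_pair <- function(pts) {
  n <- nrow(pts)
  best_d2 <- -1; bi <- 1L; bj <- 1L
  for (i in seq_len(n - 1L)) {
    dr <- pts[(i + 1L):n, 1L] - pts[i, 1L]
    dc <- pts[(i + 1L):n, 2L] - pts[i, 2L]
    d2 <- dr * dr + dc * dc
    k <- which.max(d2)
    if (d2[k] > best_d2) {
      best_d2 <- d2[k]; bi <- i; bj <- i + k
    }
  }
  list(d2 = best_d2, p1 = pts[bi, ], p2 = pts[bj, ])
}

#' Ellipse-estimate area from axis lengths
#'
#' The radiologists' manual estimate: `long/2 * short/2 * pi`, assuming the
#' lesion is elliptical.
#'
#' @param long_axis_mm,short_axis_mm axis lengths in mm, `long >= short >= 0`.
#' @return estimated area in mm^2.
#' @export
ellipse_area <- function(long_axis_mm, short_axis_mm) {
  if (any(long_axis_mm < 0) || any(short_axis_mm < 0))
    stop("axis lengths must be >= 0")
  if (any(long_axis_mm < short_axis_mm))
    stop("long axis must be >= short axis")
  (long_axis_mm / 2) * (short_axis_mm / 2) * pi
}

#' Ellipsoid volume from three orthogonal diameters
#'
#' `(pi/6) * d1 * d2 * d3`; the constant pi/6 is the familiar 0.52
#' multiplication factor used clinically for volume estimation (e.g. in
#' prostate measurement).
#'
#' @param d1_mm,d2_mm,d3_mm orthogonal diameters in mm, all >= 0.
#' @return volume in mm^3.
#' @export
ellipsoid_volume <- function(d1_mm, d2_mm, d3_mm) {
  if (any(c(d1_mm, d2_mm, d3_mm) < 0)) stop("diameters must be >= 0")
  (pi / 6) * d1_mm * d2_mm * d3_mm
}

#' Quantify calcified lesions in one image
#'
#' Full per-image stage composition: check that the phalanges are completely
#' visualized (see [check_visibility()]); if not, return a visibility-failure
#' marker and measure nothing — callers must count and skip such images.
#' Otherwise subtract the bone, grow lesion regions, and assemble one
#' measurement row per lesion: pixel count, area in mm^2, maximal long axis,
#' perpendicular short axis, ellipse-estimate area, centroid and degeneracy
#' flag.
#'
#' @param image a `calci_image`.
#' @param bone_mask aligned bone `calci_mask` (from a segmenter or ground
#'   truth).
#' @param params a [region_grow_params()].
#' @param expected_components number of phalanges expected (default 3).
#' @param border_margin_px border margin for the visibility check.
#' @return a `data.frame` of class `lesion_measurements` (possibly 0-row)
#'   with attribute `masks` (the lesion masks), or an object of class
#'   `visibility_failure` carrying the [check_visibility()] report.
#' @export
quantify_image <- function(image, bone_mask, params = region_grow_params(),
                           expected_components = 3, border_margin_px = 1) {
  check_aligned(image, bone_mask)
  vis <- check_visibility(bone_mask, expected_components, border_margin_px)
  if (!vis$complete)
    return(structure(list(report = vis), class = "visibility_failure"))
  sp <- spacing_of(image)
  residual <- subtract_bone(image, bone_mask, params$bone_dilation_px)
  masks <- region_grow(residual, params, exclude = bone_mask)
  rows <- lapply(seq_along(masks), function(i) {
    mk <- masks[[i]]
    ax <- measure_axes(mk)
    idx <- which(mk$pixels)
    h <- nrow(mk$pixels)
    data.frame(lesion_id = i,
               pixel_count = length(idx),
               area_mm2 = lesion_area(mk),
               long_axis_mm = ax$long_axis_mm,
               short_axis_mm = ax$short_axis_mm,
               ellipse_area_mm2 = ellipse_area(ax$long_axis_mm, ax$short_axis_mm),
               centroid_row = mean((idx - 1L) %% h),
               centroid_col = mean((idx - 1L) %/% h),
               degenerate = ax$degenerate)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lesion_id = integer(0), pixel_count = integer(0),
               area_mm2 = numeric(0), long_axis_mm = numeric(0),
               short_axis_mm = numeric(0), ellipse_area_mm2 = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               degenerate = logical(0))
  attr(out, "masks") <- masks
  attr(out, "spacing") <- sp
  class(out) <- c("lesion_measurements", "data.frame")
  out
}

#' @export
print.visibility_failure <- function(x, ...) {
  cat(sprintf(paste0("<visibility_failure> phalanges incompletely visualized: ",
                     "%d component(s), %d touching the border margin\n"),
              x$report$n_components, x$report$components_touching_border))
  invisible(x)
}
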