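#' Specification for a synthetic finger phantom
#'
#' Describes a sagittal finger image emulating a bone-window DECT reformat:
#' three bright elongated phalanges arranged end-to-end along the vertical
#' (finger) axis with joint gaps, plus 0-3 irregular bright calcinosis cutis
#' lesions adjacent to bone. Bone and lesion intensities overlap by default
#' (both are calcium hydroxyapatite in the real images), so the phases cannot
#' be separated by intensity alone and a shape-aware segmenter is genuinely
#' required.
#'
#' Intensities are pseudo-HU on a bone-window-friendly scale: soft-tissue
#' background ~50, mineralised bone and lesions ~800. The default spacing of
#' 0.25 mm/pixel is typical of high-resolution extremity CT reformats.
#'
#' @param height,width image size in pixels (>= 16 each).
#' @param spacing mm per pixel.
#' @param n_phalanges number of bone segments along the finger axis.
#' @param bone_intensity,lesion_intensity,background_intensity mean intensities.
#' @param noise_sd standard deviation of the additive Gaussian noise applied
#'   to the image (never to the ground-truth masks).
#' @param n_lesions number of lesions, 0-3.
#' @param lesion_radius_range (min, max) mean lesion radius in mm.
#' @param lesion_irregularity radius jitter fraction in [0, 1]; 0 gives discs,
#'   larger values give increasingly irregular star-convex blobs.
#' @param truncate_phalanges if TRUE, the finger is shifted so that at least
#'   one phalanx is clipped by the image border (the incomplete-visualization
#'   failure mode that quantification must detect and skip).
#' @param seed integer seed driving all randomness for this phantom; no global
#'   random state is consumed or altered.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64, spacing = 0.25,
                         n_phalanges = 3,
                         bone_intensity = 800, lesion_intensity = 800,
                         background_intensity = 50, noise_sd = 30,
                         n_lesions = 2, lesion_radius_range = c(0.5, 1.5),
                         lesion_irregularity = 0.4,
                         truncate_phalanges = FALSE, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               spacing = spacing, n_phalanges = as.integer(n_phalanges),
               bone_intensity = bone_intensity,
               lesion_intensity = lesion_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd, n_lesions = as.integer(n_lesions),
               lesion_radius_range = as.numeric(lesion_radius_range),
               lesion_irregularity = lesion_irregularity,
               truncate_phalanges = isTRUE(truncate_phalanges),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  stopifnot(s$height >= 16L, s$width >= 16L, s$spacing > 0,
            s$n_phalanges >= 1L, s$noise_sd >= 0,
            s$n_lesions >= 0L, s$n_lesions <= 3L)
  if (s$lesion_intensity <= s$background_intensity)
    stop("lesion_intensity must exceed background_intensity")
  if (s$bone_intensity <= s$background_intensity)
    stop("bone_intensity must exceed background_intensity")
  if (length(s$lesion_radius_range) != 2L ||
      s$lesion_radius_range[1] > s$lesion_radius_range[2] ||
      s$lesion_radius_range[1] <= 0)
    stop("lesion_radius_range must be (min, max) with 0 < min <= max")
  if (s$lesion_irregularity < 0 || s$lesion_irregularity > 1)
    stop("lesion_irregularity must be in [0, 1]")
  invisible(s)
}

# Run `expr` under a private RNG stream; the caller's .Random.seed survives.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rasterize a star-convex blob: K-vertex radius function r(theta) with linear
# interpolation between vertices; a pixel center is inside iff its distance to
# the blob center is <= r(its angle). Gives pixel-exact ground truth.
rasterize_blob <- function(h, w, center, mean_radius_px, irregularity, k = 9L) {
  radii <- mean_radius_px * (1 + irregularity * stats::runif(k, -1, 1))
  radii <- pmax(radii, 0.75)
  theta0 <- stats::runif(1, 0, 2 * pi)
  rows <- matrix(seq_len(h) - 1L, h, w)
  cols <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  dy <- rows - center[1]; dx <- cols - center[2]
  ang <- (atan2(dy, dx) - theta0) %% (2 * pi)
  seg <- 2 * pi / k
  i0 <- pmin(floor(ang / seg), k - 1)
  frac <- ang / seg - i0
  r_at <- radii[i0 + 1] * (1 - frac) + radii[(i0 + 1) %% k + 1] * frac
  sqrt(dy^2 + dx^2) <= r_at
}

# Capsule (rounded rectangle) footprint used for a phalanx.
rasterize_capsule <- function(h, w, r0, r1, c_mid, half_width) {
  rows <- matrix(seq_len(h) - 1L, h, w)
  cols <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  # distance from pixel center to the vertical segment (r0..r1, c_mid)
  ry <- pmin(pmax(rows, r0), r1)
  sqrt((rows - ry)^2 + (cols - c_mid)^2) <= half_width
}

#' Generate a synthetic finger phantom with ground truth
#'
#' Deterministic for a fixed spec (including its seed). The returned ground
#' truth is noise-free: the bone mask and per-lesion masks are exact pixel
#' sets, each true area is its mask's pixel count times spacing squared, and
#' lesions are disjoint from bone (separated by at least one background pixel,
#' yet within 2 px of it). The image receives additive Gaussian noise last
#' and is rounded/clamped to integer intensities in [0, 4095] so that 16-bit
#' file round trips are lossless.
#'
#' @param spec a [phantom_spec()].
#' @param max_attempts placement attempts per lesion before giving up.
#' @return an object of class `phantom_sample`: fields `image` (`calci_image`),
#'   `bone_mask` (`calci_mask`), `lesion_masks` (list of `calci_mask`),
#'   `true_areas` (mm^2), and `spec`.
#' @export
generate_phantom <- function(spec, max_attempts = 200L) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, generate_phantom_impl(spec, max_attempts))
}

generate_phantom_impl <- function(spec, max_attempts) {
  h <- spec$height; w <- spec$width
  n_ph <- spec$n_phalanges

  # --- phalanges: capsules end-to-end along the row (finger) axis ---
  total <- round(0.84 * h)
  gaps <- round(stats::runif(n_ph - 1, 0.03, 0.05) * h)
  seg_len <- rep((total - sum(gaps)) / n_ph, n_ph)
  # distal phalanx shorter, proximal longer, as in a real finger
  if (n_ph >= 2) {
    prop <- seq(0.75, 1.25, length.out = n_ph)
    seg_len <- (total - sum(gaps)) * prop / sum(prop)
  }
  top <- round(stats::runif(1, 0.05, 0.11) * h)
  if (spec$truncate_phalanges) top <- -round(stats::runif(1, 0.4, 0.7) * seg_len[1])
  c_mid <- (w - 1) / 2 + stats::runif(1, -0.05, 0.05) * w
  bone <- matrix(FALSE, h, w)
  r_cur <- top
  for (i in seq_len(n_ph)) {
    half_w <- stats::runif(1, 0.055, 0.075) * w
    jitter_c <- c_mid + stats::runif(1, -0.02, 0.02) * w
    r_end <- r_cur + seg_len[i] - 1
    cap <- rasterize_capsule(h, w, r_cur + half_w, r_end - half_w, jitter_c, half_w)
    bone <- bone | cap
    r_cur <- r_end + if (i < n_ph) gaps[i] else 0
  }
  if (!any(bone)) stop("degenerate phantom: no bone pixels (spec too small?)")

  # --- lesions: star-convex blobs near (but not touching) bone ---
  # forbidden zone: bone grown by 1 px keeps a 1-px soft-tissue rim so a
  # 1-px bone exclusion margin downstream never eats lesion pixels
  near1 <- dilate_mask(bone, 1)
  near2 <- dilate_mask(bone, 2)   # "within 2 px" adjacency band
  lesion_masks <- list()
  lesion_all <- matrix(FALSE, h, w)
  min_r_px <- spec$lesion_radius_range[1] / spec$spacing
  max_r_px <- spec$lesion_radius_range[2] / spec$spacing
  border_ok <- matrix(FALSE, h, w)
  border_ok[3:(h - 2), 3:(w - 2)] <- TRUE
  band <- which(near2 & !near1 & border_ok)
  for (li in seq_len(spec$n_lesions)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      r_px <- stats::runif(1, min_r_px, max_r_px)
      anchor <- band[sample.int(length(band), 1L)]
      ar <- ((anchor - 1L) %% h); ac <- ((anchor - 1L) %/% h)
      # push the center outward from bone so most of the blob clears the rim
      dir <- c(ar, ac) - c((nrow(bone) - 1) / 2, (ncol(bone) - 1) / 2)
      nrm <- sqrt(sum(dir^2)); if (nrm < 1e-9) dir <- c(0, 1) else dir <- dir / nrm
      center <- c(ar, ac) + dir * r_px * stats::runif(1, 0.5, 0.9)
      blob <- rasterize_blob(h, w, center, r_px, spec$lesion_irregularity)
      blob <- blob & !near1 & border_ok          # disjoint from bone + rim
      # lesions keep a 2-px gap from each other so they never merge under
      # 8-connected delineation
      if (any(lesion_all) && any(blob & dilate_mask(lesion_all, 2))) next
      lab <- label_components(blob, 8)
      if (max(lab) == 0L) next
      # keep the component nearest the anchor (clipping can split the blob)
      sizes <- tabulate(lab[lab > 0L])
      keep <- which.max(sizes)
      blob <- lab == keep
      if (sum(blob) < 5L) next
      if (!any(blob & near2)) next               # must stay within 2 px of bone
      lesion_masks[[li]] <- blob
      lesion_all <- lesion_all | blob
      placed <- TRUE
      break
    }
    if (!placed)
      stop("lesion placement failed: could not place lesion ", li,
           " without overlapping bone after ", max_attempts, " attempts")
  }

  img <- matrix(spec$background_intensity, h, w)
  img[bone] <- spec$bone_intensity
  if (any(lesion_all)) img[lesion_all] <- spec$lesion_intensity
  # gentle intra-bone texture so the bone is not perfectly flat
  img[bone] <- img[bone] + 0.06 * spec$bone_intensity *
    sin(6 * pi * (which(bone) %% h) / h)
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
  img <- round(pmin(pmax(img, 0), 4095))

  structure(list(
    image = image_grid(img, spec$spacing),
    bone_mask = binary_mask(bone, spec$spacing),
    lesion_masks = lapply(lesion_masks, binary_mask, spacing = spec$spacing),
    true_areas = vapply(lesion_masks, function(m) sum(m) * spec$spacing^2, 0),
    spec = spec
  ), class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf(paste0("<phantom_sample> %d x %d px @ %.3g mm/px, %d phalanges, ",
                     "%d lesion(s)%s\n"),
              nrow(x$image$pixels), ncol(x$image$pixels), x$image$spacing,
              x$spec$n_phalanges, length(x$lesion_masks),
              if (x$spec$truncate_phalanges) " [truncated]" else ""))
  if (length(x$true_areas))
    cat("  true lesion areas (mm^2):", paste(sprintf("%.3f", x$true_areas),
                                             collapse = ", "), "\n")
  invisible(x)
}

rotate90 <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

# nearest-neighbour rotation about the raster center by `deg` degrees
rotate_nn <- function(m, deg) {
  h <- nrow(m); w <- ncol(m)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  th <- -deg * pi / 180
  rows <- matrix(seq_len(h) - 1L, h, w) - cy
  cols <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE) - cx
  sr <- round(cy + rows * cos(th) - cols * sin(th)) + 1L
  sc <- round(cx + rows * sin(th) + cols * cos(th)) + 1L
  out <- matrix(if (is.logical(m)) FALSE else 0, h, w)
  ok <- sr >= 1L & sr <= h & sc >= 1L & sc <= w
  out[ok] <- m[cbind(sr[ok], sc[ok])]
  out
}

#' Rotation augmentation of image/mask pairs
#'
#' Expands a supervised segmentation dataset by spatially rotating each
#' image/mask pair `n_rotations` times; image and mask are always rotated
#' jointly. The originals are preserved at the head of the output, so the
#' output length is `length(pairs) * (1 + n_rotations)` (30 pairs with 3
#' rotations give 90 additional pairs, 120 in total).
#'
#' With `method = "right-angle"` (default, up to 3 rotations) the angles are
#' 90/180/270 degrees: lossless on a square raster, masks stay pixel-exact.
#' With `method = "arbitrary"` the angles are evenly spaced in (0, 360) and
#' both rasters are resampled nearest-neighbour.
#'
#' @param pairs list of `list(image =, mask =)` pairs (`calci_image` /
#'   `calci_mask` or plain matrices).
#' @param n_rotations rotations per pair, >= 0.
#' @param method "right-angle" or "arbitrary".
#' @return augmented list of pairs, originals first.
#' @export
rotate_augment <- function(pairs, n_rotations = 3, method = c("right-angle", "arbitrary")) {
  method <- match.arg(method)
  if (n_rotations < 0) stop("n_rotations must be >= 0")
  n_rotations <- as.integer(n_rotations)
  for (p in pairs) check_aligned(p$image, p$mask)
  if (n_rotations == 0L) return(pairs)
  if (method == "right-angle" && n_rotations > 3L)
    stop("right-angle mode supports at most 3 rotations (90/180/270); ",
         "use method = \"arbitrary\" for more")
  out <- pairs
  for (k in seq_len(n_rotations)) {
    ang <- 360 * k / (n_rotations + 1)
    rot <- lapply(pairs, function(p) {
      im <- as_image_matrix(p$image); mk <- as_mask_matrix(p$mask)
      if (method == "right-angle") {
        im2 <- rotate90(im, k); mk2 <- rotate90(mk, k)
      } else {
        im2 <- rotate_nn(im, ang); mk2 <- rotate_nn(mk, ang)
      }
      sp <- spacing_of(p$image)
      list(image = if (inherits(p$image, "calci_image")) image_grid(im2, sp) else im2,
           mask = if (inherits(p$mask, "calci_mask")) binary_mask(mk2, sp) else mk2)
    })
    out <- c(out, rot)
  }
  out
}
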