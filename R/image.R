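#' Image grid with physical pixel spacing
#'
#' The unit all pipeline stages share: a 2D scalar intensity raster
#' (interpretable as pseudo-HU) together with an isotropic pixel spacing in
#' mm/pixel. Pixels are stored row-major with the origin at the top-left and
#' 0-based pixel indices used in all geometric conventions (a pixel's center
#' sits at its 0-based (row, col) coordinate).
#'
#' @param pixels numeric matrix of intensities; all values must be finite.
#' @param spacing mm per pixel (isotropic), strictly positive.
#' @return an object of class `calci_image` with fields `pixels` and `spacing`.
#' @export
image_grid <- function(pixels, spacing) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("`spacing` must be a single positive number (mm/pixel)")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image must be at least 16 x 16 pixels")
  if (!all(is.finite(pixels)))
    stop("all image intensities must be finite")
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "calci_image")
}

#' Binary mask aligned to an image grid
#'
#' @param pixels logical matrix (or coercible 0/1 matrix).
#' @param spacing mm per pixel, matching the parent image.
#' @return an object of class `calci_mask` with fields `pixels` and `spacing`.
#' @export
binary_mask <- function(pixels, spacing) {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("mask values must be logical or 0/1")
    pixels <- pixels > 0
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("`spacing` must be a single positive number (mm/pixel)")
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "calci_mask")
}

as_mask_matrix <- function(x) {
  if (inherits(x, "calci_mask")) x$pixels else {
    m <- as.matrix(x)
    if (!is.logical(m)) m <- m > 0
    m
  }
}

as_image_matrix <- function(x) {
  if (inherits(x, "calci_image")) x$pixels else as.matrix(x)
}

spacing_of <- function(x, default = 1) {
  if (is.list(x) && !is.null(x$spacing)) x$spacing else default
}

as_raster_matrix <- function(x) {
  if (inherits(x, "calci_mask")) x$pixels
  else if (inherits(x, "calci_image")) x$pixels
  else as.matrix(x)
}

check_aligned <- function(a, b) {
  da <- dim(as_raster_matrix(a)); db <- dim(as_raster_matrix(b))
  if (!identical(da, db))
    stop(sprintf("rasters are not aligned: %dx%d vs %dx%d",
                 da[1], da[2], db[1], db[2]))
  sa <- spacing_of(a, NA); sb <- spacing_of(b, NA)
  if (is.finite(sa) && is.finite(sb) && !isTRUE(all.equal(sa, sb)))
    stop("pixel spacings differ between rasters")
  invisible(TRUE)
}

#' @export
print.calci_image <- function(x, ...) {
  cat(sprintf("<calci_image> %d x %d px, %.4g mm/px, intensity [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.calci_mask <- function(x, ...) {
  cat(sprintf("<calci_mask> %d x %d px, %.4g mm/px, %d foreground px (%.2f mm^2)\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing, sum(x$pixels),
              sum(x$pixels) * x$spacing^2))
  invisible(x)
}

#' @export
plot.calci_image <- function(x, window = NULL, level = NULL, ...) {
  m <- x$pixels
  if (!is.null(window)) m <- apply_window(x, window, level)$pixels
  m <- (m - min(m)) / max(max(m) - min(m), .Machine$double.eps)
  # image() draws column-major from bottom-left; flip so row 1 is at the top
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' Window/level display mapping
#'
#' Radiology display transform: intensities at or below `level - window/2`
#' map to 0, at or above `level + window/2` map to 1, linear in between.
#' The defaults are a bone window (window 1500, level 450).
#'
#' @param image a `calci_image` or numeric matrix.
#' @param window window width in intensity units; must be positive.
#' @param level window center.
#' @return a `calci_image` with intensities in [0, 1] (or a matrix when the
#'   input was a matrix).
#' @export
apply_window <- function(image, window = 1500, level = 450) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) || window <= 0)
    stop("`window` must be a single positive number")
  m <- as_image_matrix(image)
  out <- pmin(pmax((m - (level - window / 2)) / window, 0), 1)
  if (inherits(image, "calci_image")) image_grid(out, image$spacing) else out
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 * |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary masks (`calci_mask` or logical matrices) of equal shape.
#' @return a scalar in [0, 1].
#' @export
dice <- function(a, b) {
  ma <- as_mask_matrix(a); mb <- as_mask_matrix(b)
  if (!identical(dim(ma), dim(mb))) stop("mask shapes differ")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma & mb) / (sa + sb)
}

#' Label connected components of a binary mask
#'
#' Two-pass flood labelling with configurable connectivity. Component ids are
#' assigned in raster-scan order (top-left first).
#'
#' @param mask a `calci_mask` or logical matrix.
#' @param connectivity 4 or 8 (default 8, the package-wide convention).
#' @return an integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- as_mask_matrix(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  off <- if (connectivity == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, , drop = FALSE]
  }
  nxt <- 0L
  fg <- which(m)
  for (p in fg) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((q - 1L) %% h) + 1L
      cc <- ((q - 1L) %/% h) + 1L
      nr <- r + off[, 1L]; nc <- cc + off[, 2L]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- (nc[ok] - 1L) * h + nr[ok]
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Dilate a binary mask by a Chebyshev radius
#'
#' Morphological dilation with a (2r+1) x (2r+1) box structuring element,
#' i.e. growth by `r` pixels in the 8-connected sense.
#'
#' @param mask a `calci_mask` or logical matrix.
#' @param r dilation radius in pixels (0 returns the input unchanged).
#' @return same type as the input.
#' @export
dilate_mask <- function(mask, r = 1) {
  if (r < 0) stop("dilation radius must be >= 0")
  m <- as_mask_matrix(mask)
  if (r > 0 && any(m)) {
    brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "box")
    m <- EBImage::dilate(m * 1, brush) > 0
  }
  if (inherits(mask, "calci_mask")) binary_mask(m, mask$spacing) else m
}

fill_holes <- function(m) {
  EBImage::fillHull(m * 1) > 0
}
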