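# Independent oracles used across the suite. These deliberately use
# different algorithms from the package internals they check.

# Two-pass union-find connected-component labelling (row-scan with label
# merging), independent of the package's BFS labelling and of region growing.
oracle_label <- function(m, connectivity = 8) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(w)) for (r in seq_len(h)) {
    if (!m[r, cc]) next
    nbs <- integer(0)
    if (r > 1 && m[r - 1, cc]) nbs <- c(nbs, lab[r - 1, cc])
    if (cc > 1 && m[r, cc - 1]) nbs <- c(nbs, lab[r, cc - 1])
    if (connectivity == 8 && cc > 1) {
      if (r > 1 && m[r - 1, cc - 1]) nbs <- c(nbs, lab[r - 1, cc - 1])
      if (r < h && m[r + 1, cc - 1]) nbs <- c(nbs, lab[r + 1, cc - 1])
    }
    if (!length(nbs)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, cc] <- nxt
    } else {
      roots <- vapply(nbs, find, 0L)
      keep <- min(roots)
      lab[r, cc] <- keep
      for (rt in roots) parent[rt] <- keep
    }
  }
  # resolve and relabel compactly in raster order of first appearance
  out <- matrix(0L, h, w)
  seen <- integer(0)
  for (cc in seq_len(w)) for (r in seq_len(h)) {
    if (!m[r, cc]) next
    rt <- find(lab[r, cc])
    k <- match(rt, seen)
    if (is.na(k)) { seen <- c(seen, rt); k <- length(seen) }
    out[r, cc] <- k
  }
  out
}

# Exhaustive O(n^2) axes oracle over pixel centers: first lexicographic pair
# (points ordered by 0-based row then col) attaining the maximal distance
# defines the long-axis direction; short axis is the perpendicular extent.
oracle_axes <- function(mask_mat, spacing) {
  idx <- which(mask_mat)
  h <- nrow(mask_mat)
  pts <- cbind((idx - 1L) %% h, (idx - 1L) %/% h)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(pts)
  if (n == 1) return(list(long = 0, short = 0))
  best <- -1; bi <- 1L; bj <- 2L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d2 <- (pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2
    if (d2 > best) { best <- d2; bi <- i; bj <- j }
  }
  if (best == 0) return(list(long = 0, short = 0))
  v <- pts[bj, ] - pts[bi, ]
  v <- v / sqrt(sum(v^2))
  proj <- pts[, 1] * (-v[2]) + pts[, 2] * v[1]
  long <- sqrt(best) * spacing
  # same definitional bound as the implementation: short <= long
  list(long = long, short = min((max(proj) - min(proj)) * spacing, long))
}

# a batch of image/bone-mask training pairs from seeded phantoms
make_pairs <- function(seeds, size = 64, n_lesions = NULL, ...) {
  lapply(seeds, function(i) {
    nl <- if (is.null(n_lesions)) (i %% 4L) else n_lesions
    p <- generate_phantom(phantom_spec(height = size, width = size,
                                       seed = i, n_lesions = nl, ...))
    list(image = p$image, mask = p$bone_mask)
  })
}

tiny_train_config <- function(epochs = 2, seed = 0) {
  train_config(epochs = epochs, depth = 2, base_channels = 4, batch_size = 4,
               validation_fraction = 0.34, seed = seed)
}
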