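#' Training configuration for the phalanx segmenter
#'
#' @param epochs number of full passes over the training images (>= 1). The
#'   full-scale setting reported for real finger images is 500 epochs; the
#'   default here is sized for the 64x64 phantoms, where the network
#'   plateaus far earlier.
#' @param learning_rate Adam step size.
#' @param batch_size images per gradient step.
#' @param depth number of down/up-sampling levels (>= 1).
#' @param base_channels channels of the first encoder block; doubled at each
#'   level.
#' @param loss "dice", "cross-entropy", or "sum" (both added; default).
#' @param validation_fraction fraction of the dataset held out for the
#'   validation Dice, in [0, 1).
#' @param seed integer seed for weight init, the held-out split and epoch
#'   shuffling; training is reproducible given the seed (same BLAS/threads).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 30, learning_rate = 1e-3, batch_size = 8,
                         depth = 3, base_channels = 8,
                         loss = c("sum", "dice", "cross-entropy"),
                         validation_fraction = 0.15, seed = 0L) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, depth >= 1, learning_rate > 0, batch_size >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels), loss = loss,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

pad_to_multiple <- function(m, mult, value = 0) {
  h <- nrow(m); w <- ncol(m)
  H <- as.integer(ceiling(h / mult) * mult)
  W <- as.integer(ceiling(w / mult) * mult)
  if (H == h && W == w) return(m)
  out <- matrix(value, H, W)
  out[seq_len(h), seq_len(w)] <- m
  out
}

# index tables for every pyramid level at a given batch size, cached
build_tabs <- function(h, w, depth, batch, cache) {
  key <- paste(h, w, depth, batch, sep = "_")
  if (exists(key, envir = cache, inherits = FALSE))
    return(get(key, envir = cache))
  conv <- vector("list", depth + 1L)
  pool <- vector("list", depth)
  n <- vector("list", depth + 1L)
  hh <- h; ww <- w
  for (i in seq_len(depth + 1L)) {
    conv[[i]] <- conv_indices(hh, ww, batch)
    n[[i]] <- batch * hh * ww
    if (i <= depth) {
      pool[[i]] <- pool_indices(hh, ww, batch)
      hh <- hh %/% 2L; ww <- ww %/% 2L
    }
  }
  tabs <- list(conv = conv, pool = pool, n = n)
  cache[[key]] <- tabs
  tabs
}

prep_input <- function(image, mult, window = 1500, level = 450) {
  m <- apply_window(as_image_matrix(image), window, level)
  pad_to_multiple(m, mult, 0)
}

dataset_fingerprint <- function(dataset) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(lapply(dataset, function(p)
    list(i = as_image_matrix(p$image), m = as_mask_matrix(p$mask))), f)
  unname(tools::md5sum(f))
}

#' Train the encoder-decoder phalanx segmenter
#'
#' Fits a small U-shaped convolutional network (3x3 convolutions with ReLU,
#' 2x2 max pooling, nearest-neighbour upsampling, skip concatenations, 1x1
#' sigmoid output head) to image/mask pairs with the Adam optimiser. Inputs
#' are rendered through the bone display window (window 1500, level 450)
#' before entering the network, and padded to a multiple of `2^depth` when
#' needed.
#'
#' A `validation_fraction` of the pairs is held out (chosen by the config
#' seed); the final held-out Dice at threshold 0.5 is stored in the model's
#' provenance (`NA` when the split yields no validation images).
#'
#' @param dataset non-empty list of `list(image =, mask =)` pairs, all
#'   shape-aligned.
#' @param config a [train_config()].
#' @return an object of class `calci_segmenter`; see [predict.calci_segmenter()].
#' @export
train_segmenter <- function(dataset, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (!length(dataset)) stop("dataset is empty")
  dims <- dim(as_image_matrix(dataset[[1]]$image))
  for (p in dataset) {
    check_aligned(p$image, p$mask)
    if (!identical(dim(as_image_matrix(p$image)), dims))
      stop("all dataset pairs must share one raster shape")
  }
  with_seed(config$seed, train_segmenter_impl(dataset, config, dims))
}

train_segmenter_impl <- function(dataset, config, dims) {
  mult <- 2L^config$depth
  n <- length(dataset)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop("validation split leaves no training images")

  X <- lapply(dataset, function(p) prep_input(p$image, mult))
  Tm <- lapply(dataset, function(p)
    as.numeric(pad_to_multiple(as_mask_matrix(p$mask) * 1, mult, 0)))
  H <- nrow(X[[1]]); W <- ncol(X[[1]])
  npx <- H * W

  par <- unet_params(config$depth, config$base_channels)
  opt <- adam_init(par)
  cache <- new.env(parent = emptyenv())
  history <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; n_batches <- 0L
    while (length(ord)) {
      take <- seq_len(min(config$batch_size, length(ord)))
      bidx <- ord[take]; ord <- ord[-take]
      B <- length(bidx)
      tabs <- build_tabs(H, W, config$depth, B, cache)
      xb <- matrix(unlist(X[bidx], use.names = FALSE), ncol = 1L)
      tb <- unlist(Tm[bidx], use.names = FALSE)
      fw <- unet_forward(par, xb, tabs)
      ls <- seg_loss(fw$z, tb, npx, config$loss)
      if (!is.finite(ls$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      g <- unet_backward(par, fw, ls$dz, tabs)
      st <- adam_step(par, g, opt, config$learning_rate)
      par <- st$par; opt <- st$opt
      ep_loss <- ep_loss + ls$loss; n_batches <- n_batches + 1L
    }
    history[ep] <- ep_loss / n_batches
  }

  model <- structure(list(par = par, config = config,
                          input = list(window = 1500, level = 450, mult = mult),
                          loss_history = history),
                     class = "calci_segmenter")
  val_dice <- NA_real_
  if (length(val_idx)) {
    val_dice <- mean(vapply(val_idx, function(i) {
      pred <- predict_matrix(model, as_image_matrix(dataset[[i]]$image)) >= 0.5
      dice(pred, as_mask_matrix(dataset[[i]]$mask))
    }, 0))
  }
  model$provenance <- list(
    n_train = length(tr_idx), n_val = length(val_idx),
    validation_dice = val_dice,
    dataset_fingerprint = dataset_fingerprint(dataset),
    raster = dims)
  model
}

predict_matrix <- function(model, m) {
  h <- nrow(m); w <- ncol(m)
  x <- prep_input(m, model$input$mult, model$input$window, model$input$level)
  cache <- new.env(parent = emptyenv())
  tabs <- build_tabs(nrow(x), ncol(x), model$config$depth, 1L, cache)
  fw <- unet_forward(model$par, matrix(as.vector(x), ncol = 1L), tabs)
  p <- matrix(sigmoid(fw$z), nrow(x), ncol(x))
  p[seq_len(h), seq_len(w), drop = FALSE]
}

#' Predict foreground probabilities or a bone mask
#'
#' @param object a trained `calci_segmenter`.
#' @param image a `calci_image` or matrix.
#' @param type "prob" for the probability map, "mask" for a thresholded
#'   `calci_mask`.
#' @param threshold probability cut in (0, 1) for `type = "mask"`.
#' @param ... unused.
#' @return numeric matrix of probabilities, or a `calci_mask`.
#' @export
predict.calci_segmenter <- function(object, image, type = c("prob", "mask"),
                                    threshold = 0.5, ...) {
  type <- match.arg(type)
  m <- as_image_matrix(image)
  if (!all(is.finite(m))) stop("image intensities must be finite")
  p <- predict_matrix(object, m)
  if (type == "prob") return(p)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  binary_mask(p >= threshold, spacing_of(image))
}

#' Segment healthy phalanges with a trained model
#'
#' Thin wrapper over [predict.calci_segmenter()]: pixels whose predicted
#' foreground probability reaches `threshold` become mask foreground.
#'
#' @inheritParams predict.calci_segmenter
#' @param model a trained `calci_segmenter`.
#' @return a `calci_mask` aligned to the image.
#' @export
segment_bone <- function(image, model, threshold = 0.5) {
  predict(model, image, type = "mask", threshold = threshold)
}

#' @export
print.calci_segmenter <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("<calci_segmenter> depth %d, base %d channels, %d epochs (loss: %s)\n",
              x$config$depth, x$config$base_channels, x$config$epochs,
              x$config$loss))
  cat(sprintf("  trained on %d images (%d held out), validation Dice %s\n",
              pv$n_train, pv$n_val,
              if (is.na(pv$validation_dice)) "unavailable"
              else sprintf("%.3f", pv$validation_dice)))
  invisible(x)
}

#' @export
summary.calci_segmenter <- function(object, ...) {
  print(object)
  cat(sprintf("  final training loss %.4f (epoch 1: %.4f)\n",
              utils::tail(object$loss_history, 1), object$loss_history[1]))
  cat(sprintf("  dataset fingerprint %s\n", object$provenance$dataset_fingerprint))
  invisible(object)
}

#' Save / load a trained segmenter
#'
#' The checkpoint is a single serialized file; a JSON provenance sidecar
#' (`<path>.json`) records the config and validation Dice for audit.
#'
#' @param model a `calci_segmenter`.
#' @param path checkpoint file path.
#' @return `save_segmenter` returns `path` invisibly; `load_segmenter`
#'   returns the model.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "calci_segmenter"))
  saveRDS(model, path)
  jsonlite::write_json(c(model$provenance[c("n_train", "n_val",
                                            "validation_dice",
                                            "dataset_fingerprint")],
                         unclass(model$config)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "calci_segmenter"))
  model
}

#' Sweep the training length and recommend an epoch count
#'
#' Trains one model per grid point (same data, same config otherwise) and
#' records the held-out Dice. The recommended count is the smallest epoch
#' count whose Dice is within `tolerance` of the sweep maximum — an
#' automated, reproducible proxy for choosing the training length by visual
#' inspection of segmentations between runs.
#'
#' @param dataset as in [train_segmenter()].
#' @param config a [train_config()]; its `epochs` field is overridden.
#' @param epoch_grid ascending epoch counts to evaluate (non-empty).
#' @param tolerance Dice slack defining the plateau (default 0.005).
#' @return an object of class `epoch_sweep`: `$table` (epochs, val_dice) and
#'   `$recommended`.
#' @export
epoch_sweep <- function(dataset, config = train_config(), epoch_grid,
                        tolerance = 0.005) {
  if (!length(epoch_grid)) stop("epoch_grid must be non-empty")
  if (is.unsorted(epoch_grid, strictly = TRUE))
    stop("epoch_grid must be sorted ascending")
  rows <- lapply(epoch_grid, function(ep) {
    cfg <- config; cfg$epochs <- as.integer(ep)
    m <- train_segmenter(dataset, cfg)
    data.frame(epochs = ep, val_dice = m$provenance$validation_dice)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$val_dice)))
    stop("no validation images: cannot recommend an epoch count")
  best <- max(tab$val_dice, na.rm = TRUE)
  rec <- tab$epochs[which(tab$val_dice >= best - tolerance)[1]]
  structure(list(table = tab, recommended = rec, tolerance = tolerance),
            class = "epoch_sweep")
}

#' @export
print.epoch_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("recommended epochs: %d (plateau within %.3f of max Dice)\n",
              x$recommended, x$tolerance))
  invisible(x)
}

#' Classical intensity-threshold bone segmentation
#'
#' CPU-cheap baseline: threshold the image, label 8-connected components,
#' drop components smaller than `min_region_px`, fill internal holes. On a
#' noise-free image whose bone intensity is separable from everything else
#' this reproduces the ground-truth bone mask exactly.
#'
#' @param image a `calci_image` or matrix.
#' @param intensity_threshold pixels at or above this value are candidates.
#' @param min_region_px minimum component size in pixels (>= 1).
#' @return a `calci_mask`.
#' @export
classical_segment_bone <- function(image, intensity_threshold, min_region_px = 20) {
  if (min_region_px < 1) stop("min_region_px must be >= 1")
  m <- as_image_matrix(image)
  fg <- m >= intensity_threshold
  lab <- label_components(fg, 8)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_region_px)
    fg <- matrix(lab %in% keep, nrow(m), ncol(m))
    if (any(fg)) fg <- fill_holes(fg)
  } else {
    fg <- matrix(FALSE, nrow(m), ncol(m))
  }
  binary_mask(fg, spacing_of(image))
}

#' Check that the phalanges are completely visualized
#'
#' The quantification stages must be skipped on images where the phalanges
#' are incompletely visualized (e.g. clipped by the image border). An image
#' is complete when the bone mask has at least `expected_components`
#' 8-connected components and none of them intersects the border margin.
#'
#' @param bone_mask a `calci_mask` or logical matrix.
#' @param expected_components phalanges expected (>= 1; default 3).
#' @param border_margin_px width of the border band a component must not
#'   touch (default 1).
#' @return an object of class `visibility_report`: `n_components`,
#'   `components_touching_border`, `complete`.
#' @export
check_visibility <- function(bone_mask, expected_components = 3,
                             border_margin_px = 1) {
  if (expected_components < 1) stop("expected_components must be >= 1")
  m <- as_mask_matrix(bone_mask)
  lab <- label_components(m, 8)
  ncomp <- max(lab)
  touching <- 0L
  if (ncomp > 0L && border_margin_px > 0) {
    h <- nrow(m); w <- ncol(m)
    band <- matrix(FALSE, h, w)
    mg <- min(border_margin_px, floor(min(h, w) / 2))
    band[c(seq_len(mg), h - seq_len(mg) + 1L), ] <- TRUE
    band[, c(seq_len(mg), w - seq_len(mg) + 1L)] <- TRUE
    touching <- length(unique(lab[band & lab > 0L]))
  }
  structure(list(n_components = ncomp,
                 components_touching_border = touching,
                 complete = ncomp >= expected_components && touching == 0L),
            class = "visibility_report")
}

#' @export
print.visibility_report <- function(x, ...) {
  cat(sprintf("<visibility_report> %d component(s), %d touching border -> %s\n",
              x$n_components, x$components_touching_border,
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}
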