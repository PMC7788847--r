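#' Write phantom samples to a directory
#'
#' One sample becomes `sample_###_image.tif` (16-bit TIFF; quantitative
#' pixels, lossless for the generator's integer intensities in [0, 4095]),
#' `sample_###_bone.png` and `sample_###_lesion_##.png` (8-bit masks with
#' values 0/255), and a JSON sidecar `sample_###_meta.json` holding
#' `spacing_mm`, `n_lesions`, `true_areas_mm2`, `truncated` and `seed`.
#'
#' @param samples list of `phantom_sample` objects.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of sample prefixes written.
#' @export
write_dataset <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefixes <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stopifnot(inherits(s, "phantom_sample"))
    pre <- file.path(dir, sprintf("sample_%03d", i))
    prefixes[i] <- pre
    px <- s$image$pixels
    if (min(px) < 0 || max(px) > 65535)
      stop("image intensities outside [0, 65535] cannot be written as 16-bit TIFF")
    tiff::writeTIFF(px / 65535, paste0(pre, "_image.tif"),
                    bits.per.sample = 16L, compression = "none")
    png::writePNG(s$bone_mask$pixels * 1, paste0(pre, "_bone.png"))
    for (j in seq_along(s$lesion_masks))
      png::writePNG(s$lesion_masks[[j]]$pixels * 1,
                    sprintf("%s_lesion_%02d.png", pre, j))
    meta <- list(spacing_mm = s$image$spacing,
                 n_lesions = length(s$lesion_masks),
                 true_areas_mm2 = as.numeric(s$true_areas),
                 truncated = isTRUE(s$spec$truncate_phalanges),
                 seed = s$spec$seed)
    jsonlite::write_json(meta, paste0(pre, "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(basename(prefixes))
}

read_mask_png <- function(path, spacing) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  binary_mask(m > 0.5, spacing)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' The round trip is lossless for masks, spacing and true areas, and for
#' image pixels whenever they are integers in [0, 65535] (as produced by
#' [generate_phantom()]).
#'
#' @param dir directory containing `sample_###_*` files.
#' @return list of `phantom_sample`-like objects (field `spec` carries only
#'   what the sidecar records: truncation flag and seed).
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "^sample_[0-9]+_image\\.tif$",
                          full.names = TRUE))
  if (!length(imgs)) stop("no samples found in ", dir)
  lapply(imgs, function(f) {
    pre <- sub("_image\\.tif$", "", f)
    meta_path <- paste0(pre, "_meta.json")
    if (!file.exists(meta_path))
      stop("metadata sidecar missing for ", basename(pre),
           " (expected ", basename(meta_path), ")")
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    px <- tiff::readTIFF(f)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    img <- image_grid(round(px * 65535), meta$spacing_mm)
    bone <- read_mask_png(paste0(pre, "_bone.png"), meta$spacing_mm)
    check_aligned(img, bone)
    lesion_files <- sort(list.files(dir, full.names = TRUE,
      pattern = paste0("^", basename(pre), "_lesion_[0-9]+\\.png$")))
    lesions <- lapply(lesion_files, read_mask_png, spacing = meta$spacing_mm)
    for (lm in lesions) check_aligned(img, lm)
    if (length(lesions) != meta$n_lesions)
      stop("sidecar reports ", meta$n_lesions, " lesions but ",
           length(lesions), " mask files found for ", basename(pre))
    structure(list(image = img, bone_mask = bone, lesion_masks = lesions,
                   true_areas = as.numeric(meta$true_areas_mm2),
                   spec = list(truncate_phalanges = isTRUE(meta$truncated),
                               seed = meta$seed, spacing = meta$spacing_mm)),
              class = "phantom_sample")
  })
}
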