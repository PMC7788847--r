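#' Configuration for a full synthetic study run
#'
#' Mirrors the study design of the real-image experiment: 40 generated
#' finger images split 30/10 into training and test sets, training images
#' rotation-augmented three times (120 training inputs), a segmenter trained
#' on the augmented set, and lesions quantified on the test set. The two
#' "raters" compared in the agreement analysis are the two area estimators
#' the pipeline itself produces per lesion: the region-growing pixel-count
#' area and the ellipse estimate from the measured axes.
#'
#' @param n_train,n_test split sizes (positive).
#' @param n_rotations rotations per training image (default 3).
#' @param n_truncated_test how many test phantoms are generated with clipped
#'   phalanges (they must be flagged and excluded downstream; default 0).
#' @param phantom named list of [phantom_spec()] overrides applied to every
#'   generated sample (e.g. `list(noise_sd = 40)`); `seed`, `n_lesions` and
#'   `truncate_phalanges` are managed by the run.
#' @param train a [train_config()].
#' @param grow a [region_grow_params()].
#' @param alpha significance level for the agreement analysis.
#' @param seed master seed; every stage derives its own stream from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_train = 30, n_test = 10, n_rotations = 3,
                       n_truncated_test = 0, phantom = list(),
                       train = train_config(), grow = region_grow_params(),
                       alpha = 0.05, seed = 42L) {
  stopifnot(n_train >= 1, n_test >= 1, n_rotations >= 0,
            n_truncated_test >= 0, n_truncated_test <= n_test,
            inherits(train, "train_config"),
            inherits(grow, "region_grow_params"))
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_rotations = as.integer(n_rotations),
                 n_truncated_test = as.integer(n_truncated_test),
                 phantom = phantom, train = train, grow = grow,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; `train` and `grow` are
#' nested maps passed to [train_config()] / [region_grow_params()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("train", "grow"))]
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$grow)) args$grow <- do.call(region_grow_params, y$grow)
  do.call(run_config, args)
}

derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

study_phantom <- function(config, seed, n_lesions, truncated = FALSE) {
  args <- config$phantom
  args$seed <- seed
  args$n_lesions <- n_lesions
  args$truncate_phalanges <- truncated
  generate_phantom(do.call(phantom_spec, args))
}

file_md5 <- function(paths) {
  x <- tools::md5sum(paths)
  stats::setNames(unname(x), basename(paths))
}

#' Run the full synthetic study end to end
#'
#' Generate phantoms, split into training and test sets, rotation-augment
#' the training set, train the segmenter, segment and quantify every test
#' image (skipping and counting images whose phalanges are incompletely
#' visualized), and compare the two per-lesion area estimators with the
#' three-part agreement analysis. All artifacts (datasets, model checkpoint,
#' per-lesion CSV, run summary, agreement plots, manifest) are written under
#' `out_dir`; the run is reproducible from the master seed.
#'
#' Every generated phantom contains 1-3 lesions (the study images all showed
#' clinically evident calcinosis); the per-sample lesion count and phantom
#' seeds derive from the master seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress per-stage messages.
#' @return an object of class `run_manifest` (invisibly also written as
#'   `manifest.json`): config snapshot, per-stage counts, artifact
#'   checksums, the agreement result and the measurement table.
#' @export
run_study <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop("out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  n_all <- config$n_train + config$n_test
  seeds <- derive_seeds(config$seed, n_all + 1L)
  lesion_counts <- with_seed(seeds[n_all + 1L],
                             sample(1:3, n_all, replace = TRUE))

  say("stage generate: %d phantoms (%d train / %d test, %d truncated in test)",
      n_all, config$n_train, config$n_test, config$n_truncated_test)
  stage <- "generate"
  manifest <- list(config = serialize_config(config),
                   started = format(t_start, tz = "UTC"), stages = list())
  result <- try({
    train_samples <- lapply(seq_len(config$n_train), function(i)
      study_phantom(config, seeds[i], lesion_counts[i]))
    trunc_flags <- rep(FALSE, config$n_test)
    if (config$n_truncated_test > 0)
      trunc_flags[seq_len(config$n_truncated_test)] <- TRUE
    test_samples <- lapply(seq_len(config$n_test), function(i) {
      j <- config$n_train + i
      study_phantom(config, seeds[j], lesion_counts[j], trunc_flags[i])
    })
    write_dataset(train_samples, file.path(out_dir, "train"))
    write_dataset(test_samples, file.path(out_dir, "test"))
    manifest$stages$generate <- list(
      n_generated = n_all, n_train = config$n_train, n_test = config$n_test,
      n_truncated_test = config$n_truncated_test,
      checksums = file_md5(list.files(file.path(out_dir, "train"),
                                      full.names = TRUE)))

    stage <- "augment"
    pairs <- lapply(train_samples, function(s)
      list(image = s$image, mask = s$bone_mask))
    aug <- rotate_augment(pairs, config$n_rotations)
    say("stage augment: %d -> %d training pairs", length(pairs), length(aug))
    manifest$stages$augment <- list(n_input = length(pairs),
                                    n_augmented = length(aug),
                                    n_additional = length(aug) - length(pairs))

    stage <- "train"
    say("stage train: %d epochs on %d pairs", config$train$epochs, length(aug))
    model <- train_segmenter(aug, config$train)
    ckpt <- file.path(out_dir, "model.ckpt")
    save_segmenter(model, ckpt)
    manifest$stages$train <- list(
      epochs = config$train$epochs,
      validation_dice = model$provenance$validation_dice,
      checksums = file_md5(ckpt))

    stage <- "quantify"
    rows <- list(); fail_ids <- character(0)
    for (i in seq_along(test_samples)) {
      s <- test_samples[[i]]
      id <- sprintf("test_%03d", i)
      bone <- segment_bone(s$image, model)
      q <- quantify_image(s$image, bone, config$grow)
      if (inherits(q, "visibility_failure")) {
        fail_ids <- c(fail_ids, id)
        next
      }
      if (nrow(q))
        rows[[length(rows) + 1L]] <- cbind(image_id = id, q,
                                           visibility_complete = TRUE)
    }
    meas <- if (length(rows)) do.call(rbind, rows) else NULL
    csv <- file.path(out_dir, "measurements.csv")
    utils::write.csv(as.data.frame(meas), csv, row.names = FALSE)
    summary_json <- file.path(out_dir, "run_summary.json")
    jsonlite::write_json(list(n_images = length(test_samples),
                              n_failed = length(fail_ids),
                              failure_ids = fail_ids),
                         summary_json, auto_unbox = TRUE, digits = NA)
    say("stage quantify: %d of %d images excluded (incomplete phalanges), %d lesions measured",
        length(fail_ids), length(test_samples),
        if (is.null(meas)) 0L else nrow(meas))
    manifest$stages$quantify <- list(
      n_attempted = length(test_samples), n_failed = length(fail_ids),
      failure_ids = fail_ids,
      n_lesions = if (is.null(meas)) 0L else nrow(meas),
      checksums = file_md5(c(csv, summary_json)))

    stage <- "validate"
    agreement <- NULL
    if (!is.null(meas) && nrow(meas) >= 3) {
      series <- paired_series(meas$area_mm2, meas$ellipse_area_mm2,
                              paste(meas$image_id, meas$lesion_id, sep = ":"))
      agreement <- validate_agreement(series, alpha = config$alpha,
                                      plot_dir = file.path(out_dir, "report"))
      manifest$stages$validate <- list(
        n_pairs = agreement$n, spearman_rho = agreement$spearman_rho,
        ccc = agreement$ccc, bias = agreement$bias,
        checksums = file_md5(list.files(file.path(out_dir, "report"),
                                        full.names = TRUE)))
    } else {
      manifest$stages$validate <- list(n_pairs = 0L,
                                       note = "fewer than 3 lesions; agreement skipped")
    }
    list(meas = meas, agreement = agreement, model = model)
  }, silent = TRUE)

  if (inherits(result, "try-error")) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(attr(result, "condition"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("run_study failed at stage '", stage, "': ", manifest$error)
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  out <- structure(c(manifest,
                     list(measurements = result$meas,
                          agreement = result$agreement)),
                   class = "run_manifest")
  json_copy <- manifest
  jsonlite::write_json(json_copy, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

serialize_config <- function(config) {
  list(n_train = config$n_train, n_test = config$n_test,
       n_rotations = config$n_rotations,
       n_truncated_test = config$n_truncated_test,
       phantom = config$phantom, train = unclass(config$train),
       grow = unclass(config$grow), alpha = config$alpha, seed = config$seed)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(report(x), sep = "\n")
  invisible(x)
}

#' Human-readable study report
#'
#' Summarizes counts per stage, the held-out segmentation Dice, the failure
#' tally ("k of n images not amenable"), and the three agreement statistics.
#'
#' @param manifest a `run_manifest` from [run_study()].
#' @param agreement optionally, an `agreement_result` overriding the one in
#'   the manifest.
#' @return character vector of report lines (also printed).
#' @export
report <- function(manifest, agreement = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (is.null(agreement)) agreement <- manifest$agreement
  st <- manifest$stages
  lines <- c(
    sprintf("images generated: %d (%d train / %d test)",
            st$generate$n_generated, st$generate$n_train, st$generate$n_test),
    sprintf("training inputs after x%d rotation augmentation: %d (%d additional)",
            manifest$config$n_rotations, st$augment$n_augmented,
            st$augment$n_additional),
    sprintf("segmenter: %d epochs, held-out Dice %s", st$train$epochs,
            if (is.na(st$train$validation_dice)) "unavailable"
            else sprintf("%.3f", st$train$validation_dice)),
    sprintf("%d of %d test images not amenable (incomplete phalange visualization)",
            st$quantify$n_failed, st$quantify$n_attempted),
    sprintf("lesions measured: %d", st$quantify$n_lesions))
  if (!is.null(agreement)) {
    lines <- c(lines,
      sprintf("agreement (region-growing vs ellipse estimate, %d lesions):",
              agreement$n),
      sprintf("  Spearman rho %.3f (p = %.3g)", agreement$spearman_rho,
              agreement$spearman_p),
      sprintf("  Lin's CCC %.3f (95%% CI %.3f-%.3f)", agreement$ccc,
              agreement$ccc_ci_low, agreement$ccc_ci_high),
      sprintf("  Bland-Altman bias %.3f mm^2 (95%% LoA %.3f to %.3f)",
              agreement$bias, agreement$loa_low, agreement$loa_high))
  } else {
    lines <- c(lines, "no lesions detected; agreement section omitted")
  }
  lines
}
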