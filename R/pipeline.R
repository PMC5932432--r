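# End-to-end orchestration: scales -> oriented filter-bank responses ->
# feature matrix + labels -> fusion network -> thresholded mask -> metrics.

#' Pipeline configuration
#'
#' Resolves either a named preset or explicit filter parameters, plus the
#' fusion-network architecture, training configuration, thresholding choice
#' and evaluation options, into one serializable run description.
#'
#' @param preset preset name passed to [gmf_preset()]; ignored when
#'   `sigmas` is given.
#' @param sigmas optional explicit scale list (overrides the preset).
#' @param L,T,kappa template parameters when `sigmas` is given.
#' @param hidden hidden-layer sizes of the fusion network.
#' @param use_ann fuse scales with the network (default). With `FALSE` and
#'   a single scale, the raw matched-filter response is used directly (the
#'   single-scale baseline path).
#' @param training a [training_config()].
#' @param threshold_method default binarization method (see
#'   [threshold_methods()]).
#' @param threshold_params a [local_params()] for local methods.
#' @param n_thresholds ROC sweep resolution.
#' @param stability_runs number of extra seeded retrainings whose test A_z
#'   spread is reported (0 disables).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "mgmf", sigmas = NULL, L = 13L, T = 15L,
                            kappa = 12L, hidden = c(3L, 8L), use_ann = TRUE,
                            training = training_config(),
                            threshold_method = "otsu",
                            threshold_params = local_params(),
                            n_thresholds = 256L, stability_runs = 0L) {
  if (is.null(sigmas)) {
    p <- gmf_preset(preset)
    sigmas <- p$sigmas; L <- p$L; T <- p$T; kappa <- p$kappa
  } else {
    preset <- "custom"
  }
  threshold_method <- match.arg(threshold_method, threshold_methods())
  if (!use_ann && length(sigmas) > 1L) {
    stop("`use_ann = FALSE` requires a single scale")
  }
  structure(
    list(preset = preset, sigmas = as.numeric(sigmas), L = as.integer(L),
         T = as.integer(T), kappa = as.integer(kappa),
         hidden = as.integer(hidden), use_ann = use_ann,
         training = training, threshold_method = threshold_method,
         threshold_params = threshold_params,
         n_thresholds = as.integer(n_thresholds),
         stability_runs = as.integer(stability_runs)),
    class = "pipeline_config"
  )
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$training <- unclass(out$training)
  out$threshold_params <- unclass(out$threshold_params)
  out$version <- as.character(utils::packageVersion("mgmf"))
  out
}

#' Write the resolved configuration next to a run's outputs
#' @param cfg a `pipeline_config`.
#' @param out_dir directory to write `resolved_config.yaml` into.
#' @return the file path, invisibly.
#' @export
write_resolved_config <- function(cfg, out_dir) {
  path <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(config_as_list(cfg), path)
  invisible(path)
}

# Load an image/mask dataset from a directory: manifest.csv when present,
# otherwise "<name>.png" images paired with "<name>_mask.png".
load_dataset <- function(dataset_dir) {
  mf <- file.path(dataset_dir, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  } else {
    imgs <- sort(list.files(dataset_dir, pattern = "\\.(png|pgm|tif|tiff)$"))
    imgs <- imgs[!grepl("_mask\\.", imgs)]
    masks <- sub("\\.(png|pgm|tif|tiff)$", "_mask.\\1", imgs)
    manifest <- data.frame(image = imgs, mask = masks,
                           stringsAsFactors = FALSE)
  }
  manifest <- manifest[order(manifest$image), , drop = FALSE]
  missing <- !file.exists(file.path(dataset_dir, manifest$mask))
  if (any(missing)) {
    stop("missing masks: ", paste(manifest$mask[missing], collapse = ", "))
  }
  list(
    images = lapply(file.path(dataset_dir, manifest$image), read_image),
    masks = lapply(file.path(dataset_dir, manifest$mask), read_mask),
    manifest = manifest
  )
}

#' Compute detection responses for a set of images
#'
#' Runs [multiscale_response()] and, unless `cfg$use_ann` is off, the
#' fusion network on every image.
#'
#' @param images list of image matrices (or a directory path).
#' @param model a trained `network_model`, or `NULL` for the raw
#'   single-scale path.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; responses are written as 8-bit PNG
#'   previews plus full-precision `.rds` sidecars.
#' @return list of response matrices.
#' @export
run_detect <- function(images, model = NULL, cfg = pipeline_config(),
                       out_dir = NULL) {
  if (is.character(images)) images <- load_dataset(images)$images
  if (!is.null(model) &&
      model$architecture$n_inputs != length(cfg$sigmas)) {
    stop("model inputs (", model$architecture$n_inputs,
         ") != configured scale count (", length(cfg$sigmas), ")")
  }
  if (is.null(model) && cfg$use_ann) {
    stop("`use_ann` is set but no model was given")
  }
  responses <- lapply(images, function(img) {
    stack <- multiscale_response(img, cfg$sigmas, cfg$L, cfg$T, cfg$kappa)
    if (is.null(model)) stack$responses[[1L]] else predict_image(model, stack)
  })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_along(responses)) {
      r <- responses[[i]]
      rng <- range(r)
      prev <- if (diff(rng) > 0) (r - rng[1L]) / diff(rng) else r * 0
      write_image(prev, file.path(out_dir, sprintf("response_%03d.png", i)))
      saveRDS(r, file.path(out_dir, sprintf("response_%03d.rds", i)))
    }
    write_resolved_config(cfg, out_dir)
  }
  responses
}

#' Binarize a set of detection responses
#'
#' @param responses list of response matrices (or a directory of `.rds`
#'   sidecars written by [run_detect()]).
#' @param cfg a [pipeline_config()]; supplies method and parameters.
#' @param out_dir optional directory for `mask_###.png` outputs.
#' @return list of logical masks.
#' @export
run_segment <- function(responses, cfg = pipeline_config(), out_dir = NULL) {
  if (is.character(responses)) {
    files <- sort(list.files(responses, pattern = "^response_.*\\.rds$",
                             full.names = TRUE))
    responses <- lapply(files, readRDS)
  }
  masks <- lapply(responses, segment, method = cfg$threshold_method,
                  params = cfg$threshold_params)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_along(masks)) {
      write_mask(masks[[i]], file.path(out_dir, sprintf("mask_%03d.png", i)))
    }
    write_resolved_config(cfg, out_dir)
  }
  masks
}

#' Run a full detection/segmentation experiment on a dataset
#'
#' Splits the dataset 50/50 by sorted filename parity (odd positions train,
#' even positions test), trains the fusion network on the training half,
#' and reports pooled and per-image-mean A_z for both halves, the accuracy
#' of all ten thresholding methods on the test responses, per-scale
#' single-filter baseline A_z values, and (optionally) the spread of test
#' A_z over repeated seeded retrainings. Rerunning with the same
#' configuration reproduces the report byte-identically.
#'
#' @param dataset_dir directory with images, masks and optional
#'   `manifest.csv` (see [generate_dataset()]).
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory: `report.json`,
#'   `threshold_accuracy.csv`, `resolved_config.yaml`.
#' @return the report as a list.
#' @export
run_experiment <- function(dataset_dir, cfg = pipeline_config(),
                           out_dir = NULL) {
  ds <- load_dataset(dataset_dir)
  n <- length(ds$images)
  if (n < 2L) stop("experiment needs at least 2 images")
  idx_train <- seq(1L, n, by = 2L)
  idx_test <- seq(2L, n, by = 2L)
  stacks <- lapply(ds$images, function(img)
    multiscale_response(img, cfg$sigmas, cfg$L, cfg$T, cfg$kappa))
  tr_stacks <- stacks[idx_train]; te_stacks <- stacks[idx_test]
  tr_masks <- ds$masks[idx_train]; te_masks <- ds$masks[idx_test]

  if (cfg$use_ann) {
    arch <- network_architecture(length(cfg$sigmas), cfg$hidden)
    model <- train_network(tr_stacks, tr_masks, arch, cfg$training)
    tr_resp <- lapply(tr_stacks, function(s) predict_image(model, s))
    te_resp <- lapply(te_stacks, function(s) predict_image(model, s))
  } else {
    model <- NULL
    tr_resp <- lapply(tr_stacks, function(s) s$responses[[1L]])
    te_resp <- lapply(te_stacks, function(s) s$responses[[1L]])
  }

  nt <- cfg$n_thresholds
  report <- list(
    dataset = list(n_images = n, n_train = length(idx_train),
                   n_test = length(idx_test),
                   train_images = ds$manifest$image[idx_train],
                   test_images = ds$manifest$image[idx_test]),
    detection = list(
      train_az_pooled = dataset_auc(tr_resp, tr_masks, nt),
      test_az_pooled = dataset_auc(te_resp, te_masks, nt),
      train_az_mean = dataset_auc(tr_resp, tr_masks, nt, pool = FALSE),
      test_az_mean = dataset_auc(te_resp, te_masks, nt, pool = FALSE)
    )
  )

  # Per-scale single-filter baselines on the test half.
  report$single_scale <- data.frame(
    sigma = cfg$sigmas,
    test_az_pooled = vapply(seq_along(cfg$sigmas), function(k) {
      dataset_auc(lapply(te_stacks, function(s) s$responses[[k]]),
                  te_masks, nt)
    }, numeric(1)))

  # Threshold-method comparison on the test responses.
  acc_tab <- vapply(threshold_methods(), function(m) {
    accs <- vapply(seq_along(te_resp), function(i) {
      msk <- suppressWarnings(
        segment(te_resp[[i]], m, cfg$threshold_params))
      accuracy(confusion(msk, te_masks[[i]]))
    }, numeric(1))
    c(mean = mean(accs), min = min(accs), max = max(accs))
  }, numeric(3))
  report$threshold_accuracy <- data.frame(
    method = colnames(acc_tab), t(acc_tab), row.names = NULL)
  report$default_threshold <- list(
    method = cfg$threshold_method,
    test_accuracy_mean =
      report$threshold_accuracy$mean[
        report$threshold_accuracy$method == cfg$threshold_method])

  if (cfg$use_ann && cfg$stability_runs > 0L) {
    azs <- vapply(seq_len(cfg$stability_runs), function(k) {
      tc <- cfg$training; tc$seed <- cfg$training$seed + k - 1L
      m_k <- train_network(tr_stacks, tr_masks,
                           network_architecture(length(cfg$sigmas), cfg$hidden),
                           tc)
      dataset_auc(lapply(te_stacks, function(s) predict_image(m_k, s)),
                  te_masks, nt)
    }, numeric(1))
    report$stability <- list(
      runs = cfg$stability_runs, max = max(azs), min = min(azs),
      mean = mean(azs), sd = stats::sd(azs), median = stats::median(azs),
      values = azs)
  }

  report$config <- config_as_list(cfg)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         digits = I(12), auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
    utils::write.csv(report$threshold_accuracy,
                     file.path(out_dir, "threshold_accuracy.csv"),
                     row.names = FALSE)
    write_resolved_config(cfg, out_dir)
  }
  if (cfg$use_ann) attr(report, "model") <- model
  report
}
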