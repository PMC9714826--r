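# End-to-end pipeline: preprocessing, feature extraction, ensemble fusion,
# postprocessing, and the leave-one-out evaluation harness.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline. Defaults are the
#' package's standard desk-scale settings.
#'
#' @param block_size Neighbouring-slice block size (1, 3 or 5).
#' @param tau Classification threshold on the infarct probability L.
#' @param cell_size Evaluation cell edge (majority-rule subsampling).
#' @param label_positive Which perfusion classes count as infarct when
#'   collapsing labels (`"core+penumbra"` or `"core"`).
#' @param features A [feature_config()].
#' @param extractor_specs List of [extractor_spec()]s for the deep feature
#'   maps (default three variants).
#' @param extractor_epochs,f4_epochs,ensemble_epochs Training epochs.
#' @param extractor_sample_frac,ensemble_sample_frac Fraction of training
#'   slices/blocks each epoch visits (stochastic subsampling).
#' @param extractor_lr,f4_lr,ensemble_lr Learning rates.
#' @param bone_hu,air_hu Skull-stripping thresholds.
#' @param postprocess Apply hemisphere selection to predictions.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(block_size = 3, tau = 0.5, cell_size = 32,
                            label_positive = "core+penumbra",
                            features = feature_config(),
                            extractor_specs = default_extractor_specs(),
                            extractor_epochs = 4, f4_epochs = 20,
                            ensemble_epochs = 3, extractor_lr = 2e-3,
                            extractor_sample_frac = 0.4,
                            ensemble_sample_frac = 0.6,
                            f4_lr = 1e-3, ensemble_lr = 2e-3,
                            bone_hu = 300, air_hu = -200,
                            postprocess = TRUE) {
  structure(list(block_size = block_size, tau = tau, cell_size = cell_size,
                 label_positive = label_positive, features = features,
                 extractor_specs = extractor_specs,
                 extractor_epochs = extractor_epochs, f4_epochs = f4_epochs,
                 ensemble_epochs = ensemble_epochs,
                 extractor_sample_frac = extractor_sample_frac,
                 ensemble_sample_frac = ensemble_sample_frac,
                 extractor_lr = extractor_lr, f4_lr = f4_lr,
                 ensemble_lr = ensemble_lr, bone_hu = bone_hu,
                 air_hu = air_hu, postprocess = postprocess),
            class = "pipeline_config")
}

#' Prepare a case for training or prediction
#'
#' Runs preprocessing (brain masks, hull registration, label transfer,
#' class collapsing) and precomputes the hand-crafted per-pixel feature
#' maps. Idempotent: already-prepared cases are returned unchanged.
#'
#' @param case List with `ct` ([ct_volume]) and `labels` ([label_map] in the
#'   perfusion frame); optionally `truth` (3-D 0/1 ground-truth lesion mask
#'   in the CT frame, used for evaluation when present).
#' @param config A [pipeline_config()].
#' @return The case augmented with `mask`, `labels3`, `transform` and `hc`
#'   (per-slice hand-crafted feature arrays).
#' @export
prepare_case <- function(case, config = pipeline_config()) {
  if (!is.null(case$prepared) && isTRUE(case$prepared)) return(case)
  pp <- preprocess_case(case$ct, case$labels, bone_hu = config$bone_hu,
                        air_hu = config$air_hu)
  case$mask <- pp$mask
  case$transform <- pp$transform
  case$labels3 <- collapse_labels(pp$labels_ct, pp$mask,
                                  positive = config$label_positive)
  k <- dim(case$ct$slices)[3]
  case$hc <- lapply(seq_len(k), function(i)
    assemble_pixel_features(case$ct$slices[, , i], case$mask[, , i],
                            config$features))
  case$prepared <- TRUE
  case
}

#' Train the full model stack on a set of cases
#'
#' Trains the three deep feature extractors, the pixel-wise F4 network and
#' the ensemble, in that order, all from `seed`-derived sub-seeds.
#'
#' @param cases List of prepared cases ([prepare_case()]).
#' @param config A [pipeline_config()].
#' @param seed Integer seed controlling every stochastic step.
#' @return A `pipeline_models` list.
#' @export
train_pipeline <- function(cases, config = pipeline_config(), seed = 1L) {
  cases <- lapply(cases, prepare_case, config = config)
  extractors <- vector("list", length(config$extractor_specs))
  for (i in seq_along(extractors)) {
    spec <- config$extractor_specs[[i]]
    spec$seed <- derive_seed(seed, spec$seed)
    extractors[[i]] <- train_extractor(spec, cases,
                                       epochs = config$extractor_epochs,
                                       lr = config$extractor_lr,
                                       sample_frac = config$extractor_sample_frac)
  }
  hc_all <- list(); lab_all <- list(); msk_all <- list()
  for (case in cases) {
    for (k in seq_len(dim(case$ct$slices)[3])) {
      hc_all[[length(hc_all) + 1]] <- case$hc[[k]]
      lab_all[[length(lab_all) + 1]] <- case$labels3[, , k]
      msk_all[[length(msk_all) + 1]] <- case$mask[, , k]
    }
  }
  f4 <- train_pixel_net(hc_all, lab_all, msk_all, config = config$features,
                        epochs = config$f4_epochs, lr = config$f4_lr,
                        seed = derive_seed(seed, 4L))
  models <- list(extractors = extractors, f4 = f4, config = config)
  blocks <- list(); blab <- list(); bmask <- list()
  for (case in cases) {
    feats <- case_feature_maps(models, case)
    for (k in seq_along(feats)) {
      blocks[[length(blocks) + 1]] <-
        build_input_block(feats, k, config$block_size)
      blab[[length(blab) + 1]] <- case$labels3[, , k]
      bmask[[length(bmask) + 1]] <- case$mask[, , k]
    }
  }
  set.seed(derive_seed(seed, 5L))
  models$ensemble <- train_ensemble(blocks, blab, bmask,
                                    epochs = config$ensemble_epochs,
                                    lr = config$ensemble_lr,
                                    sample_frac = config$ensemble_sample_frac,
                                    seed = derive_seed(seed, 5L))
  structure(models, class = "pipeline_models")
}

#' Compute the per-slice feature maps of a case
#'
#' @param models A `pipeline_models` (at least extractors and f4).
#' @param case A prepared case.
#' @return List (per slice) of named matrices `F1, F2, F3, F4, h`.
#' @export
case_feature_maps <- function(models, case) {
  k <- dim(case$ct$slices)[3]
  lapply(seq_len(k), function(i) {
    sl <- case$ct$slices[, , i]
    msk <- case$mask[, , i]
    out <- list()
    for (j in seq_along(models$extractors))
      out[[paste0("F", j)]] <- extract_feature_map(models$extractors[[j]],
                                                   sl, msk)
    out$F4 <- predict_f4(models$f4, sl, msk, features = case$hc[[i]])
    out$h <- (msk > 0) * 1
    out
  })
}

#' Predict the infarct mask for a case
#'
#' @param models Trained [train_pipeline()] models.
#' @param case A prepared case.
#' @return List: `L` (3-D infarct-probability array), `pred_raw`
#'   (thresholded), `pred` (after hemisphere selection if configured),
#'   `side` (hemisphere kept), `features` (per-slice feature maps).
#' @export
predict_case <- function(models, case) {
  config <- models$config
  case <- prepare_case(case, config)
  feats <- case_feature_maps(models, case)
  pv <- predict_volume(models$ensemble, feats, config$block_size)
  pred_raw <- threshold_probability(pv$L, config$tau, mask = case$mask)
  if (config$postprocess) {
    mid <- mask_midline(case$mask)
    pred <- select_hemisphere(pred_raw, mid)
  } else {
    pred <- pred_raw
  }
  list(L = pv$L, pred_raw = pred_raw, pred = pred,
       side = attr(pred, "side_kept"), features = feats)
}

case_truth <- function(case) {
  if (!is.null(case$truth)) case$truth else as_imat(case$labels3 == 2L)
}

#' Leave-one-out evaluation harness
#'
#' For each case, trains the whole model stack (feature extractors, F4
#' network, ensemble) on the remaining cases and evaluates on the held-out
#' case with the cell-wise protocol and pixel IoU. Fold seeds are derived
#' from the master seed, so the run is reproducible. Optionally also scores
#' each single feature map (thresholded and postprocessed like the
#' ensemble output) as a baseline.
#'
#' @param cases List of cases (see [prepare_case()]); at least 2.
#' @param config A [pipeline_config()].
#' @param master_seed Integer master seed.
#' @param compare_single_maps Also compute per-feature-map baseline IoU.
#' @return List with `reports` (per-fold metric lists), `aggregate` (mean
#'   over folds, NA metrics excluded with a warning), and optionally
#'   `single_map_iou` (mean pixel IoU per feature map).
#' @export
leave_one_out <- function(cases, config = pipeline_config(),
                          master_seed = 1L, compare_single_maps = FALSE) {
  n <- length(cases)
  if (n < 2) stop_parameter("leave-one-out needs at least 2 cases")
  cases <- lapply(cases, prepare_case, config = config)
  reports <- vector("list", n)
  single_iou <- if (compare_single_maps)
    matrix(NA_real_, n, 4, dimnames = list(NULL, paste0("F", 1:4)))
  for (fold in seq_len(n)) {
    fit <- tryCatch(
      train_pipeline(cases[-fold], config,
                     seed = derive_seed(master_seed, fold)),
      error = function(e)
        stop_state(sprintf("fold %d failed: %s", fold, conditionMessage(e))))
    pred <- predict_case(fit, cases[[fold]])
    truth <- case_truth(cases[[fold]])
    rep_f <- evaluate_case(pred$pred, truth, cases[[fold]]$mask,
                           cell_size = config$cell_size)
    rep_f$fold <- fold
    rep_f$side <- pred$side
    reports[[fold]] <- rep_f
    if (compare_single_maps) {
      mid <- mask_midline(cases[[fold]]$mask)
      for (j in 1:4) {
        fm <- paste0("F", j)
        Lj <- array(0, dim(cases[[fold]]$mask))
        for (k in seq_along(pred$features))
          Lj[, , k] <- pred$features[[k]][[fm]]
        pj <- threshold_probability(Lj, config$tau,
                                    mask = cases[[fold]]$mask)
        if (config$postprocess) pj <- select_hemisphere(pj, mid)
        single_iou[fold, j] <- compute_iou(pj, truth)
      }
    }
  }
  metrics <- c("accuracy", "precision", "recall", "f1", "iou_pixel",
               "iou_cell", "precision_pixel", "recall_pixel")
  aggregate <- sapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], numeric(1))
    if (anyNA(v))
      warning(sprintf("metric %s undefined in %d fold(s); excluded from the mean",
                      m, sum(is.na(v))))
    mean(v, na.rm = TRUE)
  })
  out <- list(reports = reports, aggregate = as.list(aggregate))
  if (compare_single_maps)
    out$single_map_iou <- colMeans(single_iou)
  out
}
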