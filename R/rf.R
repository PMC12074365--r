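#' Random-forest training protocol
#'
#' @param voxels_per_volume elements sampled per volume/slice (paper setting
#'   10,000).
#' @param n_trees trees in the forest (paper setting 500).
#' @param hyperparameters named list passed to [ranger::ranger()] (e.g.
#'   `mtry`, `min.node.size`); empty means the conventional defaults.
#' @param ablation `"gf_plus_cluster"` (full feature set: voxel, Gabor and
#'   cluster blocks) or `"gf_only"` (classification solely from the Gabor
#'   responses — the baseline arm of the ablation comparison).
#' @param seed integer seed.
#' @return object of class `training_protocol`.
#' @export
training_protocol <- function(voxels_per_volume = 10000L, n_trees = 500L,
                              hyperparameters = list(),
                              ablation = c("gf_plus_cluster", "gf_only"),
                              seed = NULL) {
  stopifnot(voxels_per_volume >= 1, n_trees >= 1)
  structure(list(voxels_per_volume = as.integer(voxels_per_volume),
                 n_trees = as.integer(n_trees),
                 hyperparameters = hyperparameters,
                 ablation = match.arg(ablation), seed = seed),
            class = "training_protocol")
}

#' Sample labeled training voxels across volumes
#'
#' Draws a uniform random sample of `voxels_per_volume` non-background
#' elements from every volume (all of them if fewer are available),
#' assembles their features and attaches the ground-truth tumor label.
#'
#' @param volumes list of volumes; each a list with `image`
#'   (a [multimodal_image()]), `labels` (cluster labeling grid, may be `NULL`
#'   for the GF-only ablation) and `mask` (logical ground-truth tumor mask).
#' @param protocol a [training_protocol()].
#' @param filters a selected `gabor_bank`.
#' @return a feature data.frame with a `tumor` factor column and the feature
#'   `schema` attribute.
#' @export
sample_training_voxels <- function(volumes, protocol, filters) {
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  include_cluster <- protocol$ablation == "gf_plus_cluster"
  parts <- list()
  for (v in volumes) {
    idx <- which(!v$image$background)
    if (length(idx) == 0L) {
      warning("skipping a volume with no non-background elements")
      next
    }
    take <- idx[sample.int(length(idx),
                           min(protocol$voxels_per_volume, length(idx)))]
    ft <- assemble_features(v$image, v$labels, filters, index = take,
                            include_cluster = include_cluster,
                            include_voxel = include_cluster)
    ft$tumor <- factor(as.integer(v$mask[take]), levels = c(0, 1))
    parts[[length(parts) + 1L]] <- ft
  }
  if (length(parts) == 0L) stop("no usable volumes")
  out <- do.call(rbind, parts)
  attr(out, "schema") <- attr(parts[[1]], "schema")
  out
}

#' Train the random-forest voxel classifier
#'
#' Fits a forest on an assembled feature table with binary tumor labels.
#' Feature importances (impurity) and the out-of-bag prediction error are
#' retained for interpretability.
#'
#' @param features a feature data.frame with a `tumor` column (from
#'   [sample_training_voxels()]).
#' @param protocol a [training_protocol()].
#' @return object of class `rf_segmenter`: list with the fitted `forest`,
#'   `schema`, `protocol`, `importance` and `oob_error`.
#' @export
rf_train <- function(features, protocol) {
  stopifnot(nrow(features) > 0, "tumor" %in% names(features))
  if (length(unique(as.character(features$tumor))) < 2L)
    stop("training data contain a single class; ",
         "sample volumes with both tumor and non-tumor elements")
  hp <- protocol$hyperparameters
  args <- c(list(dependent.variable.name = "tumor", data = features,
                 num.trees = protocol$n_trees, probability = FALSE,
                 importance = "impurity", num.threads = 1L,
                 seed = protocol$seed %||% 1L,
                 respect.unordered.factors = TRUE),
            hp)
  forest <- do.call(ranger::ranger, args)
  structure(list(forest = forest,
                 schema = attr(features, "schema"),
                 protocol = protocol,
                 importance = forest$variable.importance,
                 oob_error = forest$prediction.error),
            class = "rf_segmenter")
}

#' @export
print.rf_segmenter <- function(x, ...) {
  cat(sprintf("Random-forest voxel segmenter: %d trees, %d features (%s)\n",
              x$forest$num.trees, x$forest$num.independent.variables,
              x$protocol$ablation))
  cat(sprintf("  out-of-bag error: %.4f\n", x$oob_error))
  invisible(x)
}

#' Predict a binary tumor mask
#'
#' Assembles the model's feature schema for every non-background element of
#' an image, applies the forest, and reshapes the votes to the image grid.
#' Background elements are forced to background.
#'
#' @param model an [rf_train()] fit.
#' @param image a [multimodal_image()].
#' @param labels the image's cluster labeling (required unless the model was
#'   trained GF-only).
#' @param filters the `gabor_bank` used at training time.
#' @return integer grid with values in `{0, 1}`.
#' @export
predict_mask <- function(model, image, labels = NULL, filters) {
  idx <- which(!image$background)
  out <- array(0L, dim = image$shape)
  if (length(idx) == 0L) return(out)
  include_cluster <- model$protocol$ablation == "gf_plus_cluster"
  ft <- assemble_features(image, labels, filters, index = idx,
                          include_cluster = include_cluster,
                          include_voxel = include_cluster,
                          gaussian_window = model$schema$gaussian_window,
                          median_window = model$schema$median_window)
  expect_cols <- setdiff(model$schema$columns, "tumor")
  if (!identical(names(ft), expect_cols))
    stop("feature schema mismatch between training and prediction")
  pr <- stats::predict(model$forest, data = ft, num.threads = 1L)
  out[idx] <- as.integer(as.character(pr$predictions))
  out
}

#' Tune forest hyperparameters by sequential model-based optimization
#'
#' Searches `mtry` (as a fraction of the feature count) and
#' `min.node.size` to maximize the mean validation Dice, using
#' [tpe_optimize()]. Training and validation volumes must be disjoint.
#'
#' @param train_features feature table for fitting (from
#'   [sample_training_voxels()]).
#' @param val_volumes validation volumes (same structure as in
#'   [sample_training_voxels()]).
#' @param filters the `gabor_bank` in use.
#' @param protocol base [training_protocol()].
#' @param budget number of trials.
#' @param seed integer seed.
#' @return list with `hyperparameters` (best configuration), `value` (its
#'   validation Dice) and the full `trials` log.
#' @export
tune_hyperparameters <- function(train_features, val_volumes, filters,
                                 protocol, budget = 10L, seed = NULL) {
  stopifnot(budget >= 1, length(val_volumes) >= 1)
  p_feat <- sum(names(train_features) != "tumor")
  objective <- function(x) {
    hp <- list(mtry = max(1L, round(x[1] * p_feat)),
               min.node.size = max(1L, round(x[2])))
    proto <- protocol
    proto$hyperparameters <- hp
    model <- rf_train(train_features, proto)
    dices <- vapply(val_volumes, function(v) {
      pm <- predict_mask(model, v$image, v$labels, filters)
      cm <- confusion_metrics(confusion_counts(pm, v$mask))
      if (is.na(cm$dice)) 0 else cm$dice
    }, 0)
    mean(dices)
  }
  res <- tpe_optimize(objective,
                      lower = c(mtry_frac = 0.05, min_node = 1),
                      upper = c(mtry_frac = 0.9, min_node = 20),
                      n_trials = budget, seed = seed)
  list(hyperparameters = list(mtry = max(1L, round(res$par[1] * p_feat)),
                              min.node.size = max(1L, round(res$par[2]))),
       value = res$value, trials = res$trials)
}
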