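#' Class labels used by the pixel classifier
#'
#' Label masks are integer matrices: 0 = unlabeled (excluded from training),
#' 1 = intact EZ, 2 = absent EZ.
#'
#' @return Character vector `c("intact", "absent")` in class-index order.
#' @export
ez_classes <- function() c("intact", "absent")

check_config_match <- function(a, b) {
  for (f in c("scales", "feature_families", "membrane_kernel_size",
              "membrane_rotations")) {
    if (!identical(a[[f]], b[[f]]))
      stopf("feature config mismatch in field '%s'", f)
  }
  invisible(TRUE)
}

#' Train a random-forest pixel classifier
#'
#' Fits a random forest on the labeled pixels of one or more feature stacks.
#' Labels are sparse scribbles: only pixels labeled 1 (intact) or 2 (absent)
#' enter training; 0 pixels are ignored. Defaults (200 trees, 2 candidate
#' features per split, unlimited depth) follow the fast-random-forest
#' defaults of trainable-segmentation practice. Training is reproducible
#' given `seed`; out-of-bag accuracy is stored on the model.
#'
#' @param examples List of `list(stack = FeatureStack, labels = matrix)`
#'   pairs; label matrices must match the stack dimensions.
#' @param n_trees Number of trees (default 200).
#' @param features_per_split Candidate features per split (default 2).
#' @param seed Integer seed recorded in the model.
#' @return An `RFModel`: the fitted ensemble plus its `FeatureConfig`, the
#'   class order, `seed`, `oob_accuracy`, and `training_digest` (MD5 of the
#'   training design).
#' @export
train_classifier <- function(examples, n_trees = 200L,
                             features_per_split = 2L, seed = 1L) {
  if (length(examples) == 0) stopf("no training examples supplied")
  config <- examples[[1]]$stack$config
  for (e in examples) check_config_match(config, e$stack$config)

  xs <- list()
  ys <- list()
  for (e in examples) {
    lab <- e$labels
    d <- dim(e$stack$channels)
    if (!identical(dim(lab), d[1:2]))
      stopf("label mask %d x %d does not match stack %d x %d",
            nrow(lab), ncol(lab), d[1], d[2])
    if (any(!lab %in% 0:2))
      stopf("labels must be 0 (unlabeled), 1 (intact) or 2 (absent)")
    keep <- which(lab != 0)
    if (length(keep) > 0) {
      xs[[length(xs) + 1]] <- stack_matrix(e$stack)[keep, , drop = FALSE]
      ys[[length(ys) + 1]] <- as.integer(lab[keep])
    }
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  present <- sort(unique(y))
  if (!identical(present, 1:2))
    stopf("both classes must be represented in the labels; found only: %s",
          paste(ez_classes()[present], collapse = ", "))
  yf <- factor(ez_classes()[y], levels = ez_classes())

  forest <- ranger::ranger(
    x = x, y = yf,
    num.trees = as.integer(n_trees), mtry = as.integer(features_per_split),
    min.node.size = 1, probability = TRUE,
    seed = as.integer(seed), num.threads = 1L
  )
  structure(
    list(forest = forest, config = config,
         n_trees = as.integer(n_trees),
         features_per_split = as.integer(features_per_split),
         seed = as.integer(seed), classes = ez_classes(),
         oob_accuracy = 1 - forest$prediction.error,
         training_digest = object_digest(list(x, y)),
         version = "ezquant-model-1"),
    class = "RFModel"
  )
}

#' @export
print.RFModel <- function(x, ...) {
  cat(sprintf("RFModel: %d trees, mtry %d, seed %d; OOB accuracy %.4f\n",
              x$n_trees, x$features_per_split, x$seed, x$oob_accuracy))
  cat(sprintf("  %d feature channels, classes: %s\n",
              length(feature_names(x$config)),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify every pixel of a feature stack
#'
#' Applies a trained model to a full feature stack. Per-pixel class
#' probabilities are the forest's vote fractions; the label is the argmax,
#' with exact ties broken toward "intact" so that defect is never
#' over-called on ambiguous pixels.
#'
#' @param model An `RFModel`.
#' @param stack A `FeatureStack` with the same configuration the model was
#'   trained with.
#' @return A `ClassMap`: list with integer matrix `labels` (1 = intact,
#'   2 = absent), array `probabilities` (`rows x cols x 2`), and `classes`.
#' @export
predict_classmap <- function(model, stack) {
  stopifnot(inherits(model, "RFModel"), inherits(stack, "FeatureStack"))
  check_config_match(model$config, stack$config)
  d <- dim(stack$channels)
  m <- stack_matrix(stack)
  pred <- stats::predict(model$forest, m, num.threads = 1L)$predictions
  pred <- pred[, model$classes, drop = FALSE]
  # argmax with ties toward class 1 ("intact")
  labels <- ifelse(pred[, 2] > pred[, 1], 2L, 1L)
  structure(
    list(labels = matrix(labels, d[1], d[2]),
         probabilities = array(pred, c(d[1], d[2], 2)),
         classes = model$classes),
    class = "ClassMap"
  )
}

#' Save / load a trained classifier
#'
#' The model file embeds the feature configuration, seed, class order and
#' training-set digest alongside the fitted ensemble, so a loaded model
#' reproduces predictions exactly and refuses stacks built with a different
#' configuration.
#'
#' @param model An `RFModel`.
#' @param path File path for the model archive.
#' @return `save_model`: `path`, invisibly. `load_model`: the `RFModel`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "RFModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  model <- readRDS(path)
  if (!inherits(model, "RFModel") ||
      !identical(model$version, "ezquant-model-1"))
    stopf("unrecognized or incompatible model file version in %s", path)
  model
}
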