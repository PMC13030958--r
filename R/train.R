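# Training-set assembly (annotation-local feature computation) and classifier
# fitting. Features are computed only on bounding crops of annotated regions,
# padded by the extractor's context margin so crop features equal full-image
# features exactly; whole-image-context extractors fall back to full planes.

#' Sparse annotation mask aligned to an image stack
#'
#' @param labels integer matrix `(y, x)` or array `(y, x, plane)`; 0 means
#'   unannotated, classes are 1..K.
#' @export
annotation_mask <- function(labels) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (any(labels < 0)) stop("labels must be >= 0 (0 = unannotated)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "annotation_mask")
}

as_annotation <- function(ann) {
  if (inherits(ann, "annotation_mask")) ann else annotation_mask(ann)
}

#' Assemble a training set from sparse annotations
#'
#' For local extractors, features are computed only on the bounding crop of
#' each annotated plane's annotations, padded by [context_margin()] (so the
#' sampled rows equal full-image extraction exactly); whole-image-context
#' extractors use the full plane; volumetric extractors use the full volume.
#' Only planes containing annotations are touched. Row order is deterministic:
#' ascending (plane, y, x).
#'
#' @param stack an [image_stack()].
#' @param ann an [annotation_mask()] (or plain integer matrix/array).
#' @param spec an extractor spec.
#' @return a `training_set`: `X` (n x F), `y`, `plane_index`, `coords`,
#'   `classes`, the spec and the input channel count.
#' @export
sample_training_set <- function(stack, ann, spec) {
  stopifnot(inherits(stack, "image_stack"), inherits(spec, "extractor_spec"))
  ann <- as_annotation(ann)
  d <- dim(stack$data)
  da <- dim(ann$labels)
  if (!all(da[1:2] == d[1:2]) || da[3] != d[4])
    stop(sprintf("annotation shape (%s) does not match stack spatial shape (%s)",
                 paste(da, collapse = "x"), paste(c(d[1:2], d[4]), collapse = "x")))
  classes <- sort(unique(ann$labels[ann$labels > 0L]))
  if (length(classes) == 0) stop("empty annotation: no labeled pixels")
  if (length(classes) < 2)
    stop("training requires at least 2 annotated classes; found ",
         length(classes))

  Fn <- n_feature_channels(spec, d[3])
  if (isTRUE(spec$volumetric)) {
    vals <- extract_volume_features(stack, spec)       # (y, x, plane, F)
    sel <- which(ann$labels > 0L)
    ai <- arrayInd(sel, da)
    ord <- order(ai[, 3], ai[, 1], ai[, 2])
    ai <- ai[ord, , drop = FALSE]
    X <- matrix(0, nrow(ai), dim(vals)[4])
    for (i in seq_len(nrow(ai)))
      X[i, ] <- vals[ai[i, 1], ai[i, 2], ai[i, 3], ]
    y <- ann$labels[cbind(ai[, 1], ai[, 2], ai[, 3])]
    return(new_training_set(X, y, ai[, 3], ai[, 1:2], classes, spec, d[3]))
  }

  margin <- context_margin(spec)
  rows <- list()
  for (p in seq_len(da[3])) {
    lab <- ann$labels[, , p]
    sel <- which(lab > 0L)
    if (length(sel) == 0) next
    ij <- arrayInd(sel, da[1:2])
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    if (isTRUE(spec$whole_image_context)) {
      y0 <- 1L; x0 <- 1L
      fm <- extract_plane_features(spec, get_plane(stack, p))
    } else {
      y0 <- max(1L, min(ij[, 1]) - margin)
      y1 <- min(d[1], max(ij[, 1]) + margin)
      x0 <- max(1L, min(ij[, 2]) - margin)
      x1 <- min(d[2], max(ij[, 2]) + margin)
      crop <- get_plane(stack, p)[y0:y1, x0:x1, , drop = FALSE]
      fm <- extract_plane_features(spec, crop)
    }
    X <- matrix(0, nrow(ij), n_map_channels(fm))
    for (i in seq_len(nrow(ij)))
      X[i, ] <- fm$values[ij[i, 1] - y0 + 1L, ij[i, 2] - x0 + 1L, ]
    rows[[length(rows) + 1L]] <-
      list(X = X, y = lab[ij], p = rep(p, nrow(ij)), coords = ij)
  }
  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  stopifnot(ncol(X) == Fn)
  new_training_set(X,
                   unlist(lapply(rows, `[[`, "y")),
                   unlist(lapply(rows, `[[`, "p")),
                   do.call(rbind, lapply(rows, `[[`, "coords")),
                   classes, spec, d[3])
}

new_training_set <- function(X, y, plane_index, coords, classes, spec, n_in) {
  structure(list(X = X, y = as.integer(y), plane_index = as.integer(plane_index),
                 coords = coords, classes = as.integer(classes), spec = spec,
                 n_channels_in = as.integer(n_in)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d pixels x %d features, classes: %s\n",
              nrow(x$X), ncol(x$X), paste(x$classes, collapse = ",")))
  invisible(x)
}

#' Train a classifier on a sparse-annotation training set
#'
#' The default classifier family is gradient-boosted trees (multiclass
#' softmax boosting with Newton leaf values); random forests (bagged CART,
#' gini splits, sqrt-mtry feature subsampling) are the alternative. Both are
#' deterministic given `seed`.
#'
#' @param ts a `training_set` from [sample_training_set()].
#' @param kind `"gradient_boosted_trees"` (default) or `"random_forest"`.
#' @param seed integer seed controlling all classifier randomness.
#' @param normalization the [normalization_config()] that was applied to the
#'   training stack (stored in the model; default `none`).
#' @param n_trees,max_depth forest size / boosting rounds and tree depth.
#' @param learning_rate shrinkage for boosting.
#' @param provenance free-text metadata stored in the model.
#' @return a `trained_model`.
#' @export
train_classifier <- function(ts,
                             kind = c("gradient_boosted_trees", "random_forest"),
                             seed = 0L,
                             normalization = normalization_config("none"),
                             n_trees = if (kind == "random_forest") 100L else 40L,
                             max_depth = if (kind == "random_forest") 12L else 4L,
                             learning_rate = 0.2,
                             provenance = "") {
  kind <- match.arg(kind)
  stopifnot(inherits(ts, "training_set"))
  y0 <- match(ts$y, ts$classes) - 1L
  K <- length(ts$classes)
  if (any(is.na(y0))) stop("labels outside class inventory")
  const_x <- all(apply(ts$X, 2, function(v) max(v) - min(v) == 0))
  if (const_x && K > 1)
    warning("constant feature matrix with multiple classes: ties allowed")
  seed <- as.integer(seed) %% .Machine$integer.max
  if (kind == "random_forest") {
    mtry <- max(1L, as.integer(floor(sqrt(ncol(ts$X)))))
    trees <- cpp_rf_fit(ts$X, y0, K, as.integer(n_trees), mtry,
                        as.integer(max_depth), 2L, seed)
    clf <- list(kind = kind, trees = trees, K = K, mtry = mtry,
                n_trees = as.integer(n_trees), max_depth = as.integer(max_depth))
  } else {
    trees <- cpp_gbt_fit(ts$X, y0, K, as.integer(n_trees),
                         as.integer(max_depth), learning_rate, 2L, seed)
    clf <- list(kind = kind, trees = trees, K = K,
                n_rounds = as.integer(n_trees),
                max_depth = as.integer(max_depth),
                learning_rate = learning_rate)
  }
  structure(list(classifier = clf, extractor = ts$spec,
                 normalization = normalization, classes = ts$classes,
                 n_channels_in = ts$n_channels_in, seed = seed,
                 format_version = 1L, provenance = provenance),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %s features; classes: %s; %d input channel(s)\n",
              x$classifier$kind, x$extractor$kind,
              paste(x$classes, collapse = ","), x$n_channels_in))
  invisible(x)
}

classifier_probs <- function(clf, X) {
  if (clf$kind == "random_forest")
    cpp_rf_predict(clf$trees, X, clf$K)
  else
    cpp_gbt_predict(clf$trees, X, clf$K, clf$learning_rate)
}

#' One-call training from a stack and annotations
#'
#' Convenience wrapper: normalize, sample the training set and fit.
#' @inheritParams sample_training_set
#' @inheritParams train_classifier
#' @export
train_pixel_classifier <- function(stack, ann, spec,
                                   normalization = normalization_config("none"),
                                   kind = c("gradient_boosted_trees", "random_forest"),
                                   seed = 0L, ...) {
  kind <- match.arg(kind)
  stack <- normalize_stack(stack, normalization)
  ts <- sample_training_set(stack, ann, spec)
  train_classifier(ts, kind = kind, seed = seed,
                   normalization = normalization, ...)
}

# test probes for the laziness contract
feature_probe_reset <- function() the$extract_count <- 0L
feature_probe_count <- function() the$extract_count
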