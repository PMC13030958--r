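# Dense prediction: per-plane label maps, plane streaming over stacks,
# optional downscale-before-features with majority-filter smoothing.

check_channels <- function(model, n_in) {
  if (n_in != model$n_channels_in)
    stop(sprintf("channel mismatch: model trained on %d channel(s), input has %d",
                 model$n_channels_in, n_in))
}

predict_from_features <- function(model, vals) {
  d <- dim(vals)
  X <- matrix(vals, d[1] * d[2], d[3])
  P <- classifier_probs(model$classifier, X)
  # argmax with ties broken toward the lower class id (first column wins)
  lab <- matrix(model$classes[max.col(P, ties.method = "first")], d[1], d[2])
  storage.mode(lab) <- "integer"
  list(labels = lab, probs = P)
}

#' Predict a class label for every pixel of one plane
#'
#' @param plane `(y, x)` matrix or `(y, x, channel)` array. Must carry the
#'   channel count the model was trained with.
#' @param model a `trained_model`.
#' @param probabilities also return the `(y, x, K)` class-probability array.
#' @return integer label matrix, or a list `(labels, probabilities)`.
#' @export
predict_image <- function(plane, model, probabilities = FALSE) {
  plane <- as_plane(plane)
  check_channels(model, dim(plane)[3])
  fm <- extract_plane_features(model$extractor, plane)
  pr <- predict_from_features(model, fm$values)
  if (!probabilities) return(pr$labels)
  K <- length(model$classes)
  list(labels = pr$labels,
       probabilities = array(pr$probs, dim = c(dim(pr$labels), K)))
}

#' Predict labels for selected planes of a stack, streaming plane by plane
#'
#' `stack` may be an [image_stack()] or a lazy plane source: a function
#' `function(p)` returning plane `p` as a `(y, x, channel)` array (so
#' larger-than-memory stacks can be processed without materializing all
#' planes; peak feature memory is one plane's features).
#'
#' @param stack an [image_stack()] or `function(p)`.
#' @param model a `trained_model`.
#' @param planes plane selection (default all; required for lazy sources).
#' @return integer array `(y, x, length(planes))`.
#' @export
predict_stack <- function(stack, model, planes = NULL) {
  if (inherits(stack, "image_stack")) {
    if (is.null(planes)) planes <- seq_len(n_planes(stack))
    src <- function(p) get_plane(stack, p)
  } else if (is.function(stack)) {
    if (is.null(planes)) stop("`planes` must be given for a lazy plane source")
    src <- stack
  } else stop("`stack` must be an image_stack or a plane-source function")
  if (length(planes) == 0) stop("empty plane selection")

  if (inherits(stack, "image_stack") && isTRUE(model$extractor$volumetric)) {
    check_channels(model, n_channels(stack))
    vals <- extract_volume_features(stack, model$extractor)
    d <- dim(vals)
    out <- array(NA_integer_, dim = c(d[1], d[2], length(planes)))
    for (i in seq_along(planes)) {
      pv <- array(vals[, , planes[i], ], c(d[1], d[2], d[4]))
      out[, , i] <- predict_from_features(model, pv)$labels
    }
    dimnames(out) <- list(NULL, NULL, as.character(planes))
    return(out)
  }

  first <- as_plane(src(planes[1]))
  out <- array(NA_integer_, dim = c(dim(first)[1:2], length(planes)))
  out[, , 1] <- predict_image(first, model)
  for (i in seq_along(planes)[-1])
    out[, , i] <- predict_image(as_plane(src(planes[i])), model)
  dimnames(out) <- list(NULL, NULL, as.character(planes))
  out
}

#' Predict after downscaling, then upscale and smooth the labels
#'
#' Downscales the plane by an integer factor (bilinear) before feature
#' extraction, predicts, upscales the label map back to the original shape
#' (nearest neighbor, preserving label integrality) and applies a majority
#' filter. The recommended fast configuration uses factor 2.
#'
#' @param plane image plane.
#' @param model a `trained_model`.
#' @param factor integer downscale factor >= 1.
#' @param majority apply the majority filter (default TRUE for factor > 1).
#' @param majority_radius window radius of the majority filter.
#' @export
predict_with_downscale <- function(plane, model, factor = 2L,
                                   majority = factor > 1, majority_radius = 1L) {
  plane <- as_plane(plane)
  d <- dim(plane)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor > min(d[1:2])) stop("factor larger than image side")
  if (factor == 1L) {
    lab <- predict_image(plane, model)
  } else {
    ph <- d[1] %/% factor
    pw <- d[2] %/% factor
    small <- array(0, dim = c(ph, pw, d[3]))
    for (c_ in seq_len(d[3]))
      small[, , c_] <- cpp_resize_bilinear(plane[, , c_], ph, pw)
    lab <- cpp_resize_nearest(predict_image(small, model), d[1], d[2])
  }
  if (majority) lab <- smooth_labels_majority(lab, majority_radius)
  lab
}

#' Majority (modal) label filter
#'
#' Replaces each pixel's label by the modal label in its `(2r+1)^2` window;
#' ties keep the center pixel's label.
#' @param labels integer label matrix.
#' @param footprint_radius window radius r >= 1.
#' @export
smooth_labels_majority <- function(labels, footprint_radius = 1L) {
  if (footprint_radius < 1) stop("footprint_radius must be >= 1")
  storage.mode(labels) <- "integer"
  cpp_majority_filter(labels, as.integer(footprint_radius))
}
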