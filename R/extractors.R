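# Extractor framework: declarative specs, a plugin registry, and the
# built-in feature extractors. A feature extractor maps one plane
# (y, x, channel array) to a feature_map: per-pixel feature vectors at full
# spatial resolution, stamped with the producing spec's fingerprint.

the <- new.env(parent = emptyenv())
the$registry <- list()
the$extract_count <- 0L   # probe used by laziness tests

#' Register a feature extractor kind
#'
#' Third-party extractors plug in by registering a new kind name with three
#' functions: `extract(spec, plane)` returning a [feature_map()],
#' `channels(spec, n_in)` giving the declared channel count as a pure function
#' of the spec parameters and input channel count, and `margin(spec)` giving
#' the context margin in pixels (ignored when `whole_image_context` is set on
#' the spec).
#'
#' @param kind character kind name.
#' @param extract,channels,margin functions as described above.
#' @export
register_extractor <- function(kind, extract, channels, margin = function(spec) 0L) {
  the$registry[[kind]] <- list(extract = extract, channels = channels,
                               margin = margin)
  invisible(kind)
}

registry_entry <- function(kind) {
  e <- the$registry[[kind]]
  if (is.null(e)) stop(sprintf("unknown extractor kind '%s'", kind))
  e
}

new_extractor_spec <- function(kind, params, whole_image_context = FALSE,
                               volumetric = FALSE) {
  structure(list(kind = kind, params = params,
                 whole_image_context = whole_image_context,
                 volumetric = volumetric),
            class = "extractor_spec")
}

#' @export
print.extractor_spec <- function(x, ...) {
  cat(sprintf("<extractor_spec> kind: %s  global-context: %s\n", x$kind,
              x$whole_image_context))
  invisible(x)
}

# stable, human-readable identity of a spec (stored on feature maps & models)
spec_fingerprint <- function(spec) {
  ser <- serializable_params(spec)
  paste0(spec$kind, ":", jsonlite::toJSON(ser, auto_unbox = TRUE, digits = 10))
}

serializable_params <- function(spec) {
  p <- spec$params
  if (!is.null(p$backbone)) {
    p$backbone <- p$backbone$id
  }
  if (!is.null(p$children)) {
    p$children <- lapply(p$children, function(ch)
      list(kind = ch$kind, params = serializable_params(ch)))
  }
  if (!is.null(p$base)) {
    p$base <- list(kind = p$base$kind, params = serializable_params(p$base))
  }
  p
}

#' Per-pixel feature map
#'
#' @param values array `(y, x, F)` of feature channels.
#' @param fingerprint identity string of the producing extractor spec.
#' @param scale resolution ratio to the source image (1 after upsampling).
#' @export
feature_map <- function(values, fingerprint, scale = 1) {
  stopifnot(length(dim(values)) == 3)
  structure(list(values = values, fingerprint = fingerprint, scale = scale),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_map> %dx%d, %d channels, scale %g\n",
              d[1], d[2], d[3], x$scale))
  invisible(x)
}

n_map_channels <- function(fm) dim(fm$values)[3]

#' Number of feature channels an extractor spec will produce
#'
#' A pure function of the spec parameters and the input channel count.
#' @param spec an extractor spec.
#' @param n_in number of input image channels.
#' @export
n_feature_channels <- function(spec, n_in = 1L) {
  as.integer(registry_entry(spec$kind)$channels(spec, as.integer(n_in)))
}

#' Context margin of an extractor spec
#'
#' The halo of pixels such that features computed on any crop padded by at
#' least this margin equal full-image features exactly. `NA` for
#' whole-image-context extractors (tiling and cropping are refused for them by
#' default).
#' @param spec an extractor spec.
#' @export
context_margin <- function(spec) {
  if (isTRUE(spec$whole_image_context)) return(NA_integer_)
  as.integer(registry_entry(spec$kind)$margin(spec))
}

as_plane <- function(plane) {
  if (is.matrix(plane)) plane <- array(plane, dim = c(dim(plane), 1L))
  stopifnot(is.array(plane), length(dim(plane)) == 3)
  plane
}

#' Extract per-pixel features for one plane
#'
#' Dispatches on the spec's registered kind. `plane` is a `(y, x)` matrix or
#' `(y, x, channel)` array.
#' @param spec an extractor spec.
#' @param plane image plane.
#' @return a [feature_map()] at scale 1.
#' @export
extract_plane_features <- function(spec, plane) {
  plane <- as_plane(plane)
  the$extract_count <- the$extract_count + 1L
  fm <- registry_entry(spec$kind)$extract(spec, plane)
  stopifnot(inherits(fm, "feature_map"))
  fm
}

# ---------------------------------------------------------------- gaussian --

#' Gaussian-baseline extractor: raw intensity plus one smoothed channel per
#' input channel
#'
#' @param sigma Gaussian standard deviation in pixels (> 0); default 3.
#' @export
extractor_gaussian <- function(sigma = 3) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a positive scalar")
  new_extractor_spec("gaussian_baseline", list(sigma = sigma))
}

extract_gaussian_impl <- function(spec, plane) {
  d <- dim(plane)
  s <- spec$params$sigma
  out <- array(0, dim = c(d[1], d[2], 2L * d[3]))
  for (c_ in seq_len(d[3])) {
    out[, , c_] <- plane[, , c_]
    out[, , d[3] + c_] <- smooth2(plane[, , c_], s)
  }
  feature_map(out, spec_fingerprint(spec))
}

# -------------------------------------------------------------- filterbank --

#' Multi-scale filter-bank extractor
#'
#' Per input channel: the raw intensity channel, then for each sigma eight
#' filter responses in deterministic order: Gaussian, Laplacian of Gaussian,
#' Gaussian gradient magnitude, difference of Gaussians, structure-tensor
#' eigenvalues (descending), Hessian-of-Gaussian eigenvalues (descending).
#' Total channels: `n_in * (8 * length(sigmas) + 1)`.
#'
#' @param sigmas strictly positive scales; default
#'   `c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0)`.
#' @export
extractor_filterbank <- function(sigmas = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0)) {
  if (length(sigmas) == 0 || any(sigmas <= 0))
    stop("sigmas must be a non-empty vector of positive scalars")
  new_extractor_spec("filterbank", list(sigmas = as.numeric(sigmas)))
}

extract_filterbank_impl <- function(spec, plane) {
  d <- dim(plane)
  if (d[1] < 2 || d[2] < 2) stop("filter bank undefined on degenerate (<2 px) images")
  sigmas <- spec$params$sigmas
  F_ <- d[3] * (8L * length(sigmas) + 1L)
  out <- array(0, dim = c(d[1], d[2], F_))
  f <- 0L
  for (c_ in seq_len(d[3])) {
    f <- f + 1L
    out[, , f] <- plane[, , c_]
    for (s in sigmas) {
      ch <- filterbank_one_sigma(plane[, , c_], s)
      for (k in seq_along(ch)) out[, , f + k] <- ch[[k]]
      f <- f + 8L
    }
  }
  feature_map(out, spec_fingerprint(spec))
}

# ------------------------------------------------------------ context mean --

#' Large-window context extractor
#'
#' Per input channel and per sigma: the Gaussian-weighted local mean and the
#' Gaussian-window local standard deviation at large scales. A deliberately
#' simple "semantic surrogate": its features are monotone in the identity of
#' the enclosing environment, which is what scribble-trained tree classifiers
#' need to generalize from sparse strokes (see the methods vignette for why
#' randomly initialized deep backbones do not provide this). Registered as a
#' plugin kind like any third-party extractor would be.
#'
#' @param sigmas large window scales in pixels (default `c(16, 48)`).
#' @export
extractor_context_mean <- function(sigmas = c(16, 48)) {
  if (length(sigmas) == 0 || any(sigmas <= 0))
    stop("sigmas must be positive")
  new_extractor_spec("context_mean", list(sigmas = as.numeric(sigmas)))
}

extract_context_mean_impl <- function(spec, plane) {
  d <- dim(plane)
  sigmas <- spec$params$sigmas
  out <- array(0, dim = c(d[1], d[2], 2L * length(sigmas) * d[3]))
  f <- 0L
  for (c_ in seq_len(d[3]))
    for (s in sigmas) {
      mu <- smooth2(plane[, , c_], s)
      v <- pmax(smooth2(plane[, , c_]^2, s) - mu^2, 0)
      out[, , f + 1L] <- mu
      out[, , f + 2L] <- sqrt(v)
      f <- f + 2L
    }
  feature_map(out, spec_fingerprint(spec))
}

# ------------------------------------------------------------- cnn pyramid --

#' Featurized-pyramid extractor over a convolutional backbone
#'
#' Downscales the input by each factor in `scales` (bilinear), runs the
#' backbone, upscales every selected layer output back to the original
#' resolution (bilinear) and concatenates across layers and scales. Total
#' channels: `sum(layer channels) * length(scales)` (independent of input
#' channel count, which the backbone consumes).
#'
#' @param backbone a backbone provider as returned by [toy_cnn_backbone()]: a
#'   list with `id`, `n_in`, `layer_channels`, `layer_downsample`, `min_size`,
#'   `receptive_radius` and `forward(plane)`.
#' @param scales integer downscale factors, subset of `{1, 2, 4, 8}`.
#' @param layers indices of backbone layers to keep (default all).
#' @export
extractor_cnn_pyramid <- function(backbone, scales = c(1L, 2L),
                                  layers = seq_along(backbone$layer_channels)) {
  if (!all(scales %in% c(1L, 2L, 4L, 8L))) stop("scales must be within {1,2,4,8}")
  new_extractor_spec("cnn_pyramid",
                     list(backbone = backbone, scales = as.integer(scales),
                          layers = as.integer(layers)))
}

extract_cnn_pyramid_impl <- function(spec, plane) {
  d <- dim(plane)
  bb <- spec$params$backbone
  if (d[3] != bb$n_in)
    stop(sprintf("backbone expects %d channels, got %d", bb$n_in, d[3]))
  scales <- spec$params$scales
  layers <- spec$params$layers
  for (s in scales) {
    if (floor(d[1] / s) < bb$min_size || floor(d[2] / s) < bb$min_size)
      stop(sprintf("image too small for backbone at scale %d", s))
  }
  F_ <- sum(bb$layer_channels[layers]) * length(scales)
  out <- array(0, dim = c(d[1], d[2], F_))
  f <- 0L
  for (s in scales) {
    ph <- max(bb$min_size, floor(d[1] / s))
    pw <- max(bb$min_size, floor(d[2] / s))
    small <- array(0, dim = c(ph, pw, d[3]))
    for (c_ in seq_len(d[3]))
      small[, , c_] <- if (s == 1L) plane[, , c_] else
        cpp_resize_bilinear(plane[, , c_], ph, pw)
    feats <- bb$forward(small)
    for (li in layers) {
      fm <- feats[[li]]
      for (c_ in seq_len(dim(fm)[3])) {
        f <- f + 1L
        m <- fm[, , c_]
        out[, , f] <- if (all(dim(m) == d[1:2])) m else
          cpp_resize_bilinear(m, d[1], d[2])
      }
    }
  }
  feature_map(out, spec_fingerprint(spec))
}

# --------------------------------------------------------------- vit patch --

#' Patch-embedding extractor over a vision-transformer style backbone
#'
#' The image is resized (bilinear) so each side is the nearest positive
#' multiple of `patch_size`, cut into non-overlapping patches, and each patch
#' is embedded by the backbone into a `D`-vector. Patch features have
#' whole-image-context semantics here: tiling and annotation crops are refused
#' by default for specs containing this extractor.
#'
#' @param backbone a patch-embedding provider as returned by
#'   [toy_vit_backbone()], with fields `id`, `patch_size`, `dim`, `n_in` and
#'   `embed(patch_matrix)`.
#' @param interpolation `"nearest"` (piecewise-constant patch semantics,
#'   default) or `"bilinear"` for the upsampling step.
#' @export
extractor_vit <- function(backbone, interpolation = c("nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  new_extractor_spec("vit_patch",
                     list(backbone = backbone,
                          patch_size = backbone$patch_size,
                          dim = backbone$dim,
                          interpolation = interpolation),
                     whole_image_context = TRUE)
}

#' Extract a patch grid from one plane
#'
#' Lower-level entry point returning the raw patch grid rather than an
#' upsampled feature map.
#' @param spec a `vit_patch` extractor spec.
#' @param plane `(y, x)` matrix or `(y, x, channel)` array.
#' @return a `patch_grid`: embeddings `(grid_y, grid_x, D)`, `patch_size`,
#'   `orig_shape`, `resized_shape` and `origin_offset` (pixels of
#'   padding/cropping implied by the resize, for exact back-mapping).
#' @export
extract_vit_patch <- function(spec, plane) {
  plane <- as_plane(plane)
  d <- dim(plane)
  bb <- spec$params$backbone
  if (is.null(bb) || is.null(bb$embed))
    stop("ViT backend missing: supply a patch-embedding backbone ",
         "(see toy_vit_backbone()) or install/register one")
  if (d[3] != bb$n_in)
    stop(sprintf("backbone expects %d channels, got %d", bb$n_in, d[3]))
  ps <- spec$params$patch_size
  rh <- max(1L, round(d[1] / ps)) * ps
  rw <- max(1L, round(d[2] / ps)) * ps
  gy <- rh %/% ps
  gx <- rw %/% ps
  res <- array(0, dim = c(rh, rw, d[3]))
  for (c_ in seq_len(d[3]))
    res[, , c_] <- if (rh == d[1] && rw == d[2]) plane[, , c_] else
      cpp_resize_bilinear(plane[, , c_], rh, rw)
  # rows = patches in row-major (y-fastest column order: gy x gx grid)
  P <- matrix(0, gy * gx, ps * ps * d[3])
  idx <- 0L
  for (px in seq_len(gx))
    for (py in seq_len(gy)) {
      idx <- idx + 1L
      block <- res[((py - 1L) * ps + 1L):(py * ps),
                   ((px - 1L) * ps + 1L):(px * ps), , drop = FALSE]
      P[idx, ] <- as.vector(block)
    }
  E <- bb$embed(P)
  stopifnot(ncol(E) == bb$dim)
  emb <- array(0, dim = c(gy, gx, bb$dim))
  idx <- 0L
  for (px in seq_len(gx))
    for (py in seq_len(gy)) {
      idx <- idx + 1L
      emb[py, px, ] <- E[idx, ]
    }
  structure(list(embeddings = emb, patch_size = ps,
                 orig_shape = d[1:2], resized_shape = c(rh, rw),
                 origin_offset = c(rh - d[1], rw - d[2])),
            class = "patch_grid")
}

#' Upsample a patch grid to per-pixel features
#'
#' Each pixel receives the embedding of its covering patch
#' (nearest-neighbor, default) or a bilinear interpolation of patch-center
#' values. Back-mapping through the resize is exact: pixel centers are mapped
#' into resized coordinates before patch lookup.
#' @param grid a `patch_grid` from [extract_vit_patch()].
#' @param target_shape `(height, width)` of the original image.
#' @param interpolation `"nearest"` or `"bilinear"`.
#' @param fingerprint identity string to stamp on the result.
#' @export
upsample_patch_features <- function(grid, target_shape = grid$orig_shape,
                                    interpolation = c("nearest", "bilinear"),
                                    fingerprint = "patch_grid") {
  interpolation <- match.arg(interpolation)
  stopifnot(all(target_shape == grid$orig_shape))
  gy <- dim(grid$embeddings)[1]
  gx <- dim(grid$embeddings)[2]
  D <- dim(grid$embeddings)[3]
  H <- target_shape[1]; W <- target_shape[2]
  out <- array(0, dim = c(H, W, D))
  if (interpolation == "nearest") {
    # pixel center -> resized coords -> covering patch
    py <- pmin(floor(((seq_len(H) - 0.5) * grid$resized_shape[1] / H) /
                       grid$patch_size), gy - 1L) + 1L
    px <- pmin(floor(((seq_len(W) - 0.5) * grid$resized_shape[2] / W) /
                       grid$patch_size), gx - 1L) + 1L
    for (d_ in seq_len(D))
      out[, , d_] <- grid$embeddings[py, px, d_]
  } else {
    for (d_ in seq_len(D))
      out[, , d_] <- cpp_resize_bilinear(grid$embeddings[, , d_, drop = TRUE], H, W)
  }
  feature_map(out, fingerprint)
}

extract_vit_impl <- function(spec, plane) {
  grid <- extract_vit_patch(spec, plane)
  upsample_patch_features(grid, dim(plane)[1:2],
                          interpolation = spec$params$interpolation,
                          fingerprint = spec_fingerprint(spec))
}

# ---------------------------------------------------------------- combined --

#' Fused extractor: channel-wise concatenation of child extractors
#'
#' @param ... child extractor specs, concatenated in argument order.
#' @export
extractor_combined <- function(...) {
  children <- list(...)
  if (length(children) == 1 && is.list(children[[1]]) &&
      !inherits(children[[1]], "extractor_spec"))
    children <- children[[1]]
  stopifnot(length(children) >= 1,
            all(vapply(children, inherits, TRUE, "extractor_spec")))
  new_extractor_spec("combined", list(children = children),
                     whole_image_context =
                       any(vapply(children, function(s) isTRUE(s$whole_image_context), TRUE)))
}

#' Concatenate feature maps channel-wise
#'
#' All maps must be at scale 1 with identical spatial shape; channels are
#' stacked in list order and the fingerprint chains the child fingerprints.
#' @param maps list of [feature_map()]s.
#' @export
combine_features <- function(maps) {
  stopifnot(length(maps) >= 1)
  if (length(maps) == 1) return(maps[[1]])
  sh <- dim(maps[[1]]$values)[1:2]
  for (i in seq_along(maps)) {
    if (maps[[i]]$scale != 1) stop(sprintf("map %d is not at scale 1", i))
    if (!all(dim(maps[[i]]$values)[1:2] == sh))
      stop(sprintf("map %d spatial shape (%s) mismatches map 1 (%s)", i,
                   paste(dim(maps[[i]]$values)[1:2], collapse = "x"),
                   paste(sh, collapse = "x")))
  }
  vals <- array(0, dim = c(sh, sum(vapply(maps, n_map_channels, 1L))))
  f <- 0L
  for (m in maps) {
    nf <- n_map_channels(m)
    vals[, , f + seq_len(nf)] <- m$values
    f <- f + nf
  }
  feature_map(vals, paste(vapply(maps, function(m) m$fingerprint, ""),
                          collapse = "+"))
}

extract_combined_impl <- function(spec, plane) {
  maps <- lapply(spec$params$children, function(ch)
    registry_entry(ch$kind)$extract(ch, plane))
  fm <- combine_features(maps)
  fm$fingerprint <- spec_fingerprint(spec)
  fm
}

# --------------------------------------------------------- multiprojection --

#' Orthogonal-projection extractor for volumes
#'
#' Runs a 2D base extractor slice-wise along each of the xy, xz and yz
#' orientations of a z-stack, transposes the results back to `(y, x, plane)`
#' voxel alignment, and concatenates: `3 * base channels` per voxel.
#'
#' @param base a 2D extractor spec.
#' @export
extractor_multiprojection <- function(base) {
  stopifnot(inherits(base, "extractor_spec"))
  if (isTRUE(base$volumetric)) stop("base must be a 2D extractor")
  new_extractor_spec("multiprojection", list(base = base),
                     whole_image_context = isTRUE(base$whole_image_context),
                     volumetric = TRUE)
}

#' Extract multi-projection features for a whole volume
#'
#' @param stack an [image_stack()] with a plane axis (single- or
#'   multi-channel).
#' @param spec a `multiprojection` extractor spec.
#' @return array `(y, x, plane, 3 * F_base)`.
#' @export
extract_volume_features <- function(stack, spec) {
  stopifnot(inherits(spec, "extractor_spec"), spec$kind == "multiprojection")
  d <- dim(stack$data)                      # (y, x, channel, plane)
  if (d[4] < 2) stop("input has no plane axis; use the base 2D extractor instead")
  base <- spec$params$base
  Fb <- n_feature_channels(base, d[3])
  out <- array(0, dim = c(d[1], d[2], d[4], 3L * Fb))
  # xy orientation: slice along plane
  for (p in seq_len(d[4])) {
    fm <- registry_entry(base$kind)$extract(base, array(stack$data[, , , p], d[1:3]))
    out[, , p, seq_len(Fb)] <- fm$values
  }
  # xz orientation: slice along y -> image (x, plane)
  for (yy in seq_len(d[1])) {
    sl <- array(aperm(array(stack$data[yy, , , ], d[2:4]), c(1, 3, 2)),
                c(d[2], d[4], d[3]))
    fm <- registry_entry(base$kind)$extract(base, sl)
    out[yy, , , Fb + seq_len(Fb)] <- fm$values
  }
  # yz orientation: slice along x -> image (y, plane)
  for (xx in seq_len(d[2])) {
    sl <- array(aperm(array(stack$data[, xx, , ], c(d[1], d[3], d[4])), c(1, 3, 2)),
                c(d[1], d[4], d[3]))
    fm <- registry_entry(base$kind)$extract(base, sl)
    out[, xx, , 2L * Fb + seq_len(Fb)] <- fm$values
  }
  out
}

extract_multiprojection_impl <- function(spec, plane) {
  stop("multiprojection is a volume extractor; use extract_volume_features()")
}

# ---------------------------------------------------------------- registry --

register_builtin_extractors <- function() {
  register_extractor("gaussian_baseline", extract_gaussian_impl,
                     channels = function(spec, n_in) 2L * n_in,
                     margin = function(spec) max(1L, ceiling(4 * spec$params$sigma)))
  register_extractor("filterbank", extract_filterbank_impl,
                     channels = function(spec, n_in)
                       n_in * (8L * length(spec$params$sigmas) + 1L),
                     margin = function(spec)
                       max(vapply(spec$params$sigmas, filter_margin_one_sigma, 1)))
  register_extractor("context_mean", extract_context_mean_impl,
                     channels = function(spec, n_in)
                       2L * length(spec$params$sigmas) * n_in,
                     margin = function(spec)
                       max(1L, ceiling(4 * max(spec$params$sigmas))))
  register_extractor("cnn_pyramid", extract_cnn_pyramid_impl,
                     channels = function(spec, n_in) {
                       bb <- spec$params$backbone
                       sum(bb$layer_channels[spec$params$layers]) *
                         length(spec$params$scales)
                     },
                     margin = function(spec)
                       spec$params$backbone$receptive_radius * max(spec$params$scales))
  register_extractor("vit_patch", extract_vit_impl,
                     channels = function(spec, n_in) spec$params$dim)
  register_extractor("combined", extract_combined_impl,
                     channels = function(spec, n_in)
                       sum(vapply(spec$params$children, function(ch)
                         n_feature_channels(ch, n_in), integer(1))),
                     margin = function(spec)
                       max(vapply(spec$params$children, context_margin, 1L)))
  register_extractor("multiprojection", extract_multiprojection_impl,
                     channels = function(spec, n_in)
                       3L * n_feature_channels(spec$params$base, n_in),
                     margin = function(spec) context_margin(spec$params$base))
}
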