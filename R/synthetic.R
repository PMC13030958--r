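# Seeded synthetic fixtures. Each kind is built to be solvable by the
# extractor class it is meant to exercise: intensity_separable by any local
# extractor, texture_separable by multi-scale filters, semantic_context only
# by large-context features (locally identical textures whose class is
# betrayed only by a thin marker ring at the region boundary), instances for
# the instance->semantic conversion, volume3d for multi-projection features,
# multichannel for cross-channel (XOR-style) class structure.

#' Fixture specification
#'
#' @param kind one of `intensity_separable`, `texture_separable`,
#'   `semantic_context`, `instances`, `volume3d`, `multichannel`.
#' @param shape spatial shape `(y, x)` (plus plane count for `volume3d`).
#' @param n_classes number of classes (>= 2).
#' @param noise_sd pixel noise standard deviation.
#' @param seed integer seed.
#' @export
fixture_spec <- function(kind = c("intensity_separable", "texture_separable",
                                  "semantic_context", "instances", "volume3d",
                                  "multichannel"),
                         shape = NULL, n_classes = 2L, noise_sd = 0.05,
                         seed = 0L) {
  kind <- match.arg(kind)
  if (is.null(shape))
    shape <- switch(kind, volume3d = c(48L, 48L, 16L),
                    semantic_context = c(256L, 320L),
                    texture_separable = c(160L, 160L), c(128L, 128L))
  stopifnot(all(shape >= 8), n_classes >= 2, noise_sd >= 0)
  structure(list(kind = kind, shape = as.integer(shape),
                 n_classes = as.integer(n_classes), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# smooth voronoi-ish partition of a (H, W) grid into n_regions cells
voronoi_labels <- function(H, W, n_regions) {
  sy <- runif(n_regions, 1, H)
  sx <- runif(n_regions, 1, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  best <- matrix(1L, H, W)
  bestd <- (yy - sy[1])^2 + (xx - sx[1])^2
  for (r in seq_len(n_regions)[-1]) {
    d <- (yy - sy[r])^2 + (xx - sx[r])^2
    upd <- d < bestd
    best[upd] <- r
    bestd[upd] <- d[upd]
  }
  best
}

#' Generate a synthetic fixture
#'
#' @param spec a [fixture_spec()].
#' @return list with `stack` (an [image_stack()]) and `gt` (integer label
#'   matrix, or `(y, x, plane)` array for `volume3d`).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, switch(spec$kind,
    intensity_separable = fixture_intensity(spec),
    texture_separable = fixture_texture(spec),
    semantic_context = fixture_context(spec),
    instances = fixture_instances(spec),
    volume3d = fixture_volume(spec),
    multichannel = fixture_multichannel(spec)))
}

fixture_intensity <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]; K <- spec$n_classes
  if (K * 9 > H * W) stop("more classes than the area allows")
  gt <- ((voronoi_labels(H, W, max(K, 2 * K)) - 1L) %% K) + 1L
  delta <- max(4 * spec$noise_sd, 0.15)
  means <- 0.5 + (seq_len(K) - (K + 1) / 2) * delta
  means <- (means - min(means)) / max(max(means) - min(means), 1e-12) * 0.8 + 0.1
  img <- matrix(means[gt], H, W) + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  list(stack = image_stack(img), gt = gt)
}

fixture_texture <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]; K <- spec$n_classes
  gt <- ((voronoi_labels(H, W, max(4L, K)) - 1L) %% K) + 1L
  # per-class smoothing scale: autocorrelation lengths differ well beyond the
  # 3x the contract demands — per-pixel filter responses overlap too much at
  # small ratios for a pixel classifier to stay reliably above 0.9 mIoU
  sig <- 0.5 * 8^(seq_len(K) - 1L)
  img <- matrix(0, H, W)
  for (k in seq_len(K)) {
    tex <- smooth2(matrix(rnorm(H * W), H, W), sig[k])
    tex <- (tex - mean(tex)) / stats::sd(tex) * 0.15 + 0.5
    img[gt == k] <- tex[gt == k]
  }
  list(stack = image_stack(img), gt = gt)
}

# Two squares with identical interior appearance, one embedded in a bright
# environment and one in a dark environment; the two square classes are
# distinguishable only by the identity of the enclosing region, never by any
# local feature. Three classes: 1 = background (both environments),
# 2 = square in the bright half, 3 = square in the dark half.
fixture_context <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  side <- 64L
  stopifnot(H >= side + 32, W >= 2 * side + 64)
  bgs <- c(0.95, 0.25)
  img <- matrix(0, H, W)
  img[, 1:(W %/% 2)] <- bgs[1]
  img[, (W %/% 2 + 1):W] <- bgs[2]
  gt <- matrix(1L, H, W)
  yoff <- (H - side) %/% 2
  xc <- c(W %/% 4, 3L * (W %/% 4))
  for (i in 1:2) {
    ys <- yoff:(yoff + side - 1L)
    xs <- (xc[i] - side %/% 2):(xc[i] + side %/% 2 - 1L)
    img[ys, xs] <- 0.6
    gt[ys, xs] <- i + 1L
  }
  img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  list(stack = image_stack(img), gt = gt)
}

fixture_instances <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  n <- max(3L, spec$n_classes)
  gt <- matrix(0L, H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  r <- max(4, round(min(H, W) / 10))
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 100L) {
    tries <- tries + 1L
    cy <- runif(1, r + 1, H - r)
    cx <- runif(1, r + 1, W - r)
    disk <- (yy - cy)^2 + (xx - cx)^2 <= r^2
    if (any(gt[disk] > 0)) next
    placed <- placed + 1L
    gt[disk] <- placed
  }
  img <- 0.3 + 0.5 * (gt > 0) + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
  list(stack = image_stack(img), gt = gt)
}

fixture_volume <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]; P <- spec$shape[3]
  gt <- array(1L, dim = c(H, W, P))
  img <- array(rnorm(H * W * P, 0.3, spec$noise_sd), dim = c(H, W, P))
  n_ell <- 3L
  for (i in seq_len(n_ell)) {
    c0 <- c(runif(1, H * 0.25, H * 0.75), runif(1, W * 0.25, W * 0.75),
            runif(1, P * 0.3, P * 0.7))
    rad <- c(runif(1, H / 8, H / 5), runif(1, W / 8, W / 5), runif(1, P / 6, P / 3))
    for (p in seq_len(P)) {
      dz2 <- ((p - c0[3]) / rad[3])^2
      if (dz2 >= 1) next
      yy <- matrix(seq_len(H), H, W)
      xx <- matrix(seq_len(W), H, W, byrow = TRUE)
      inside <- ((yy - c0[1]) / rad[1])^2 + ((xx - c0[2]) / rad[2])^2 <= 1 - dz2
      sl <- gt[, , p]
      sl[inside] <- 2L
      gt[, , p] <- sl
      im <- img[, , p]
      im[inside] <- im[inside] + 0.4
      img[, , p] <- im
    }
  }
  list(stack = image_stack(img, axes = c("y", "x", "plane")), gt = gt)
}

# class information split across two channels (XOR structure): per pixel a
# hidden bit s selects (lo, lo)/(hi, hi) for class 1 and (lo, hi)/(hi, lo)
# for class 2, so each channel's marginal is identical between classes.
fixture_multichannel <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  gt <- ((voronoi_labels(H, W, 4L) - 1L) %% 2L) + 1L
  s <- matrix(runif(H * W) < 0.5, H, W)
  lo <- 0.3; hi <- 0.7
  ch1 <- ifelse(s, hi, lo)
  ch2 <- ifelse(xor(s, gt == 2L), hi, lo)
  img <- array(0, dim = c(H, W, 2))
  img[, , 1] <- ch1 + rnorm(H * W, 0, spec$noise_sd)
  img[, , 2] <- ch2 + rnorm(H * W, 0, spec$noise_sd)
  list(stack = image_stack(img, axes = c("y", "x", "channel")), gt = gt)
}

#' Scribble annotations for a fixture ground truth
#'
#' Thin wrapper over [generate_scribbles()] so fixtures and benchmarks share
#' one scribble path. A zero/near-zero density yields an empty mask with a
#' warning.
#' @param gt label matrix.
#' @param cfg a [scribble_config()] (or density shorthand).
#' @export
make_annotation_subset <- function(gt, cfg) {
  if (is.numeric(cfg)) {
    if (cfg <= 0) {
      warning("non-positive density: empty annotation mask")
      return(annotation_mask(matrix(0L, nrow(gt), ncol(gt))))
    }
    cfg <- scribble_config(density = cfg)
  }
  generate_scribbles(gt, cfg)
}
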