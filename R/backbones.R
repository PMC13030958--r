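# Toy randomly-initialized backbones. Pretrained networks (VGG16, DINOv2-like
# ViTs, ...) are pluggable third-party providers satisfying the same contract;
# nothing in this package downloads or ships weights. The toy versions
# reproduce the declared geometry (layer widths, downsampling factors, patch
# size 14 or 16, embedding width 384 or 1024) with seeded random weights, so
# every architectural code path is exercised without any network access.

#' Toy convolutional backbone (random weights)
#'
#' A three-stage convnet: 3x3 conv + ReLU (stride 1), then two stages of
#' 2x2 max-pool + 3x3 conv + ReLU (downsampling 2 and 4). Weights are drawn
#' once from a seeded normal distribution. Satisfies the backbone-provider
#' contract consumed by [extractor_cnn_pyramid()]: fields `id`, `n_in`,
#' `layer_channels`, `layer_downsample`, `min_size`, `receptive_radius`, and
#' `forward(plane)` returning one `(y, x, channels)` array per layer.
#'
#' @param n_in input channel count.
#' @param widths channels per stage.
#' @param pool logical per stage: max-pool 2x2 before that stage's conv.
#'   Defaults to pooling before every stage after the first. Fewer pools keep
#'   spatial localization while extra conv stages still grow the receptive
#'   field.
#' @param seed weight seed.
#' @export
toy_cnn_backbone <- function(n_in = 1L, widths = c(8L, 16L, 16L),
                             pool = c(FALSE, rep(TRUE, length(widths) - 1L)),
                             pool_type = c("max", "avg"),
                             activation = c("relu", "tanh"), gain = 1,
                             seed = 42L) {
  stopifnot(length(pool) == length(widths))
  pool_type <- match.arg(pool_type)
  activation <- match.arg(activation)
  n_prev <- c(n_in, widths[-length(widths)])
  kernels <- with_seed(seed, lapply(seq_along(widths), function(l) {
    # (3, 3, in, out) weights, He-style scale
    array(stats::rnorm(9 * n_prev[l] * widths[l], sd = sqrt(2 / (9 * n_prev[l]))),
          dim = c(3, 3, n_prev[l], widths[l]))
  }))
  ds <- as.integer(2^cumsum(pool))
  # receptive-field radius: conv radius 1 at each stage, dilated by the stride
  rf <- sum(1L * ds)
  forward <- function(plane) {
    cur <- plane
    out <- vector("list", length(widths))
    for (l in seq_along(widths)) {
      if (pool[l]) {
        poolfun <- if (pool_type == "avg")
          function(m) cpp_resize_bilinear(m, (nrow(m) + 1L) %/% 2L,
                                          (ncol(m) + 1L) %/% 2L)
        else cpp_maxpool2
        pooled <- lapply(seq_len(dim(cur)[3]), function(c_) poolfun(cur[, , c_]))
        cur <- array(unlist(pooled), dim = c(dim(pooled[[1]]), dim(cur)[3]))
      }
      nxt <- array(0, dim = c(dim(cur)[1:2], widths[l]))
      for (o in seq_len(widths[l])) {
        acc <- matrix(0, dim(cur)[1], dim(cur)[2])
        for (c_ in seq_len(dim(cur)[3]))
          acc <- acc + cpp_conv2(cur[, , c_], kernels[[l]][, , c_, o])
        nxt[, , o] <- if (activation == "tanh") tanh(gain * acc)
                      else pmax(acc, 0)
      }
      cur <- nxt
      out[[l]] <- cur
    }
    out
  }
  list(id = sprintf("toy_cnn(n_in=%d,widths=%s,pool=%s,%s,%s%g,seed=%d)", n_in,
                    paste(widths, collapse = "-"),
                    paste(as.integer(pool), collapse = ""), pool_type,
                    activation, gain, seed),
       n_in = as.integer(n_in), layer_channels = as.integer(widths),
       layer_downsample = ds, min_size = 8L, receptive_radius = rf,
       forward = forward)
}

#' Toy patch-embedding backbone (random projection)
#'
#' Embeds each `patch_size^2 * n_in` patch vector through a fixed random
#' linear map followed by tanh. Geometry defaults follow the small-ViT
#' convention: 14-pixel patches and 384-dimensional embeddings; the large
#' variant uses 16-pixel patches and 1024 features.
#'
#' @param patch_size pixels per patch side.
#' @param dim embedding width.
#' @param n_in input channel count.
#' @param seed weight seed.
#' @export
toy_vit_backbone <- function(patch_size = 14L, dim = 384L, n_in = 1L, seed = 42L) {
  W <- with_seed(seed, matrix(
    stats::rnorm(patch_size^2 * n_in * dim, sd = 1 / patch_size),
    patch_size^2 * n_in, dim))
  list(id = sprintf("toy_vit(patch=%d,dim=%d,n_in=%d,seed=%d)",
                    patch_size, dim, n_in, seed),
       patch_size = as.integer(patch_size), dim = as.integer(dim),
       n_in = as.integer(n_in),
       embed = function(P) tanh(P %*% W))
}

# run `code` under set.seed(seed) without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
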