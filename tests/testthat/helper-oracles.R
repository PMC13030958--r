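# Independent oracles used across the suite. These re-derive the documented
# kernel conventions and compute everything by direct dense convolution /
# explicit enumeration, never by calling the implementation under test.

# symmetric reflection (edge included) of 1-based index i into 1..n
oracle_reflect <- function(i, n) {
  i <- i - 1L
  while (any(bad <- i < 0 | i >= n)) {
    i[bad & i < 0] <- -i[bad & i < 0] - 1L
    bad <- i >= n
    i[bad] <- 2L * n - 1L - i[bad]
  }
  i + 1L
}

# dense 2D convolution with a centered kernel, symmetric reflect boundary;
# vectorized over shifted copies (independent of the package's C++ path)
oracle_conv2 <- function(img, ker) {
  H <- nrow(img); W <- ncol(img)
  rh <- (nrow(ker) - 1L) / 2L
  rw <- (ncol(ker) - 1L) / 2L
  out <- matrix(0, H, W)
  ys <- seq_len(H); xs <- seq_len(W)
  for (a in -rh:rh) {
    ry <- oracle_reflect(ys + a, H)
    for (b in -rw:rw) {
      k <- ker[a + rh + 1L, b + rw + 1L]
      if (k == 0) next
      rx <- oracle_reflect(xs + b, W)
      out <- out + k * img[ry, rx]
    }
  }
  out
}

# 1D kernels, re-derived from the documented convention
oracle_kernel1d <- function(sigma, order = 0L) {
  radius <- max(1L, ceiling(4 * sigma))
  t <- seq(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-t / sigma^2 * g)
  k <- (t^2 / sigma^4 - 1 / sigma^2) * g
  k - mean(k)
}

oracle_sep_kernel <- function(ky, kx) outer(ky, kx)

# the full 8-channel filter response at one sigma, all by dense convolution
# and the explicit closed-form symmetric 2x2 eigen decomposition
oracle_filterbank_sigma <- function(img, sigma) {
  g0 <- oracle_kernel1d(sigma, 0L)
  g1 <- oracle_kernel1d(sigma, 1L)
  g2 <- oracle_kernel1d(sigma, 2L)
  eig2 <- function(a, b, c) {
    tr <- (a + c) / 2; disc <- sqrt(((a - c) / 2)^2 + b^2)
    list(hi = tr + disc, lo = tr - disc)
  }
  gs <- oracle_conv2(img, oracle_sep_kernel(g0, g0))
  log_ <- oracle_conv2(img, oracle_sep_kernel(g2, g0)) +
          oracle_conv2(img, oracle_sep_kernel(g0, g2))
  dy <- oracle_conv2(img, oracle_sep_kernel(g1, g0))
  dx <- oracle_conv2(img, oracle_sep_kernel(g0, g1))
  ggm <- sqrt(dy^2 + dx^2)
  gi <- oracle_kernel1d(0.66 * sigma, 0L)
  dog <- oracle_conv2(img, oracle_sep_kernel(gi, gi)) - gs
  sh <- sigma / 2
  h0 <- oracle_kernel1d(sh, 0L)
  h1 <- oracle_kernel1d(sh, 1L)
  sdy <- oracle_conv2(img, oracle_sep_kernel(h1, h0))
  sdx <- oracle_conv2(img, oracle_sep_kernel(h0, h1))
  sm <- function(m) oracle_conv2(m, oracle_sep_kernel(h0, h0))
  st <- eig2(sm(sdy^2), sm(sdy * sdx), sm(sdx^2))
  he <- eig2(oracle_conv2(img, oracle_sep_kernel(g2, g0)),
             oracle_conv2(img, oracle_sep_kernel(g1, g1)),
             oracle_conv2(img, oracle_sep_kernel(g0, g2)))
  list(gs, log_, ggm, dog, st$hi, st$lo, he$hi, he$lo)
}

# brute-force double-loop mIoU
oracle_miou <- function(pred, gt) {
  classes <- sort(union(unique(pred[pred > 0]), unique(gt[gt > 0])))
  ious <- numeric(0)
  for (cl in classes) {
    inter <- 0L; uni <- 0L
    for (i in seq_len(nrow(gt)))
      for (j in seq_len(ncol(gt))) {
        p <- pred[i, j] == cl; g <- gt[i, j] == cl
        if (p && g) inter <- inter + 1L
        if (p || g) uni <- uni + 1L
      }
    ious <- c(ious, inter / uni)
  }
  mean(ious)
}

# sort-based percentile (type-7 linear interpolation), written out explicitly
oracle_percentile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# small deterministic blobby multi-class mask for scribble tests
blob_mask <- function(H, W, K, seed) {
  set.seed(seed)
  v <- matrix(0L, H, W)
  cy <- runif(K + 2, 1, H); cx <- runif(K + 2, 1, W)
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  best <- matrix(Inf, H, W)
  for (r in seq_len(K + 2)) {
    d <- (yy - cy[r])^2 + (xx - cx[r])^2
    upd <- d < best
    v[upd] <- ((r - 1L) %% K) + 1L
    best[upd] <- d[upd]
  }
  v
}

fast_miou <- function(pred, gt) scribbleseg::compute_miou(pred, gt)$miou
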