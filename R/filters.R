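# Sampled Gaussian-family 1D kernels and the multi-scale filter bank.
#
# Kernel conventions (documented; the test oracle re-derives them
# independently with dense 2D convolutions):
#   * truncation radius ceil(4*sigma), minimum 1
#   * order 0: samples of exp(-t^2/2s^2), normalized to sum 1
#   * order 1: samples of -t/s^2 * g(t) (sums to 0 exactly by antisymmetry)
#   * order 2: samples of (t^2/s^4 - 1/s^2) * g(t), mean-corrected to sum 0
#     so that derivative responses to a constant image vanish identically
#   * boundary handling: symmetric reflection including the edge pixel

gauss_kernel1d <- function(sigma, order = 0L, radius = ceiling(4 * sigma)) {
  radius <- max(1L, as.integer(radius))
  t <- seq(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-t / sigma^2 * g)
  if (order == 2L) {
    k <- (t^2 / sigma^4 - 1 / sigma^2) * g
    return(k - mean(k))
  }
  stop("order must be 0, 1 or 2")
}

smooth2 <- function(img, sigma, radius = ceiling(4 * sigma)) {
  k <- gauss_kernel1d(sigma, 0L, radius)
  cpp_sepconv2(img, k, k)
}

# first derivatives along y (rows) and x (cols) at scale sigma
deriv2 <- function(img, sigma, radius = ceiling(4 * sigma)) {
  g <- gauss_kernel1d(sigma, 0L, radius)
  d <- gauss_kernel1d(sigma, 1L, radius)
  list(dy = cpp_sepconv2(img, d, g), dx = cpp_sepconv2(img, g, d))
}

# eigenvalues (sorted descending) of the symmetric 2x2 field [[a, b], [b, c]]
sym_eig2 <- function(a, b, c) {
  tr <- (a + c) / 2
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  list(hi = tr + disc, lo = tr - disc)
}

# The 8 filter-bank channels for one 2D channel at one sigma, in order:
# gaussian, laplacian-of-gaussian, gradient magnitude, difference of
# gaussians, structure-tensor eigenvalues (desc), hessian eigenvalues (desc).
# Structure tensor uses derivative and integration scales both sigma/2, and
# DoG uses G(0.66*sigma) - G(sigma), so every chain's support stays within the
# declared context margin (see context_margin()).
filterbank_one_sigma <- function(img, sigma) {
  g0 <- gauss_kernel1d(sigma, 0L)
  g1 <- gauss_kernel1d(sigma, 1L)
  g2 <- gauss_kernel1d(sigma, 2L)
  gs <- cpp_sepconv2(img, g0, g0)
  log_ <- cpp_sepconv2(img, g2, g0) + cpp_sepconv2(img, g0, g2)
  dy <- cpp_sepconv2(img, g1, g0)
  dx <- cpp_sepconv2(img, g0, g1)
  ggm <- sqrt(dy^2 + dx^2)
  dog <- smooth2(img, 0.66 * sigma) - gs
  sh <- sigma / 2
  dh <- deriv2(img, sh)
  st <- sym_eig2(smooth2(dh$dy^2, sh), smooth2(dh$dy * dh$dx, sh),
                 smooth2(dh$dx^2, sh))
  he <- sym_eig2(cpp_sepconv2(img, g2, g0), cpp_sepconv2(img, g1, g1),
                 cpp_sepconv2(img, g0, g2))
  list(gs, log_, ggm, dog, st$hi, st$lo, he$hi, he$lo)
}

# margin needed so crop features equal full-image features at scale sigma:
# single-pass kernels have radius ceil(4s); the structure-tensor chain is two
# passes of radius ceil(2s) each.
filter_margin_one_sigma <- function(sigma) {
  max(max(1L, ceiling(4 * sigma)), 2L * max(1L, ceiling(2 * sigma)))
}
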