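# Feature extractors: kernels against dense-convolution oracles, channel
# counts, context margins, patch grids, fusion, multi-projection.

test_that("gaussian baseline: defaults, constants, impulse vs dense oracle", {
  spec <- extractor_gaussian()
  expect_equal(spec$params$sigma, 3)
  expect_error(extractor_gaussian(-1), "positive")

  const <- matrix(2.5, 32, 32)
  fm <- extract_plane_features(spec, const)
  expect_equal(dim(fm$values), c(32L, 32L, 2L))
  expect_equal(fm$values[, , 1], const)
  expect_equal(fm$values[, , 2], const, tolerance = 1e-12)

  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  fm2 <- extract_plane_features(spec, imp)
  k <- oracle_kernel1d(3, 0L)
  expect_equal(fm2$values[, , 2], oracle_conv2(imp, oracle_sep_kernel(k, k)),
               tolerance = 1e-12)
})

test_that("filterbank: defaults, channel count, constant-image derivatives", {
  spec <- extractor_filterbank()
  expect_equal(spec$params$sigmas, c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0))
  expect_equal(n_feature_channels(spec, 1L), 57L)
  expect_equal(n_feature_channels(spec, 3L), 171L)
  expect_error(extractor_filterbank(numeric(0)))
  expect_error(extractor_filterbank(c(1, -2)))
  expect_error(extract_plane_features(spec, matrix(1, 1, 1)), "degenerate")

  fm <- extract_plane_features(extractor_filterbank(c(0.7, 1.6)),
                               matrix(4, 24, 24))
  # per sigma: LoG, GGM, DoG, ST eigs, Hessian eigs all zero on a constant
  for (s in 0:1)
    for (ch in c(2, 3, 4, 5, 6, 7, 8) + 1 + 8 * s)
      expect_lt(max(abs(fm$values[, , ch])), 1e-10)
})

test_that("filterbank channels match the dense-convolution oracle (spot)", {
  set.seed(21)
  img <- matrix(rnorm(24 * 24), 24, 24)
  for (s in c(1.0, 3.5)) {
    fm <- extract_plane_features(extractor_filterbank(s), img)
    orc <- oracle_filterbank_sigma(img, s)
    for (ch in 1:8)
      expect_lt(max(abs(fm$values[, , ch + 1] - orc[[ch]])), 1e-6)
  }
})

test_that("declared channel count equals realized count for every kind", {
  set.seed(31)
  img1 <- matrix(runif(48 * 48), 48, 48)
  img3 <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  bb1 <- toy_cnn_backbone(1L, widths = c(4L, 6L), seed = 5)
  bb3 <- toy_cnn_backbone(3L, widths = c(4L, 6L), seed = 5)
  vb1 <- toy_vit_backbone(patch_size = 8L, dim = 32L, n_in = 1L, seed = 5)
  cases <- list(
    list(spec = extractor_gaussian(1.5), plane = img1, n_in = 1L),
    list(spec = extractor_gaussian(), plane = img3, n_in = 3L),
    list(spec = extractor_filterbank(c(0.7, 2)), plane = img3, n_in = 3L),
    list(spec = extractor_context_mean(c(4, 8)), plane = img1, n_in = 1L),
    list(spec = extractor_cnn_pyramid(bb1, scales = c(1L, 2L)), plane = img1, n_in = 1L),
    list(spec = extractor_cnn_pyramid(bb3, scales = 2L, layers = 2L), plane = img3, n_in = 3L),
    list(spec = extractor_vit(vb1), plane = img1, n_in = 1L),
    list(spec = extractor_combined(extractor_gaussian(),
                                   extractor_filterbank(c(1, 2))),
         plane = img1, n_in = 1L))
  for (cs in cases) {
    fm <- extract_plane_features(cs$spec, cs$plane)
    expect_equal(dim(fm$values)[3], n_feature_channels(cs$spec, cs$n_in),
                 info = cs$spec$kind)
    expect_equal(dim(fm$values)[1:2], dim(cs$plane)[1:2], info = cs$spec$kind)
  }
})

test_that("context margins follow the documented support rules", {
  expect_equal(context_margin(extractor_gaussian(3)), 12L)
  expect_equal(context_margin(extractor_filterbank()), 40L)
  expect_equal(context_margin(extractor_filterbank(10)), 40L)
  expect_true(is.na(context_margin(extractor_vit(
    toy_vit_backbone(patch_size = 8L, dim = 16L)))))
  expect_true(extractor_vit(toy_vit_backbone(8L, 16L))$whole_image_context)
  comb <- extractor_combined(extractor_gaussian(3), extractor_filterbank(c(1, 2)))
  expect_equal(context_margin(comb), 12L)  # max(gaussian 12, filterbank 8)
})

test_that("crop equivalence: padded-crop features equal full-image features", {
  set.seed(41)
  img <- matrix(rnorm(60 * 70), 60, 70)
  for (spec in list(extractor_gaussian(2), extractor_filterbank(c(0.7, 1.6)),
                    extractor_context_mean(3))) {
    m <- context_margin(spec)
    full <- extract_plane_features(spec, img)
    y0 <- 21L; y1 <- 34L; x0 <- 11L; x1 <- 30L
    crop <- img[max(1, y0 - m):min(60, y1 + m), max(1, x0 - m):min(70, x1 + m)]
    fmc <- extract_plane_features(spec, crop)
    oy <- y0 - max(1, y0 - m); ox <- x0 - max(1, x0 - m)
    expect_identical(
      fmc$values[(oy + 1):(oy + (y1 - y0 + 1)), (ox + 1):(ox + (x1 - x0 + 1)), ],
      full$values[y0:y1, x0:x1, ], )
  }
})

test_that("translation equivariance away from the context-margin border band", {
  set.seed(42)
  base <- matrix(rnorm(80 * 80), 80, 80)
  dy <- 3L; dx <- 5L
  shifted <- base[(1 + dy):80, (1 + dx):80]
  orig <- base[1:(80 - dy), 1:(80 - dx)]
  spec <- extractor_filterbank(c(0.7, 1.6))
  m <- context_margin(spec)
  f1 <- extract_plane_features(spec, base)
  f2 <- extract_plane_features(spec, shifted)
  # interior of the shifted frame, margin px away from every crop border
  ys <- (m + 1):(80 - dy - m); xs <- (m + 1):(80 - dx - m)
  expect_equal(f2$values[ys, xs, ], f1$values[ys + dy, xs + dx, ],
               tolerance = 1e-12)
})

test_that("cnn pyramid: identity layer, arithmetic, shape contract", {
  bb <- toy_cnn_backbone(1L, widths = c(4L, 6L), seed = 9)
  img <- matrix(runif(40 * 40), 40, 40)

  # scales {1}, first layer has downsampling 1 -> map passes through unchanged
  spec1 <- extractor_cnn_pyramid(bb, scales = 1L, layers = 1L)
  fm1 <- extract_plane_features(spec1, img)
  direct <- bb$forward(array(img, c(40, 40, 1)))[[1]]
  expect_equal(fm1$values, direct, tolerance = 1e-12)

  # channel arithmetic: (4 + 6) x |{1, 2}| = 20
  spec2 <- extractor_cnn_pyramid(bb, scales = c(1L, 2L))
  expect_equal(n_feature_channels(spec2, 1L), 20L)
  fm2 <- extract_plane_features(spec2, img)
  expect_equal(dim(fm2$values), c(40L, 40L, 20L))

  # spatial shape preserved for every scale combination
  for (sc in list(1L, 2L, c(1L, 4L))) {
    fm <- extract_plane_features(extractor_cnn_pyramid(bb, scales = sc), img)
    expect_equal(dim(fm$values)[1:2], c(40L, 40L))
  }
  expect_error(extract_plane_features(
    extractor_cnn_pyramid(bb, scales = 8L), matrix(runif(24 * 24), 24, 24)),
    "scale")
  expect_error(extractor_cnn_pyramid(bb, scales = 3L), "scales")
})

test_that("vit patch grid geometry and embedding widths", {
  vb <- toy_vit_backbone(patch_size = 14L, dim = 384L, seed = 3)
  expect_equal(vb$dim, 384L)
  expect_equal(toy_vit_backbone(patch_size = 16L, dim = 1024L)$dim, 1024L)

  spec <- extractor_vit(vb)
  img <- matrix(runif(140 * 140), 140, 140)
  g <- extract_vit_patch(spec, img)
  expect_equal(dim(g$embeddings), c(10L, 10L, 384L))
  expect_equal(g$origin_offset, c(0L, 0L))

  img2 <- matrix(runif(141 * 139), 141, 139)
  g2 <- extract_vit_patch(spec, img2)
  expect_equal(g2$resized_shape, c(140L, 140L))
  expect_equal(dim(g2$embeddings)[1:2], c(10L, 10L))
  expect_equal(g2$origin_offset, c(-1L, 1L))

  # missing backend -> instructive error
  broken <- spec
  broken$params$backbone <- NULL
  expect_error(extract_vit_patch(broken, img), "backend missing")
})

test_that("patch upsampling is exact and piecewise constant", {
  vb <- toy_vit_backbone(patch_size = 8L, dim = 12L, seed = 4)
  spec <- extractor_vit(vb)
  img <- matrix(runif(32 * 24), 32, 24)
  g <- extract_vit_patch(spec, img)
  up <- upsample_patch_features(g, c(32L, 24L))
  expect_equal(dim(up$values), c(32L, 24L, 12L))
  # nearest-neighbor: every pixel's vector equals its covering patch exactly
  for (py in 1:4) for (px in 1:3) {
    block <- up$values[((py - 1) * 8 + 1):(py * 8), ((px - 1) * 8 + 1):(px * 8), ]
    expect_equal(block[3, 5, ], g$embeddings[py, px, ])
    expect_true(all(apply(block, 3, function(m) max(m) - min(m)) == 0))
  }

  # single-patch grid -> every pixel identical
  small <- matrix(runif(8 * 8), 8, 8)
  gs <- extract_vit_patch(spec, small)
  ups <- upsample_patch_features(gs, c(8L, 8L))
  expect_true(all(apply(ups$values, 3, function(m) max(m) - min(m)) == 0))

  # bilinear on a uniform patch grid (constant image) reproduces the
  # embedding everywhere, like nearest
  gc_ <- extract_vit_patch(spec, matrix(0.4, 32, 24))
  upb <- upsample_patch_features(gc_, c(32L, 24L), interpolation = "bilinear")
  for (d_ in 1:12)
    expect_lt(max(abs(upb$values[, , d_] - gc_$embeddings[1, 1, d_])), 1e-9)
})

test_that("combine_features: order, counts, errors", {
  set.seed(51)
  img <- matrix(runif(30 * 30), 30, 30)
  a <- extract_plane_features(extractor_gaussian(1), img)
  b <- extract_plane_features(extractor_filterbank(c(1)), img)
  ab <- combine_features(list(a, b))
  expect_equal(dim(ab$values)[3], 2L + 9L)
  expect_equal(ab$values[, , 1:2], a$values)
  expect_equal(ab$values[, , 3:11], b$values)
  ba <- combine_features(list(b, a))
  expect_false(identical(ab$values, ba$values))
  expect_equal(sort(c(ab$values)), sort(c(ba$values)))

  expect_identical(combine_features(list(a)), a)
  bad <- extract_plane_features(extractor_gaussian(1), matrix(runif(100), 10, 10))
  expect_error(combine_features(list(a, bad)), "map 2")

  # fused spec: channel count = 441 for filterbank + small-vit geometry
  comb <- extractor_combined(extractor_filterbank(),
                             extractor_vit(toy_vit_backbone(14L, 384L)))
  expect_equal(n_feature_channels(comb, 1L), 441L)
  expect_true(comb$whole_image_context)
})

test_that("multiprojection equals the manual slicing oracle", {
  set.seed(61)
  vol <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  st <- image_stack(vol, axes = c("y", "x", "plane"))
  base <- extractor_gaussian(1)
  spec <- extractor_multiprojection(base)
  expect_equal(n_feature_channels(spec, 1L), 6L)

  vals <- extract_volume_features(st, spec)
  expect_equal(dim(vals), c(8L, 8L, 8L, 6L))

  # oracle: loop over orientations and slices with explicit transposition
  Fb <- 2L
  orc <- array(0, dim = c(8, 8, 8, 6))
  for (p in 1:8) {
    fm <- extract_plane_features(base, vol[, , p])
    orc[, , p, 1:2] <- fm$values
  }
  for (y in 1:8) {
    fm <- extract_plane_features(base, vol[y, , ])      # (x, plane)
    for (f in 1:2) orc[y, , , 2 + f] <- fm$values[, , f]
  }
  for (x in 1:8) {
    fm <- extract_plane_features(base, vol[, x, ])      # (y, plane)
    for (f in 1:2) orc[, x, , 4 + f] <- fm$values[, , f]
  }
  expect_equal(vals, orc, tolerance = 1e-12)

  # constant volume: the three orientation blocks are identical arrays
  cst <- image_stack(array(3, dim = c(6, 6, 6)), axes = c("y", "x", "plane"))
  cv <- extract_volume_features(cst, spec)
  expect_equal(cv[, , , 1:2], cv[, , , 3:4])
  expect_equal(cv[, , , 1:2], cv[, , , 5:6])

  # 2D input -> directed to the base extractor
  flat <- image_stack(matrix(runif(64), 8, 8))
  expect_error(extract_volume_features(flat, spec), "base 2D extractor")
  expect_error(extractor_multiprojection(spec), "2D")
})

test_that("plugin registry accepts third-party extractors", {
  register_extractor("test_identity",
                     extract = function(spec, plane)
                       feature_map(plane, "test_identity"),
                     channels = function(spec, n_in) n_in,
                     margin = function(spec) 0L)
  spec <- scribbleseg:::new_extractor_spec("test_identity", list())
  img <- matrix(runif(25), 5, 5)
  fm <- extract_plane_features(spec, img)
  expect_equal(fm$values[, , 1], img)
  expect_equal(n_feature_channels(spec, 1L), 1L)
  expect_error(extract_plane_features(
    scribbleseg:::new_extractor_spec("no_such_kind", list()), img),
    "unknown extractor kind")
})
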