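# Scribble synthesis from ground truth, dataset preparation, mIoU scoring
# and the benchmark loop.

test_that("primary skeleton: bars, disks, idempotence", {
  bar <- matrix(0L, 9, 101)
  bar[3:7, ] <- 1L
  sk <- primary_skeleton(bar)
  expect_true(all(bar[sk == 1] == 1L))             # containment
  expect_true(all(sk[5, 20:80] == 1L))             # central row segment

  yy <- matrix(seq_len(41), 41, 41)
  xx <- t(yy)
  disk <- matrix(as.integer((yy - 21)^2 + (xx - 21)^2 <= 15^2), 41, 41)
  skd <- primary_skeleton(disk)
  expect_true(all(disk[skd == 1] == 1L))
  # skeleton of a disk collapses to a small central cluster
  ij <- which(skd == 1, arr.ind = TRUE)
  expect_lt(max(abs(ij - 21)), 8)

  expect_identical(primary_skeleton(skd), skd)     # idempotent on 1-px sets
  expect_equal(sum(primary_skeleton(matrix(0L, 5, 5))), 0L)
})

test_that("secondary skeleton lies between the primary and the boundary", {
  bar <- matrix(0L, 21, 101)
  bar[4:18, ] <- 1L
  prim <- primary_skeleton(bar)
  sec <- secondary_skeleton(bar, prim, width = 1L)
  expect_true(all(bar[sec == 1] == 1L))            # inside the original mask
  expect_equal(sum(sec & prim), 0L)                # disjoint from the primary
  ij <- which(sec == 1, arr.ind = TRUE)
  # two bands parallel to the bar's long edges, one above, one below the ridge
  expect_true(any(ij[, 1] < 11) && any(ij[, 1] > 11))
  # away from the bar ends, band rows stay in the offset strips
  mid <- ij[ij[, 2] > 10 & ij[, 2] < 91, , drop = FALSE]
  expect_true(all(mid[, 1] %in% c(4:9, 13:18)))

  # mask == primary -> empty secondary
  line <- matrix(0L, 9, 30); line[5, 3:28] <- 1L
  expect_equal(sum(secondary_skeleton(line, primary_skeleton(line))), 0L)
  expect_error(secondary_skeleton(matrix(0L, 5, 5), matrix(1L, 5, 5)),
               "inside the mask")
})

test_that("perpendicular lines connect the skeleton to the boundary", {
  yy <- matrix(seq_len(41), 41, 41)
  disk <- matrix(as.integer((yy - 21)^2 + (t(yy) - 21)^2 <= 15^2), 41, 41)
  prim <- primary_skeleton(disk)
  set.seed(91)
  lines <- perpendicular_lines(disk, prim, n = 8L)
  expect_gt(length(lines), 0)
  dist <- scribbleseg:::cpp_dist_to_background(disk)
  for (ln in lines) {
    expect_true(all(disk[ln] == 1L))                       # strictly inside
    expect_true(prim[ln[1, 1], ln[1, 2]] == 1L)            # starts on skeleton
    endd <- dist[ln[nrow(ln), 1], ln[nrow(ln), 2]]
    expect_equal(endd, 1L)                                 # ends at boundary
    # disk of radius r: lengths ~ r within discretization of the start depth
    expect_lt(abs(nrow(ln) - dist[ln[1, 1], ln[1, 2]]), 2)
  }
  set.seed(91)
  lines2 <- perpendicular_lines(disk, prim, n = 8L)
  expect_identical(lines, lines2)                          # seeded
})

test_that("generate_scribbles: purity, density, determinism", {
  gt <- blob_mask(80, 80, 3, seed = 7)
  cfg <- scribble_config(0.01, seed = 5)
  ann <- generate_scribbles(gt, cfg)
  lab <- ann$labels[, , 1]
  expect_true(all(lab[lab > 0] == gt[lab > 0]))            # purity
  ach <- attr(ann, "achieved_density")
  expect_lt(abs(ach / 0.01 - 1), 0.10)                     # calibration
  ann2 <- generate_scribbles(gt, cfg)
  expect_identical(ann$labels, ann2$labels)                # deterministic

  # single-class gt covering the image
  ann3 <- generate_scribbles(matrix(1L, 60, 60), scribble_config(0.02, seed = 2))
  lab3 <- ann3$labels[, , 1]
  expect_true(all(lab3[lab3 > 0] == 1L))
  expect_lt(abs(attr(ann3, "achieved_density") / 0.02 - 1), 0.10)

  expect_error(generate_scribbles(matrix(0L, 10, 10), cfg), "no classes")
  expect_error(scribble_config(0), "density")
  expect_error(scribble_config(0.5, mix = c(1, 1, 1)))
})

test_that("scribble presets follow the stated styles", {
  expect_equal(scribble_preset("cell", 0.01)$width, 1L)
  expect_lt(max(scribble_preset("cell", 0.01)$length_range), 20L)
  expect_equal(scribble_preset("natural", 0.01)$width, 2L)
  expect_gt(max(scribble_preset("natural", 0.01)$length_range), 100L)
  expect_equal(scribble_preset("histology", 0.01)$width, 2L)
})

test_that("instance_to_semantic maps ids to foreground/background classes", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 3L
  m[7:9, 6:9] <- 7L
  sem <- instance_to_semantic(m)
  expect_setequal(unique(as.vector(sem)), c(1L, 2L))
  expect_equal(sum(sem == 1L), sum(m > 0))                 # fg count preserved
  expect_true(all(sem[m > 0] == 1L))
  expect_true(all(sem[m == 0] == 2L))

  # empty instance mask -> single class, removed by the single-class filter
  empty_sem <- instance_to_semantic(matrix(0L, 8, 8))
  expect_equal(unique(as.vector(empty_sem)), 2L)
  res <- filter_dataset(list(empty_sem), rules = list(multi_class_only = TRUE))
  expect_length(res$kept, 0)
  expect_equal(res$log$reason, "single_class")
})

test_that("filter_dataset applies the preparation rules with reason codes", {
  good <- matrix(rep(c(0L, 1L, 2L), each = 300), 30, 30)
  single <- matrix(2L, 30, 30)
  tiny <- matrix(1L, 30, 30); tiny[1, 1:4] <- 2L          # class 2 under 1%
  nocls0 <- matrix(rep(c(1L, 2L), each = 450), 30, 30)
  res <- filter_dataset(list(good, single, tiny),
                        rules = list(multi_class_only = TRUE,
                                     min_class_area = 0.01))
  expect_equal(res$kept, 1L)
  expect_equal(res$log$reason, c("", "single_class", "min_class_area"))

  res2 <- filter_dataset(list(good, nocls0),
                         rules = list(require_class0 = TRUE))
  expect_equal(res2$kept, 1L)
  expect_equal(res2$log$reason[2], "no_class0")
})

test_that("window_image picks the largest proper divisor above the minimum", {
  expect_equal(window_image(4200L, 1400L), 2100L)
  expect_equal(window_image(1400L, 1400L), 1400L)
  expect_equal(window_image(2801L, 1400L), 2801L)          # prime fallback
  expect_equal(window_image(c(4200L, 2800L), 1400L), c(2100L, 1400L))
  # windows partition the image exactly
  for (n in c(4200L, 2800L, 1500L)) {
    w <- window_image(n, 1400L)
    expect_true(w >= 1400L || w == n)
    expect_equal(n %% w, 0L)
  }
})

test_that("compute_miou matches hand counts and handles exclusions", {
  a <- matrix(1L, 4, 4)
  expect_equal(compute_miou(a, a)$miou, 1)

  gt <- matrix(c(1L, 2L), 4, 4)
  flip <- 3L - gt
  expect_equal(compute_miou(flip, gt)$miou, 0)

  # explicit 4x4 two-class case: IoU_A = 0.6, IoU_B = 0.5, mIoU = 0.55
  gt2 <- matrix(1L, 4, 4); gt2[3:4, ] <- 2L
  pr2 <- gt2
  pr2[2, 1:2] <- 2L   # two A pixels called B
  pr2[3, 1:2] <- 1L   # two B pixels called A
  sc <- compute_miou(pr2, gt2)
  expect_equal(unname(sc$per_class["1"]), 6 / 10)
  expect_equal(unname(sc$per_class["2"]), 6 / 10)
  gt3 <- matrix(1L, 4, 4); gt3[3:4, ] <- 2L
  pr3 <- gt3; pr3[1, ] <- 2L; pr3[3, 1:2] <- 1L
  sc3 <- compute_miou(pr3, gt3)
  expect_equal(sc3$miou, oracle_miou(pr3, gt3))

  # exclusion removes pixels from the counts
  exc <- matrix(FALSE, 4, 4); exc[2, 1:2] <- TRUE; exc[3, 1:2] <- TRUE
  expect_equal(compute_miou(pr2, gt2, exclude = exc)$miou, 1)

  expect_error(compute_miou(matrix(0L, 2, 2), matrix(0L, 2, 2)), "no classes")
  expect_error(compute_miou(matrix(1L, 2, 2), matrix(1L, 3, 3)), "shape")
})

test_that("run_benchmark produces one deterministic record per combination", {
  set.seed(95)
  fxs <- lapply(1:2, function(i)
    make_fixture(fixture_spec("intensity_separable", shape = c(48L, 48L),
                              seed = i)))
  images <- lapply(fxs, function(f) get_plane(f$stack))
  gts <- lapply(fxs, `[[`, "gt")
  specs <- list(gauss = extractor_gaussian(),
                gauss2 = extractor_gaussian(1.5))
  tab <- run_benchmark(images, gts, specs, levels = c(0.01, 0.025), seeds = 0L,
                       scribble_style = "cell")
  expect_equal(nrow(tab), 2L * 2L * 2L)
  expect_true(all(c("image", "extractor", "level", "seed", "miou",
                    "iou_1", "iou_2") %in% names(tab)))
  expect_true(all(tab$error == ""))
  expect_true(all(tab$miou >= 0 & tab$miou <= 1))
  expect_true(all(tab$iou_1 >= 0 & tab$iou_1 <= 1, na.rm = TRUE))

  tab2 <- run_benchmark(images, gts, specs, levels = c(0.01, 0.025), seeds = 0L,
                        scribble_style = "cell")
  expect_identical(tab$miou, tab2$miou)

  # per-item failures are logged, the run continues
  gts_bad <- gts
  gts_bad[[2]] <- matrix(1L, 48, 48) * 0L
  tab3 <- run_benchmark(images, gts_bad, specs["gauss"], levels = 0.01,
                        seeds = 0L, scribble_style = "cell")
  expect_equal(nrow(tab3), 2L)
  expect_true(tab3$error[2] != "")
  expect_true(is.na(tab3$miou[2]))
})
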