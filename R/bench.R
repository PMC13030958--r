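# Benchmark pipeline: dataset preparation (instance->semantic conversion,
# filtering rules, windowing), mIoU scoring, and the scribble->train->predict
# ->score loop producing one record per (image, extractor, level, seed).

#' Convert an instance-labeled mask to a semantic mask
#'
#' All instance ids > 0 become foreground class 1; background (0) becomes
#' class 2 so that the background itself is annotatable by scribbles.
#' @param instance_mask integer matrix, 0 = background.
#' @export
instance_to_semantic <- function(instance_mask) {
  m <- as.matrix(instance_mask)
  out <- matrix(2L, nrow(m), ncol(m))
  out[m > 0] <- 1L
  out
}

#' Mean intersection-over-union between two label masks
#'
#' `IoU_c = |pred = c & gt = c| / |pred = c | gt = c|` over all classes (> 0)
#' present in either mask; mIoU is their unweighted mean. Optionally a set of
#' pixels (e.g. training scribbles) is excluded from the counts.
#'
#' @param pred,gt integer label matrices of equal shape.
#' @param exclude optional logical matrix; TRUE pixels are ignored.
#' @return list with `miou` and named `per_class` IoU vector.
#' @export
compute_miou <- function(pred, gt, exclude = NULL) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch between pred and gt")
  if (!is.null(exclude)) {
    keep <- !exclude
    pred <- pred[keep]; gt <- gt[keep]
  }
  classes <- sort(union(unique(pred[pred > 0]), unique(gt[gt > 0])))
  if (length(classes) == 0) stop("no classes present in either mask")
  iou <- vapply(classes, function(cl) {
    inter <- sum(pred == cl & gt == cl)
    uni <- sum(pred == cl | gt == cl)
    inter / uni
  }, numeric(1))
  names(iou) <- classes
  list(miou = mean(iou), per_class = iou)
}

#' Filter a dataset of ground-truth masks
#'
#' Deterministic filtering with per-image reason codes. Available rules:
#' `require_class0` (drop masks with no class-0 pixels — the incomplete
#' annotation convention of expert-annotated histology masks),
#' `multi_class_only` (drop masks containing a single class), and
#' `min_class_area` (drop masks where any present class covers less than the
#' given fraction of the area; the reference pipeline uses 0.01).
#'
#' @param masks list of integer label matrices.
#' @param rules named list, e.g.
#'   `list(multi_class_only = TRUE, min_class_area = 0.01)`.
#' @return list with `kept` (indices) and `log` (data.frame index/kept/reason).
#' @export
filter_dataset <- function(masks, rules = list(multi_class_only = TRUE,
                                               min_class_area = 0.01)) {
  log <- data.frame(index = seq_along(masks), kept = TRUE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(masks)) {
    m <- as.matrix(masks[[i]])
    if (isTRUE(rules$require_class0) && !any(m == 0)) {
      log$kept[i] <- FALSE; log$reason[i] <- "no_class0"; next
    }
    present <- unique(as.vector(m))
    if (isTRUE(rules$multi_class_only) && length(present) < 2) {
      log$kept[i] <- FALSE; log$reason[i] <- "single_class"; next
    }
    if (!is.null(rules$min_class_area)) {
      fr <- table(m) / length(m)
      if (any(fr < rules$min_class_area)) {
        log$kept[i] <- FALSE; log$reason[i] <- "min_class_area"; next
      }
    }
  }
  list(kept = which(log$kept), log = log)
}

#' Window side length for splitting a large image
#'
#' Returns, per dimension, the largest proper divisor `d` of the dimension
#' with `min_side <= d < dimension` (so windows partition the image exactly);
#' when no such divisor exists the full dimension is returned (single window).
#' @param shape integer image dimensions.
#' @param min_side minimum window side (reference pipeline: 1400).
#' @export
window_image <- function(shape, min_side = 1400L) {
  vapply(as.integer(shape), function(n) {
    divs <- which(n %% seq_len(n - 1L) == 0)     # proper divisors
    divs <- divs[divs >= min_side]
    if (length(divs) == 0) n else max(divs)
  }, integer(1))
}

#' Run the scribble benchmark
#'
#' For each (image, extractor spec, annotation level, seed): generate
#' scribbles from the ground truth, train, predict the full image, and score
#' with mIoU. Per-item failures are logged and the run continues.
#'
#' @param images list of image planes (`(y, x)` matrices or `(y, x, channel)`
#'   arrays).
#' @param gts list of ground-truth label matrices (same length).
#' @param specs named list of extractor specs.
#' @param levels annotation densities (fractions), default the benchmark
#'   levels `c(0.0025, 0.01, 0.025)`.
#' @param seeds integer vector of seeds.
#' @param scribble_style preset passed to [scribble_preset()].
#' @param kind classifier kind.
#' @return data.frame of benchmark records (one per combination), with mIoU,
#'   per-class IoU columns and runtimes in seconds.
#' @export
run_benchmark <- function(images, gts, specs,
                          levels = c(0.0025, 0.01, 0.025), seeds = 0L,
                          scribble_style = "histology",
                          kind = "gradient_boosted_trees") {
  stopifnot(length(images) == length(gts), length(images) >= 1,
            length(specs) >= 1, length(levels) >= 1)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$kind, "")
  recs <- list()
  maxK <- max(vapply(gts, function(g) length(unique(g[g > 0])), 1L))
  for (ii in seq_along(images)) {
    for (si in seq_along(specs)) {
      for (lv in levels) {
        for (sd in seeds) {
          rec <- tryCatch({
            cfg <- scribble_preset(scribble_style, density = lv, seed = sd)
            t0 <- proc.time()[["elapsed"]]
            ann <- generate_scribbles(gts[[ii]], cfg)
            stack <- image_stack(as_plane(images[[ii]]),
                                 axes = c("y", "x", "channel"))
            t1 <- proc.time()[["elapsed"]]
            model <- train_pixel_classifier(stack, ann, specs[[si]],
                                            kind = kind, seed = sd)
            t2 <- proc.time()[["elapsed"]]
            pred <- predict_image(get_plane(stack, 1L), model)
            t3 <- proc.time()[["elapsed"]]
            sc <- compute_miou(pred, gts[[ii]])
            row <- data.frame(image = ii, extractor = names(specs)[si],
                              level = lv, seed = sd, miou = sc$miou,
                              achieved_density = attr(ann, "achieved_density"),
                              t_scribble = t1 - t0, t_train = t2 - t1,
                              t_predict = t3 - t2, error = "",
                              stringsAsFactors = FALSE)
            for (k in seq_len(maxK))
              row[[paste0("iou_", k)]] <-
                if (as.character(k) %in% names(sc$per_class))
                  sc$per_class[[as.character(k)]] else NA_real_
            row
          }, error = function(e) {
            row <- data.frame(image = ii, extractor = names(specs)[si],
                              level = lv, seed = sd, miou = NA_real_,
                              achieved_density = NA_real_, t_scribble = NA_real_,
                              t_train = NA_real_, t_predict = NA_real_,
                              error = conditionMessage(e),
                              stringsAsFactors = FALSE)
            for (k in seq_len(maxK)) row[[paste0("iou_", k)]] <- NA_real_
            row
          })
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
  }
  do.call(rbind, recs)
}
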