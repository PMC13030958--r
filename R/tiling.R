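# Exact tiled prediction: core rectangles partition the plane; each padded
# rectangle extends its core by the context margin (clipped at image bounds,
# where boundary reflection matches full-image extraction), so tiled output is
# bit-identical to untiled prediction for local extractors.

#' Plan a tiling of a plane
#'
#' Deterministic row-major plan. Core rectangles partition the plane exactly
#' (last row/column tiles may be smaller); every padded rectangle extends its
#' core by `margin`, clipped to the image bounds.
#'
#' @param shape `(height, width)`.
#' @param tile_size core tile side in pixels (> 0).
#' @param margin context padding in pixels (>= 0).
#' @return a `tile_plan` with a list of `(core, padded)` rectangles, each
#'   rectangle `c(y0, y1, x0, x1)` (1-based, inclusive).
#' @export
plan_tiles <- function(shape, tile_size = 512L, margin = 0L) {
  stopifnot(length(shape) == 2, tile_size > 0, margin >= 0)
  if (tile_size < 2 * margin)
    warning("tile_size < 2*margin: padding dominates tile computation")
  H <- shape[1]; W <- shape[2]
  tiles <- list()
  for (y0 in seq(1L, H, by = tile_size))
    for (x0 in seq(1L, W, by = tile_size)) {
      y1 <- min(H, y0 + tile_size - 1L)
      x1 <- min(W, x0 + tile_size - 1L)
      core <- c(y0, y1, x0, x1)
      padded <- c(max(1L, y0 - margin), min(H, y1 + margin),
                  max(1L, x0 - margin), min(W, x1 + margin))
      tiles[[length(tiles) + 1L]] <- list(core = as.integer(core),
                                          padded = as.integer(padded))
    }
  structure(list(tiles = tiles, tile_size = as.integer(tile_size),
                 margin = as.integer(margin), shape = as.integer(shape)),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %d tiles of %d px (margin %d) over %s\n",
              length(x$tiles), x$tile_size, x$margin,
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Tiled prediction of one plane
#'
#' Features are computed per padded tile; predictions are cropped to the core
#' rectangles and stitched. With `margin >= context_margin(model$extractor)`
#' the result is bit-identical to [predict_image()]; worker count never
#' affects results (tiles are independent and the merge is order-independent).
#' Whole-image-context extractors are refused unless
#' `allow_global_context = TRUE` is set explicitly (the tiled result is then
#' approximate by construction).
#'
#' @param plane image plane.
#' @param model a `trained_model`.
#' @param tile_size core tile side (default 512).
#' @param margin context padding; default the model extractor's
#'   [context_margin()].
#' @param workers parallel workers (forked; 1 = sequential).
#' @param allow_global_context override the whole-image-context refusal.
#' @param plan an explicit [plan_tiles()] result (overrides
#'   `tile_size`/`margin`).
#' @export
predict_tiled <- function(plane, model, tile_size = 512L, margin = NULL,
                          workers = 1L, allow_global_context = FALSE,
                          plan = NULL) {
  plane <- as_plane(plane)
  check_channels(model, dim(plane)[3])
  if (isTRUE(model$extractor$whole_image_context) && !allow_global_context)
    stop("extractor '", model$extractor$kind, "' requires whole-image context; ",
         "tiling is disabled by default (set allow_global_context = TRUE ",
         "to override)")
  if (is.null(plan)) {
    if (is.null(margin)) {
      margin <- context_margin(model$extractor)
      if (is.na(margin)) margin <- 0L
    }
    plan <- plan_tiles(dim(plane)[1:2], tile_size, margin)
  }
  run_tile <- function(tl) {
    p <- tl$padded; co <- tl$core
    crop <- plane[p[1]:p[2], p[3]:p[4], , drop = FALSE]
    lab <- predict_image(crop, model)
    lab[(co[1] - p[1] + 1L):(co[2] - p[1] + 1L),
        (co[3] - p[3] + 1L):(co[4] - p[3] + 1L), drop = FALSE]
  }
  pieces <- if (workers > 1L)
    parallel::mclapply(plan$tiles, run_tile, mc.cores = workers)
  else lapply(plan$tiles, run_tile)
  out <- matrix(NA_integer_, dim(plane)[1], dim(plane)[2])
  for (i in seq_along(plan$tiles)) {
    co <- plan$tiles[[i]]$core
    out[co[1]:co[2], co[3]:co[4]] <- pieces[[i]]
  }
  out
}
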