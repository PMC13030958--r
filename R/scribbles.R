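# Human-like scribble synthesis from ground-truth masks. Three line types are
# combined: center ridge lines sampled from the primary skeleton, boundary
# parallel lines from the secondary skeleton (mask minus dilated primary),
# and boundary perpendicular lines connecting the primary skeleton to the
# mask boundary. Strokes never cross class boundaries by construction.

#' Scribble-generation configuration
#'
#' @param density target annotated fraction of all image pixels (0 < d < 1).
#'   The benchmark levels are 0.0025, 0.01 and 0.025 (0.25%, 1.0%, 2.5%).
#' @param width stroke width in pixels (>= 1).
#' @param length_range `(min, max)` stroke length in pixels.
#' @param mix sampling proportions over the three line types, in order
#'   (ridge, boundary_parallel, boundary_perpendicular); must sum to 1.
#' @param seed integer seed; the full generation is deterministic given it.
#' @export
scribble_config <- function(density, width = 2L, length_range = c(20L, 80L),
                            mix = c(ridge = 0.5, boundary_parallel = 0.3,
                                    boundary_perpendicular = 0.2),
                            seed = 0L) {
  stopifnot(density > 0, density < 1, width >= 1,
            length(length_range) == 2, length_range[1] <= length_range[2],
            length(mix) == 3, abs(sum(mix) - 1) < 1e-8)
  structure(list(density = density, width = as.integer(width),
                 length_range = as.integer(length_range),
                 mix = as.numeric(mix), seed = as.integer(seed)),
            class = "scribble_config")
}

#' Scribble style presets
#'
#' `"cell"`: many short 1-px-wide strokes (small object datasets);
#' `"natural"`: fewer, longer 2-px strokes (large-region natural images);
#' `"histology"`: medium-length 2-px strokes.
#' @param style preset name.
#' @param density annotated fraction.
#' @param seed seed.
#' @export
scribble_preset <- function(style = c("histology", "cell", "natural"),
                            density = 0.01, seed = 0L) {
  style <- match.arg(style)
  switch(style,
    cell = scribble_config(density, width = 1L, length_range = c(4L, 15L),
                           seed = seed),
    natural = scribble_config(density, width = 2L, length_range = c(40L, 150L),
                              seed = seed),
    histology = scribble_config(density, width = 2L, length_range = c(20L, 80L),
                                seed = seed))
}

# binary dilation with a square structuring element of the given radius
dilate_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (dy in -radius:radius)
    for (dx in -radius:radius) {
      if (dy == 0 && dx == 0) next
      ys <- max(1, 1 + dy):min(H, H + dy)
      xs <- max(1, 1 + dx):min(W, W + dx)
      out[ys, xs] <- out[ys, xs] | mask[ys - dy, xs - dx]
    }
  out
}

#' Primary skeleton of a binary class mask
#'
#' One-pixel-wide medial skeleton via morphological thinning; always a subset
#' of the mask. An empty mask yields an empty skeleton.
#' @param class_mask logical or 0/1 integer matrix.
#' @return 0/1 integer matrix.
#' @export
primary_skeleton <- function(class_mask) {
  m <- matrix(as.integer(class_mask != 0), nrow(class_mask), ncol(class_mask))
  cpp_thin(m)
}

#' Secondary skeleton: skeleton of the mask after removing the primary
#'
#' The primary skeleton is dilated by `width` before subtraction so the two
#' line-type sources never overlap; components of the result lie between the
#' primary skeleton and the mask boundary.
#' @param class_mask binary mask.
#' @param primary its [primary_skeleton()].
#' @param width stroke width used for the dilation (default 1).
#' @export
secondary_skeleton <- function(class_mask, primary = primary_skeleton(class_mask),
                               width = 1L) {
  m <- class_mask != 0
  if (any(primary != 0 & !m)) stop("primary skeleton must lie inside the mask")
  rest <- m & !dilate_mask(primary != 0, max(1L, as.integer(width)))
  cpp_thin(matrix(as.integer(rest), nrow(m), ncol(m)))
}

#' Boundary perpendicular lines
#'
#' Shortest 4-connected pixel paths from sampled primary-skeleton pixels down
#' the distance-to-background field to the mask boundary; each path lies
#' strictly inside the mask, starting on the skeleton and ending adjacent to
#' background.
#' @param class_mask binary mask.
#' @param primary its [primary_skeleton()].
#' @param n number of lines to sample.
#' @return list of n x 2 matrices of 1-based (y, x) pixels.
#' @export
perpendicular_lines <- function(class_mask, primary = primary_skeleton(class_mask),
                                n = 10L) {
  m <- matrix(as.integer(class_mask != 0), nrow(class_mask), ncol(class_mask))
  px <- which(primary != 0)
  if (length(px) == 0) return(list())
  dist <- cpp_dist_to_background(m)
  starts <- px[sample.int(length(px), min(n, length(px)))]
  ij <- arrayInd(starts, dim(m))
  lapply(seq_len(nrow(ij)), function(i)
    cpp_descend_path(dist, ij[i, 1], ij[i, 2]))
}

# trace up to `len` pixels along a skeleton from a start pixel (8-connected,
# no pixel revisited within the stroke); returns n x 2 (y, x)
trace_skeleton <- function(skel, y0, x0, len) {
  H <- nrow(skel); W <- ncol(skel)
  path <- matrix(0L, len, 2)
  path[1, ] <- c(y0, x0)
  seen <- (x0 - 1L) * H + y0
  n <- 1L
  y <- y0; x <- x0
  offs <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  while (n < len) {
    found <- FALSE
    ord <- sample.int(8)     # random continuation direction
    for (k in ord) {
      ny <- y + offs[k, 1]; nx <- x + offs[k, 2]
      if (ny < 1 || ny > H || nx < 1 || nx > W) next
      key <- (nx - 1L) * H + ny
      if (skel[ny, nx] != 0 && !(key %in% seen)) {
        n <- n + 1L
        path[n, ] <- c(ny, nx)
        seen <- c(seen, key)
        y <- ny; x <- nx
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  path[seq_len(n), , drop = FALSE]
}

#' Generate human-like scribble annotations from a ground-truth mask
#'
#' Strokes are sampled per class (annotation budget proportional to class
#' pixel area) from the three line generators according to `cfg$mix`, cut to
#' lengths within `cfg$length_range`, dilated to `cfg$width`, and accumulated
#' until the requested density is reached (the last stroke is trimmed). Every
#' annotated pixel's label equals the ground truth at that pixel. If a class
#' cannot host enough strokes the achieved density falls short with a warning.
#'
#' @param gt integer label matrix, classes >= 1 (0 pixels are never annotated).
#' @param cfg a [scribble_config()].
#' @return an [annotation_mask()] with attribute `achieved_density`.
#' @export
generate_scribbles <- function(gt, cfg) {
  stopifnot(inherits(cfg, "scribble_config"))
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  classes <- sort(unique(gt[gt > 0L]))
  if (length(classes) == 0) stop("ground truth contains no classes")
  H <- nrow(gt); W <- ncol(gt)
  total_px <- H * W
  ann <- matrix(0L, H, W)
  wrad <- cfg$width - 1L   # dilation radius approximating stroke width

  with_seed(cfg$seed, {
    for (cl in classes) {
      m <- gt == cl
      area <- sum(m)
      budget <- round(cfg$density * area)
      if (budget < 1) next
      mi <- matrix(as.integer(m), H, W)
      prim <- cpp_thin(mi)
      sec <- secondary_skeleton(mi, prim, cfg$width)
      dist <- cpp_dist_to_background(mi)
      prim_avail <- which(prim != 0)
      sec_avail <- which(sec != 0)
      perp_avail <- which(prim != 0)
      placed <- 0L
      stalls <- 0L
      while (placed < budget && stalls < 200L) {
        type <- sample.int(3, 1, prob = cfg$mix)
        # fall back when a source is exhausted
        if (type == 1L && length(prim_avail) == 0) type <- 3L
        if (type == 2L && length(sec_avail) == 0) type <- 3L
        if (type == 3L && length(perp_avail) == 0)
          type <- if (length(prim_avail) > 0) 1L else if (length(sec_avail) > 0) 2L
          else break
        lens <- seq(cfg$length_range[1], cfg$length_range[2])
        len <- lens[sample.int(length(lens), 1)]
        if (type == 1L) {
          i <- sample(length(prim_avail), 1)
          start <- prim_avail[i]
          ij <- arrayInd(start, dim(gt))
          path <- trace_skeleton(prim, ij[1], ij[2], len)
        } else if (type == 2L) {
          i <- sample(length(sec_avail), 1)
          start <- sec_avail[i]
          ij <- arrayInd(start, dim(gt))
          path <- trace_skeleton(sec, ij[1], ij[2], len)
        } else {
          i <- sample(length(perp_avail), 1)
          start <- perp_avail[i]
          perp_avail <- perp_avail[-i]
          ij <- arrayInd(start, dim(gt))
          path <- cpp_descend_path(dist, ij[1], ij[2])
          if (nrow(path) > len) path <- path[seq_len(len), , drop = FALSE]
        }
        # stroke pixels: path dilated to width, restricted to the class mask
        stroke <- matrix(FALSE, H, W)
        stroke[path] <- TRUE
        if (wrad > 0L) stroke <- dilate_mask(stroke, wrad)
        stroke <- stroke & m & ann == 0L
        newpx <- which(stroke)
        if (length(newpx) == 0) { stalls <- stalls + 1L; next }
        if (placed + length(newpx) > budget)
          newpx <- newpx[seq_len(budget - placed)]    # trim the last stroke
        ann[newpx] <- cl
        placed <- placed + length(newpx)
        stalls <- 0L
        if (type == 1L) prim_avail <- setdiff(prim_avail, newpx)
        if (type == 2L) sec_avail <- setdiff(sec_avail, newpx)
      }
      if (placed < budget * 0.9)
        warning(sprintf(
          "class %d: achieved only %d of %d requested scribble pixels", cl,
          placed, budget))
    }
  })
  out <- annotation_mask(ann)
  attr(out, "achieved_density") <- sum(ann > 0L) / total_px
  out
}
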