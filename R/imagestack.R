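#' n-dimensional intensity image with declared axis roles
#'
#' An `image_stack` wraps a numeric array together with an ordered vector of
#' axis roles drawn from `plane`, `channel`, `y`, `x`. Exactly one `y` and one
#' `x` axis are required; at most one `channel` and at most one `plane` axis
#' (planes cover z slices *or* time points). Internally the data are stored in
#' canonical `(y, x, channel, plane)` order; the constructor permutes the
#' input accordingly.
#'
#' @param data numeric array (or matrix for a plain 2D image).
#' @param axes character vector of axis roles, one per array dimension, in the
#'   order of `dim(data)`. Defaults to `c("y", "x")` for matrices.
#' @param pixel_kind `"integer"` or `"float"`; inferred from storage mode when
#'   missing.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, axes = NULL, pixel_kind = NULL) {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  if (!is.array(data) || !is.numeric(data))
    stop("`data` must be a numeric array")
  nd <- length(dim(data))
  if (is.null(axes)) {
    if (nd == 2) axes <- c("y", "x")
    else stop("`axes` must be given for arrays with more than 2 dimensions")
  }
  axes <- match.arg(axes, c("plane", "channel", "y", "x"), several.ok = TRUE)
  if (length(axes) != nd)
    stop("length(axes) must equal the number of array dimensions")
  if (anyDuplicated(axes)) stop("axis roles must be unique")
  if (!all(c("y", "x") %in% axes))
    stop("exactly one `y` and one `x` axis are required")
  if (any(dim(data) < 1)) stop("all axis extents must be >= 1")

  # canonical storage order (y, x, channel, plane); absent roles as singletons
  canon <- c("y", "x", "channel", "plane")
  full <- array(as.double(data), dim = c(dim(data), rep(1L, 4 - nd)))
  pos <- match(canon, axes)                       # NA for absent roles
  spare <- setdiff(seq_len(4), pos[!is.na(pos)])  # singleton dim slots
  pos[is.na(pos)] <- spare
  full <- aperm(full, pos)

  if (is.null(pixel_kind))
    pixel_kind <- if (is.integer(data)) "integer" else "float"
  structure(list(data = full, axes = axes, pixel_kind = pixel_kind),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s  axes: %s  kind: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$axes, collapse = ","), x$pixel_kind))
  invisible(x)
}

n_planes <- function(stack) dim(stack$data)[4]
n_channels <- function(stack) dim(stack$data)[3]
spatial_shape <- function(stack) dim(stack$data)[1:2]

#' Extract one plane of an image stack as a (y, x, channel) array
#' @param stack an [image_stack()].
#' @param p 1-based plane index.
#' @return 3D array `(y, x, channel)`.
#' @export
get_plane <- function(stack, p = 1L) {
  d <- dim(stack$data)
  if (p < 1 || p > d[4]) stop("plane index out of range")
  array(stack$data[, , , p], dim = d[1:3])
}

#' Percentile-rescale normalization configuration
#'
#' @param mode one of `"none"`, `"per_plane"`, `"per_stack"`. `per_plane`
#'   rescales each plane independently; `per_stack` computes one percentile
#'   pair over all planes jointly. Both modes operate per channel.
#' @param low,high percentiles in `[0, 100]`, `low < high`. Default (1, 99).
#' @export
normalization_config <- function(mode = c("none", "per_plane", "per_stack"),
                                 low = 1, high = 99) {
  mode <- match.arg(mode)
  if (!(low >= 0 && low < high && high <= 100))
    stop("percentiles must satisfy 0 <= low < high <= 100")
  structure(list(mode = mode, low = low, high = high),
            class = "normalization_config")
}

# sort-based linear-interpolation percentile (quantile type 7)
percentile_pair <- function(v, low, high) {
  stats::quantile(v, probs = c(low, high) / 100, names = FALSE, type = 7)
}

rescale01 <- function(v, lo, hi) {
  if (hi <= lo) return(rep(0, length(v)))        # constant scope -> zeros
  pmin(pmax((v - lo) / (hi - lo), 0), 1)
}

#' Normalize an image stack by percentile rescaling
#'
#' Maps the `low`/`high` percentiles of each scope to 0/1 and clips to
#' `[0, 1]`. Scope is one plane (`per_plane`) or all planes jointly
#' (`per_stack`); statistics are always computed per channel. A constant scope
#' (low percentile equals high) maps to all zeros, never NaN.
#'
#' @param stack an [image_stack()].
#' @param cfg a [normalization_config()].
#' @return a normalized `image_stack` (`pixel_kind` becomes `"float"`).
#' @export
normalize_stack <- function(stack, cfg) {
  stopifnot(inherits(stack, "image_stack"), inherits(cfg, "normalization_config"))
  if (cfg$mode == "none") return(stack)
  d <- dim(stack$data)
  out <- stack$data
  for (ch in seq_len(d[3])) {
    if (cfg$mode == "per_stack") {
      pq <- percentile_pair(as.vector(stack$data[, , ch, ]), cfg$low, cfg$high)
      out[, , ch, ] <- rescale01(stack$data[, , ch, ], pq[1], pq[2])
    } else {
      for (p in seq_len(d[4])) {
        v <- stack$data[, , ch, p]
        pq <- percentile_pair(as.vector(v), cfg$low, cfg$high)
        out[, , ch, p] <- rescale01(v, pq[1], pq[2])
      }
    }
  }
  res <- stack
  res$data <- out
  res$pixel_kind <- "float"
  res
}
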