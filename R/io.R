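# Image I/O. Supported formats: PNG (8/16-bit, via the png package) for 2D
# intensity images and unsigned-integer label masks; ASCII PGM (P2) for
# integer images in a plain-text format; and a simple text stack format
# (.sst: one JSON header line with dims/axes, then whitespace-separated
# values) for multi-plane / multi-channel data. TIFF and zarr are not
# available in this environment; see the package vignette.

#' Read an image file
#'
#' Dispatches on extension: `.png`, `.pgm`, `.sst`.
#' @param path file path.
#' @param axes axis roles for `.sst` stacks (stored in the header; override
#'   only if you know better).
#' @return an [image_stack()].
#' @export
read_image <- function(path, axes = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 2) image_stack(a)
      else image_stack(a, axes = c("y", "x", "channel"))
    },
    pgm = image_stack(read_pgm(path)),
    sst = read_sst(path, axes),
    stop("unsupported image extension: .", ext))
}

#' Write an image or label matrix
#'
#' @param x matrix, array, or [image_stack()].
#' @param path destination; extension selects the format. For PNG, float data
#'   must lie in `[0, 1]`; integer labels are scaled to 16-bit.
#' @export
write_image <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(x, "image_stack")) {
    if (ext == "sst") return(write_sst(x, path))
    d <- dim(x$data)
    if (d[4] > 1) stop("multi-plane stacks require the .sst format")
    x <- if (d[3] == 1) x$data[, , 1, 1] else array(x$data[, , , 1], d[1:3])
  }
  switch(ext,
    png = {
      if (is.integer(x) || all(x == round(x))) {
        png::writePNG(x / 255, path)          # 8-bit integer labels
      } else png::writePNG(pmin(pmax(x, 0), 1), path)
    },
    pgm = write_pgm(x, path),
    sst = write_sst(image_stack(as_plane(x), axes = c("y", "x", "channel")), path),
    stop("unsupported image extension: .", ext))
  invisible(path)
}

#' Read an unsigned-integer label image
#'
#' @param path `.png` (8-bit grayscale convention written by [write_label()],
#'   class ids up to 255) or `.pgm` file.
#' @return integer matrix.
#' @export
read_label <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    m <- round(a * 255)
    storage.mode(m) <- "integer"
    m
  } else if (ext == "pgm") {
    read_pgm(path)
  } else stop("unsupported label extension: .", ext)
}

#' Write an unsigned-integer label image
#' @param labels integer matrix.
#' @param path `.png` or `.pgm` destination.
#' @export
write_label <- function(labels, path) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(labels) > 255)
      stop("PNG label images support class ids up to 255; use .pgm instead")
    png::writePNG(labels / 255, path)
  }
  else if (ext == "pgm") write_pgm(labels, path)
  else stop("unsupported label extension: .", ext)
  invisible(path)
}

read_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII PGM (P2) is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: expected ", w * h, " values")
  matrix(vals, h, w, byrow = TRUE)
}

write_pgm <- function(x, path) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (any(x < 0)) stop("PGM requires non-negative integers")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(max(x, 1))), con)
  utils::write.table(x, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_sst <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(dims = dim(stack$data), axes = stack$axes,
                               pixel_kind = stack$pixel_kind),
                          auto_unbox = FALSE)
  writeLines(as.character(hdr), con)
  writeLines(paste(format(as.vector(stack$data), digits = 10, trim = TRUE,
                          scientific = TRUE), collapse = " "), con)
  invisible(path)
}

read_sst <- function(path, axes = NULL) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1))
  vals <- scan(con, what = double(), quiet = TRUE)
  data <- array(vals, dim = hdr$dims)
  st <- structure(list(data = data,
                       axes = if (is.null(axes)) hdr$axes else axes,
                       pixel_kind = hdr$pixel_kind),
                  class = "image_stack")
  st
}

#' Infer axis roles from array rank (CLI convention)
#'
#' Priority: 2D -> (y, x); 3D -> (y, x, channel) if the last extent is small
#' (<= 5), else (plane, y, x); 4D -> (plane, y, x, channel) if the last
#' extent is small, else (plane, channel, y, x).
#' @param dims integer extents.
#' @export
infer_axes <- function(dims) {
  n <- length(dims)
  if (n == 2) return(c("y", "x"))
  if (n == 3) {
    if (dims[3] <= 5) return(c("y", "x", "channel"))
    return(c("plane", "y", "x"))
  }
  if (n == 4) {
    if (dims[4] <= 5) return(c("plane", "y", "x", "channel"))
    return(c("plane", "channel", "y", "x"))
  }
  stop("cannot infer axes for rank ", n)
}
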