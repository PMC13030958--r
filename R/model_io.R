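# Model persistence: a .pseg file is a zip archive holding a human-readable
# manifest (manifest.json: format version, extractor spec, normalization,
# classes, seed, provenance) and the classifier blob (classifier.bin,
# R serialization of the fitted trees).

PSEG_FORMAT_VERSION <- 1L

#' Save a trained model to a .pseg archive
#'
#' @param model a `trained_model`.
#' @param path destination path (conventionally `.pseg`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  dir <- tempfile("pseg")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- list(
    format_version = model$format_version,
    extractor = list(kind = model$extractor$kind,
                     params = serializable_params(model$extractor),
                     whole_image_context = model$extractor$whole_image_context,
                     volumetric = model$extractor$volumetric),
    normalization = unclass(model$normalization),
    classes = model$classes,
    n_channels_in = model$n_channels_in,
    classifier_kind = model$classifier$kind,
    seed = model$seed,
    provenance = model$provenance)
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = 10, null = "null")),
             file.path(dir, "manifest.json"))
  # full R objects (incl. backbone closures) travel in the binary blob
  saveRDS(list(classifier = model$classifier, extractor = model$extractor,
               normalization = model$normalization),
          file.path(dir, "classifier.bin"))
  abs <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(getwd(), path)
  zip::zip(abs, c("manifest.json", "classifier.bin"), root = dir)
  invisible(path)
}

#' Load a trained model from a .pseg archive
#'
#' @param path file written by [save_model()].
#' @return a `trained_model` equivalent to the saved one.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  dir <- tempfile("pseg")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  ok <- tryCatch({ zip::unzip(path, exdir = dir); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("not a readable model archive: ", path)
  mpath <- file.path(dir, "manifest.json")
  cpath <- file.path(dir, "classifier.bin")
  if (!file.exists(mpath))
    stop("model format error: missing section manifest.json")
  if (!file.exists(cpath))
    stop("model format error: missing section classifier.bin")
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  if (manifest$format_version != PSEG_FORMAT_VERSION)
    stop(sprintf("unsupported model format_version %s (supported: %d)",
                 manifest$format_version, PSEG_FORMAT_VERSION))
  blob <- readRDS(cpath)
  structure(list(classifier = blob$classifier, extractor = blob$extractor,
                 normalization = blob$normalization,
                 classes = as.integer(manifest$classes),
                 n_channels_in = as.integer(manifest$n_channels_in),
                 seed = as.integer(manifest$seed),
                 format_version = as.integer(manifest$format_version),
                 provenance = manifest$provenance),
            class = "trained_model")
}
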