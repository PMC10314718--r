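#' Construct an image ensemble
#'
#' An `image_ensemble` is an ordered collection of same-shape 2-D grayscale
#' images (numeric matrices) together with pixel-pitch metadata and a
#' provenance record (simulator configuration and seed, or the external
#' path images were loaded from).  It is the common currency of all
#' simulators and statistics in the package.
#'
#' @param images list of numeric matrices, all with identical dimensions.
#' @param pixel_pitch physical size of one pixel (metres per pixel), or
#'   `NA` when the model has no physical scale (for example the CLB model).
#' @param provenance named list describing how the images were produced.
#' @param validate check finiteness of every pixel (costly for large
#'   ensembles; dimension checks are always performed).
#' @return an object of class `image_ensemble`.
#' @seealso [generate_clb_ensemble()], [generate_uss_ensemble()],
#'   [generate_s2v_ensemble()], [load_image_ensemble()]
#' @export
image_ensemble <- function(images, pixel_pitch = NA_real_,
                           provenance = list(), validate = TRUE) {
  if (!is.list(images) || length(images) == 0L) {
    stop("'images' must be a nonempty list of matrices")
  }
  if (!all(vapply(images, is.matrix, logical(1)))) {
    stop("every element of 'images' must be a matrix")
  }
  d <- dim(images[[1L]])
  ok <- vapply(images, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all images must share the same dimensions")
  if (validate) {
    fin <- vapply(images, function(m) all(is.finite(m)), logical(1))
    if (!all(fin)) stop("non-finite pixel values in image(s) ",
                        paste(which(!fin)[1:min(3, sum(!fin))], collapse = ", "))
  }
  structure(list(images = images, pixel_pitch = pixel_pitch,
                 provenance = provenance),
            class = "image_ensemble")
}

#' @export
length.image_ensemble <- function(x) length(x$images)

#' @export
`[.image_ensemble` <- function(x, i) {
  image_ensemble(x$images[i], pixel_pitch = x$pixel_pitch,
                 provenance = c(x$provenance, list(subset = TRUE)),
                 validate = FALSE)
}

#' @export
print.image_ensemble <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<image_ensemble> %d images, %d x %d\n",
              length(x$images), d[1L], d[2L]))
  if (!is.na(x$pixel_pitch)) {
    cat(sprintf("  pixel pitch: %g m\n", x$pixel_pitch))
  }
  if (length(x$provenance)) {
    keys <- names(x$provenance)
    scal <- vapply(x$provenance, function(v)
      if (is.atomic(v) && length(v) == 1L) format(v) else "<...>", "")
    cat("  provenance:", paste(keys, scal, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn image_ensemble display one image of the ensemble with a
#'   gray colour ramp.
#' @param x an `image_ensemble`.
#' @param i index of the image to display.
#' @param ... passed on to [graphics::image()].
#' @export
plot.image_ensemble <- function(x, i = 1L, ...) {
  m <- x$images[[i]]
  graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Write an ensemble to a directory of grayscale images
#'
#' Quantized (integer, 0-255) ensembles are written as 8-bit PNG; raw
#' floating-point ensembles as 32-bit float TIFF.
#'
#' @param e an [image_ensemble()].
#' @param dir output directory (created if missing).
#' @param format `"png8"` for 8-bit PNG (values must lie in 0..255) or
#'   `"tiff32"` for 32-bit float TIFF.
#' @return `dir`, invisibly.
#' @export
write_image_ensemble <- function(e, dir, format = c("png8", "tiff32")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(e$images)) {
    f <- file.path(dir, sprintf("img_%05d.%s", i,
                                if (format == "png8") "png" else "tif"))
    m <- e$images[[i]]
    if (format == "png8") {
      if (min(m) < 0 || max(m) > 255) {
        stop("png8 output requires pixel values in [0, 255]")
      }
      png::writePNG(m / 255, f)
    } else {
      tiff::writeTIFF(m, f, bits.per.sample = 32L)
    }
  }
  invisible(dir)
}

#' Load an image ensemble from a directory
#'
#' Reads all PNG/TIFF files (sorted by name) from a directory, validating
#' that every image shares the same shape.  PNG pixel values are rescaled
#' from the `[0, 1]` convention of [png::readPNG()] back to `0..255`.
#'
#' @param dir directory containing `.png`, `.tif` or `.tiff` files.
#' @param pixel_pitch optional pixel pitch metadata (metres per pixel).
#' @return an [image_ensemble()] with provenance recording `dir`.
#' @export
load_image_ensemble <- function(dir, pixel_pitch = NA_real_) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no PNG/TIFF images found in ", dir)
  imgs <- lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]  # collapse grayscale-as-RGB
      round(m * 255)
    } else {
      m <- tiff::readTIFF(f)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      m
    }
  })
  image_ensemble(imgs, pixel_pitch = pixel_pitch,
                 provenance = list(source = "directory", path = dir))
}
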