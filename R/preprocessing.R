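#' Load a canopy image as an 8-bit grayscale matrix
#'
#' Reads a PNG or TIFF image and returns it as a numeric matrix of
#' integer-valued intensities in 0--255, rows indexing image height and
#' columns indexing width.  RGB input is collapsed to luminance; an alpha
#' channel, if present, is dropped.
#'
#' Chlorophyll-fluorescence cameras emit nearly identical values on all
#' three channels, so the exact luminance weighting has little effect; the
#' classic Rec.601 weights (0.299, 0.587, 0.114) are used and recorded in
#' [canopy_config()].
#'
#' @param path Path to an 8-bit PNG or TIFF file.
#' @return A numeric matrix with values in 0--255 (whole numbers).
#' @seealso [standardize_frame()], [normalize_intensity()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(c(0, 17, 60, 255) / 255, 2, 2), f)
#' img <- load_image(f)
#' range(img)
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG or TIFF required)")
  )
  if (is.list(arr)) arr <- arr[[1L]]
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      arr <- .luma_weights[1L] * arr[, , 1L] +
        .luma_weights[2L] * arr[, , 2L] +
        .luma_weights[3L] * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  if (length(dim(arr)) != 2L) {
    stop("unsupported image layout: expected 2-D grayscale or RGB")
  }
  round(arr * 255)
}

# Rec.601 luminance weights used to collapse RGB input.
.luma_weights <- c(r = 0.299, g = 0.587, b = 0.114)

#' Resize an image to the fixed analysis frame
#'
#' All segmentation and texture computation happens on a fixed frame so
#' that pixel counts and cooccurrence statistics are comparable across a
#' time series.  Intensity images are resampled bilinearly; binary masks
#' must use nearest-neighbour resampling (`mask = TRUE`) so they stay
#' binary.
#'
#' @param img Numeric intensity matrix (see [load_image()]).
#' @param frame Integer vector `c(width, height)` of the target frame.
#'   Defaults to the native capture frame 1388 x 1038.
#' @param mask Logical; if `TRUE`, resample nearest-neighbour and round to
#'   \{0, 1\}.
#' @return A matrix with `frame[2]` rows and `frame[1]` columns.
#' @export
standardize_frame <- function(img, frame = c(1388L, 1038L), mask = FALSE) {
  stopifnot(is.matrix(img), is.numeric(frame), length(frame) == 2L)
  if (any(frame <= 0)) stop("frame dimensions must be positive")
  w <- as.integer(frame[1L]); h <- as.integer(frame[2L])
  if (nrow(img) == h && ncol(img) == w) return(img)
  # EBImage's first dimension corresponds to our rows
  out <- EBImage::resize(img, w = h, h = w,
                         filter = if (mask) "none" else "bilinear")
  out <- as.matrix(out)
  if (mask) {
    out <- (out > 0.5) + 0L
    storage.mode(out) <- "integer"
    out
  } else {
    pmin(pmax(round(out), 0), 255)
  }
}

#' Rescale intensities from 0--255 to the unit interval
#'
#' Division by 255, as required before the K-means stage.  The mapping is
#' monotone, so pixel ordering is preserved.
#'
#' @param img Numeric matrix with values in 0--255.
#' @return The same matrix with values in \[0, 1\].
#' @export
normalize_intensity <- function(img) {
  stopifnot(is.matrix(img))
  img / 255
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask 0/1 integer matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write an intensity image as an 8-bit PNG
#'
#' @param img Numeric matrix with values in 0--255.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}
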