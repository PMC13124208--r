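#' Intensity image container
#'
#' A 2-D numeric matrix of pixel intensities carrying a modality tag and a
#' declared dynamic range. All pipeline stages operate on unit-range `[0, 1]`
#' images internally; 8-bit `[0, 255]` integers appear only at file I/O
#' boundaries.
#'
#' @param pixels numeric matrix of intensities
#' @param modality one of `"MRI"`, `"CT"`, `"PET"`, `"DTI"` (or `NA`)
#' @param range declared `c(min, max)` intensity range
#' @return an object of class `intensity_image` (a matrix with attributes)
#' @export
intensity_image <- function(pixels, modality = NA_character_, range = c(0, 1)) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("intensity_image: non-finite pixel values")
  if (any(pixels < range[1] - 1e-9) || any(pixels > range[2] + 1e-9))
    stop("intensity_image: pixels outside declared range")
  if (!is.na(modality)) modality <- match.arg(modality, MND_MODALITIES)
  structure(pixels, modality = modality, range = as.numeric(range),
            class = c("intensity_image", "matrix", "array"))
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image %dx%d, modality=%s, range=[%g, %g]>\n",
              nrow(x), ncol(x), attr(x, "modality"),
              attr(x, "range")[1], attr(x, "range")[2]))
  invisible(x)
}

img_pixels <- function(img) {
  x <- unclass(img)
  attr(x, "modality") <- NULL
  attr(x, "range") <- NULL
  x
}

img_range <- function(img) attr(img, "range") %||% c(0, 1)
img_modality <- function(img) attr(img, "modality") %||% NA_character_

#' Read a grayscale PNG as an intensity image
#'
#' RGB input is converted to luminance; values are rescaled to `[0, 1]`.
#'
#' @param path PNG file path
#' @param modality optional modality tag
#' @return an [intensity_image()]
#' @export
read_image_png <- function(path, modality = NA_character_) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  intensity_image(a, modality = modality, range = c(0, 1))
}

#' Write an intensity image as an 8-bit grayscale PNG
#'
#' @param img an [intensity_image()] or numeric matrix in `[0, 1]`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_image_png <- function(img, path) {
  x <- clip01(img_pixels(img))
  # quantize explicitly so that a write/read round trip is bit-stable
  x <- floor(x * 255 + 0.5) / 255
  png::writePNG(x, path)
  invisible(path)
}
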