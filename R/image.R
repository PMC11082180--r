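#' Tissue class vocabulary
#'
#' The five tissue classes used throughout the package, in canonical code
#' order: benign and stroma (non-malignant), then Gleason patterns 3, 4 and 5.
#' Label rasters store the integer code (1-5); 0 means unlabeled/background.
#'
#' @return Character vector of the five class names.
#' @export
#' @examples
#' gleason_classes()
gleason_classes <- function() c("benign", "stroma", "GP3", "GP4", "GP5")

# Severity used for deterministic tie-breaking: never prefer a less severe
# class when scores tie (GP5 > GP4 > GP3 > benign > stroma).
severity_rank <- function(classes = gleason_classes()) {
  rank <- c(stroma = 1, benign = 2, GP3 = 3, GP4 = 4, GP5 = 5)
  unname(rank[classes])
}

#' Map class labels to integer codes
#'
#' @param label Character vector of class names from
#'   \code{\link{gleason_classes}}.
#' @return Integer codes (1-5) as used in label rasters.
#' @export
#' @examples
#' class_code(c("GP3", "stroma"))
class_code <- function(label) {
  code <- match(label, gleason_classes())
  if (anyNA(code)) stop("unknown class label: ",
                        paste(label[is.na(code)], collapse = ", "), call. = FALSE)
  code
}

#' Labeled RGB image container
#'
#' Bundles an 8-bit RGB raster with an optional per-pixel class-label raster.
#' Pixels are addressed as \code{[row, column]}; intensities are numeric in
#' \code{[0, 255]}; label codes follow \code{\link{gleason_classes}} with 0
#' for unlabeled background.
#'
#' @param rgb Numeric array \code{h x w x 3} with values in \code{[0, 255]}.
#' @param labels Optional integer matrix \code{h x w} of class codes 0-5.
#' @return An object of class \code{labeled_image}.
#' @export
labeled_image <- function(rgb, labels = NULL) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("'rgb' must be an h x w x 3 array", call. = FALSE)
  if (min(rgb) < -1e-9 || max(rgb) > 255 + 1e-9)
    stop("'rgb' intensities must lie in [0, 255]", call. = FALSE)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (is.null(labels)) labels <- matrix(0L, h, w)
  labels <- matrix(as.integer(labels), h, w)
  if (!all(dim(labels) == c(h, w)))
    stop("'labels' must match the image extent", call. = FALSE)
  if (any(labels < 0L) || any(labels > 5L))
    stop("label codes must be 0 (unlabeled) or 1-5", call. = FALSE)
  structure(list(rgb = rgb, labels = labels), class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$rgb)
  lab <- table(factor(x$labels, levels = 0:5,
                      labels = c("unlabeled", gleason_classes())))
  cat(sprintf("<labeled_image> %d x %d px, mean RGB (%.1f, %.1f, %.1f)\n",
              d[1], d[2], mean(x$rgb[, , 1]), mean(x$rgb[, , 2]),
              mean(x$rgb[, , 3])))
  lab <- lab[lab > 0]
  cat("  labels:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.labeled_image <- function(x) dim(x$rgb)[1:2]

crop_image <- function(img, r0, c0, side) {
  rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
  labeled_image(img$rgb[rows, cols, , drop = FALSE],
                img$labels[rows, cols, drop = FALSE])
}

#' Read and write images and label rasters as PNG
#'
#' RGB images round-trip at 8-bit depth. Label rasters are written as a
#' single-channel PNG whose gray value equals the class code (0-5 out of 255),
#' the convention documented in \code{\link{gleason_classes}}.
#'
#' @param img A \code{\link{labeled_image}}.
#' @param path File path.
#' @name image_io
#' @return \code{read_image_png} returns a \code{labeled_image} (labels all 0);
#'   writers return \code{path} invisibly.
NULL

#' @rdname image_io
#' @export
write_image_png <- function(img, path) {
  png::writePNG(round(img$rgb) / 255, target = path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  labeled_image(x[, , 1:3, drop = FALSE] * 255)
}

#' @rdname image_io
#' @param labels Integer matrix of class codes.
#' @export
write_label_png <- function(labels, path) {
  png::writePNG(matrix(as.integer(labels), nrow(labels), ncol(labels)) / 255,
                target = path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write an RGB image as TIFF
#'
#' Convenience wrapper for pipelines whose scanners emit TIFF tiles; requires
#' the optional \pkg{tiff} package.
#' @inheritParams image_io
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output", call. = FALSE)
  tiff::writeTIFF(round(img$rgb) / 255, where = path)
  invisible(path)
}
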