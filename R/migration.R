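#' Scanner appearance migration
#'
#' Images of the same slide scanned on different instruments differ markedly
#' in color and brightness, which degrades a classifier trained on one
#' scanner. Appearance migration maps each image's per-channel intensity
#' distribution onto a fixed reference distribution (per-channel PDF/CDF
#' matching over tissue pixels), pulling all scanners into one unified color
#' space while leaving spatial structure and labels untouched.
#'
#' @name appearance_migration
NULL

#' Tissue mask parameters
#'
#' Background pixels on an H&E slide are bright and unsaturated; everything
#' else is tissue. Small isolated foreground specks are removed and holes
#' (e.g. gland lumens) are filled.
#'
#' @param background_value_min Minimum brightness (value channel, 0-255) for
#'   a pixel to qualify as background, expressed at a white point of 255.
#'   The threshold is rescaled by each image's own white point (99th
#'   percentile of brightness), so the mask is robust to scanner gain,
#'   offset and gamma shifts.
#' @param background_saturation_max Maximum HSV saturation for background.
#' @param min_object_area Foreground components smaller than this are dropped.
#' @return A \code{tissue_mask_params} object.
#' @export
tissue_mask_params <- function(background_value_min = 232,
                               background_saturation_max = 0.08,
                               min_object_area = 64L) {
  stopifnot(background_value_min >= 0, background_value_min <= 255,
            background_saturation_max >= 0, background_saturation_max <= 1,
            min_object_area >= 0)
  structure(list(background_value_min = background_value_min,
                 background_saturation_max = background_saturation_max,
                 min_object_area = as.integer(min_object_area)),
            class = "tissue_mask_params")
}

#' Compute a binary tissue mask
#'
#' @param img A \code{\link{labeled_image}}.
#' @param params A \code{\link{tissue_mask_params}}.
#' @return Logical matrix, \code{TRUE} on tissue.
#' @export
tissue_mask <- function(img, params = tissue_mask_params()) {
  stopifnot(inherits(img, "labeled_image"))
  r <- img$rgb[, , 1]; g <- img$rgb[, , 2]; b <- img$rgb[, , 3]
  v <- pmax(r, g, b)
  s <- ifelse(v > 0, (v - pmin(r, g, b)) / v, 0)
  white <- stats::quantile(v, 0.99, names = FALSE)
  # the rescaled threshold never drops below 180: a uniformly mid-gray image
  # is dim tissue-like content, not slide background
  thr_v <- max(params$background_value_min * white / 255, 180)
  mask <- !(v >= thr_v & s <= params$background_saturation_max)
  if (!any(mask)) return(mask)
  comp <- EBImage::bwlabel(mask)
  areas <- tabulate(comp[comp > 0L])
  drop <- which(areas < params$min_object_area)
  if (length(drop)) mask[matrix(comp %in% drop, nrow(mask))] <- FALSE
  if (any(mask)) mask <- EBImage::fillHull(mask) > 0
  mask
}

channel_hist <- function(channel, mask) {
  v <- as.integer(round(channel[mask]))
  tabulate(pmin(pmax(v, 0L), 255L) + 1L, nbins = 256L)
}

#' Estimate a per-channel reference PDF from a set of images
#'
#' The reference is the per-channel average of each image's normalized
#' 256-bin intensity histogram over its tissue pixels (per-image averaging,
#' not pooled pixels, so images with unequal tissue areas contribute
#' equally).
#'
#' @param images List of \code{\link{labeled_image}}s.
#' @param masks Optional list of logical tissue masks (default: computed with
#'   \code{\link{tissue_mask}}).
#' @param ids Optional character provenance ids.
#' @return A \code{reference_pdf}: list of three 256-bin probability vectors
#'   (\code{r}, \code{g}, \code{b}, bin index = intensity value) plus
#'   provenance.
#' @export
estimate_reference_pdf <- function(images, masks = NULL, ids = NULL) {
  stopifnot(length(images) >= 1L)
  if (is.null(masks)) masks <- lapply(images, tissue_mask)
  nonempty <- vapply(masks, any, TRUE)
  if (!any(nonempty)) stop("all tissue masks are empty", call. = FALSE)
  images <- images[nonempty]; masks <- masks[nonempty]
  acc <- matrix(0, 256L, 3L)
  for (i in seq_along(images)) {
    for (ch in 1:3) {
      hst <- channel_hist(images[[i]]$rgb[, , ch], masks[[i]])
      acc[, ch] <- acc[, ch] + hst / sum(hst)
    }
  }
  acc <- acc / length(images)
  structure(list(r = acc[, 1], g = acc[, 2], b = acc[, 3],
                 provenance = ids %||% paste0("image_", seq_along(images))),
            class = "reference_pdf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reference_pdf <- function(x, ...) {
  cat(sprintf("<reference_pdf> 256 bins/channel, %d source images\n",
              length(x$provenance)))
  invisible(x)
}

#' Read and write reference PDFs as JSON
#' @param ref A \code{reference_pdf}.
#' @param path File path.
#' @name reference_pdf_io
NULL

#' @rdname reference_pdf_io
#' @export
write_reference_pdf <- function(ref, path) {
  stopifnot(inherits(ref, "reference_pdf"))
  jsonlite::write_json(unclass(ref), path, digits = NA)
  invisible(path)
}

#' @rdname reference_pdf_io
#' @export
read_reference_pdf <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(r = x$r, g = x$g, b = x$b, provenance = x$provenance),
            class = "reference_pdf")
}

# Monotone per-channel intensity map T = invCDF_ref o CDF_source, linear
# interpolation on the inverse, ties broken toward the lowest intensity.
# Both CDFs are continuity-corrected at bin midpoints (F(v-1) + p(v)/2) so a
# concentrated source bin lands in the middle of its reference quantile
# range instead of its upper edge.
match_lut <- function(src_pdf, ref_pdf) {
  src_cdf <- cumsum(src_pdf) - src_pdf / 2
  ref_cdf <- cumsum(ref_pdf) - ref_pdf / 2
  if (sum(src_pdf > 0) <= 1L) {
    # degenerate constant channel: map everything to the reference median
    med <- which(ref_cdf >= 0.5)[1] - 1L
    return(rep(med, 256L))
  }
  # invert the reference CDF: for quantile q, lowest intensity j with
  # ref_cdf[j+1] >= q, interpolated linearly between distinct CDF values
  keep <- !duplicated(ref_cdf)             # lowest intensity per CDF value
  xs <- ref_cdf[keep]; ys <- (0:255)[keep]
  stats::approx(x = xs, y = ys, xout = src_cdf, rule = 2, ties = "ordered")$y
}

#' Migrate an image to a reference color distribution
#'
#' Per channel, builds the monotone non-decreasing map
#' \code{T = invCDF_ref(CDF_source(v))} from the tissue-pixel CDF and applies
#' it to \emph{all} pixels (background included, to avoid seams). Output is
#' clipped and rounded to 8-bit. A constant source channel maps to the
#' reference median with a warning.
#'
#' @param img A \code{\link{labeled_image}}.
#' @param ref A \code{reference_pdf}.
#' @param mask Optional tissue mask (default computed).
#' @return A \code{\link{labeled_image}} (labels unchanged).
#' @export
migrate_image <- function(img, ref, mask = NULL) {
  stopifnot(inherits(img, "labeled_image"), inherits(ref, "reference_pdf"))
  if (is.null(mask)) mask <- tissue_mask(img)
  if (!any(mask)) stop("empty tissue mask", call. = FALSE)
  refs <- list(ref$r, ref$g, ref$b)
  rgb <- img$rgb
  for (ch in 1:3) {
    hst <- channel_hist(rgb[, , ch], mask)
    if (sum(hst > 0) <= 1L)
      warning("constant channel ", ch, "; mapping to reference median")
    lut <- match_lut(hst / sum(hst), refs[[ch]])
    v <- as.integer(round(rgb[, , ch]))
    rgb[, , ch] <- matrix(lut[pmin(pmax(v, 0L), 255L) + 1L], nrow(mask))
  }
  labeled_image(clip255(round(rgb)), img$labels)
}

#' Histogram intersection between two PDFs
#'
#' \code{sum(pmin(a, b))} per channel: 1 for identical distributions, 0 for
#' disjoint supports. Symmetric.
#'
#' @param pdf_a,pdf_b \code{reference_pdf} objects (or plain lists with
#'   \code{r}, \code{g}, \code{b} probability vectors).
#' @return List with per-channel intersections and their \code{mean}.
#' @export
histogram_intersection <- function(pdf_a, pdf_b) {
  per <- vapply(c("r", "g", "b"),
                function(ch) sum(pmin(pdf_a[[ch]], pdf_b[[ch]])), 0)
  list(r = per[["r"]], g = per[["g"]], b = per[["b"]], mean = mean(per))
}

#' Per-image tissue-mean RGB summary and cluster compactness
#'
#' The appearance of a scanner cohort is summarized by each image's mean RGB
#' over tissue; compactness is the mean pairwise Euclidean distance between
#' the image points (0 when all images share one appearance). Migration
#' should shrink compactness across scanner styles.
#'
#' @inheritParams estimate_reference_pdf
#' @return List with \code{means} (data.frame image, r, g, b) and
#'   \code{compactness}.
#' @export
channel_mean_summary <- function(images, masks = NULL) {
  stopifnot(length(images) >= 2L)
  if (is.null(masks)) masks <- lapply(images, tissue_mask)
  means <- t(vapply(seq_along(images), function(i) {
    m <- masks[[i]]
    vapply(1:3, function(ch) mean(images[[i]]$rgb[, , ch][m]), 0)
  }, numeric(3)))
  colnames(means) <- c("r", "g", "b")
  d <- stats::dist(means)
  list(means = data.frame(image = seq_along(images), means),
       compactness = if (length(d)) mean(d) else 0)
}
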