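#' Patch scale configuration
#'
#' Sliding-window geometry for patch extraction and slide inference. A
#' window of side \code{x} pixels moves with a stride of \code{(x-1)/2}
#' pixels, so adjacent windows overlap by \code{(x+1)/(2x)} of their width.
#' Extracted windows are resized to \code{target_side} (default 224) pixels,
#' giving an effective sampling resolution of
#' \code{side_x * scan_resolution / target_side} micrometres per pixel.
#'
#' @param side_x Window side in pixels; must be odd so the stride is an
#'   integer. The study scales are 251, 501, 1001 and 2001, but any odd side
#'   >= 33 is accepted.
#' @param scan_resolution Scan resolution in micrometres per pixel
#'   (default 0.5).
#' @param target_side Classifier input side in pixels (default 224).
#' @param coverage_min Minimum single-class annotated coverage for a window
#'   to yield a training patch (default 0.70).
#' @return A \code{patch_scale} object with derived \code{stride} and
#'   \code{overlap_ratio}.
#' @export
#' @examples
#' s <- patch_scale(501)
#' s$stride          # 250
#' s$overlap_ratio   # (501 + 1) / (2 * 501)
patch_scale <- function(side_x, scan_resolution = 0.5, target_side = 224L,
                        coverage_min = 0.70) {
  side_x <- as.integer(side_x)
  if (side_x < 33L || side_x %% 2L == 0L)
    stop("'side_x' must be an odd integer >= 33", call. = FALSE)
  stopifnot(scan_resolution > 0, target_side > 0,
            coverage_min > 0, coverage_min < 1)
  structure(list(side_x = side_x,
                 stride = (side_x - 1L) %/% 2L,
                 overlap_ratio = (side_x + 1) / (2 * side_x),
                 coverage_min = coverage_min,
                 target_side = as.integer(target_side),
                 scan_resolution = scan_resolution),
            class = "patch_scale")
}

#' Effective sampling resolution after resizing
#'
#' A window of \code{side_x} source pixels scanned at
#' \code{scan_resolution} micrometres per pixel and resized to
#' \code{target_side} pixels samples the tissue at
#' \code{side_x * scan_resolution / target_side} micrometres per pixel,
#' reported rounded to two decimals.
#'
#' @inheritParams patch_scale
#' @return Resolution in micrometres per pixel, rounded to 2 decimals.
#' @export
#' @examples
#' effective_resolution(501)   # 1.12
#' effective_resolution(2001)  # 4.47
effective_resolution <- function(side_x, scan_resolution = 0.5,
                                 target_side = 224L) {
  stopifnot(side_x > 0, scan_resolution > 0, target_side > 0)
  round(side_x * scan_resolution / target_side, 2)
}

# 1-D window starts (0-based, half-open [s, s + side)).
window_starts <- function(extent, side, stride) {
  if (extent < side) return(integer())
  as.integer(seq.int(0L, extent - side, by = stride))
}

#' Enumerate sliding windows over a rectangular extent
#'
#' Windows start at 0, step by the scale's stride, and lie fully inside the
#' extent (0-based, half-open pixel coordinates).
#'
#' @param extent Integer extent \code{c(height, width)} (a single value is
#'   recycled to a square).
#' @param scale A \code{\link{patch_scale}}.
#' @return data.frame with 0-based \code{r0}, \code{c0} and \code{side};
#'   empty (with a warning) when the extent is smaller than one window.
#' @export
enumerate_windows <- function(extent, scale) {
  stopifnot(inherits(scale, "patch_scale"))
  if (length(extent) == 1L) extent <- c(extent, extent)
  rs <- window_starts(extent[1], scale$side_x, scale$stride)
  cs <- window_starts(extent[2], scale$side_x, scale$stride)
  if (!length(rs) || !length(cs)) {
    warning("extent smaller than one window")
    return(data.frame(r0 = integer(), c0 = integer(), side = integer()))
  }
  g <- expand.grid(r0 = rs, c0 = cs)
  data.frame(r0 = g$r0, c0 = g$c0, side = scale$side_x)
}

#' Extract labeled training patches from annotations
#'
#' Rasterizes the annotation polygons, slides windows per the scale, and
#' keeps a window iff a single class covers more than
#' \code{scale$coverage_min} of its area (windows whose classes are mixed
#' below that bar yield no patch). Kept windows are resized to
#' \code{target_side} by exact area averaging. Deterministic and independent
#' of annotation ordering.
#'
#' @param img A \code{\link{labeled_image}}.
#' @param ann An \code{annotation_set} (or an integer class raster).
#' @param scale A \code{\link{patch_scale}}.
#' @return List of \code{labeled_patch} objects: \code{pixels}
#'   (target_side^2 RGB), \code{label}, \code{window} (0-based r0, c0, side),
#'   \code{coverage}.
#' @export
extract_patches <- function(img, ann, scale) {
  stopifnot(inherits(img, "labeled_image"), inherits(scale, "patch_scale"))
  h <- nrow(img$labels); w <- ncol(img$labels)
  raster <- if (inherits(ann, "annotation_set"))
    rasterize_annotations(ann, h, w) else matrix(as.integer(ann), h, w)
  wins <- enumerate_windows(c(h, w), scale)
  out <- list()
  for (k in seq_len(nrow(wins))) {
    rows <- (wins$r0[k] + 1L):(wins$r0[k] + scale$side_x)
    cols <- (wins$c0[k] + 1L):(wins$c0[k] + scale$side_x)
    sub <- raster[rows, cols]
    cov <- tabulate(sub[sub > 0L], nbins = 5L) / length(sub)
    best <- which.max(cov)
    if (cov[best] <= scale$coverage_min) next
    pix <- resize_area_rgb(img$rgb[rows, cols, , drop = FALSE],
                           scale$target_side, scale$target_side)
    out[[length(out) + 1L]] <- structure(
      list(pixels = pix, label = gleason_classes()[best],
           window = c(r0 = wins$r0[k], c0 = wins$c0[k], side = scale$side_x),
           coverage = cov[best]),
      class = "labeled_patch")
  }
  out
}

#' Augmentation configuration
#'
#' Geometric augmentation produces the exact 90-degree rotations and flips
#' (no interpolation); color augmentation jitters per-channel gain, offset
#' and gamma within bounded ranges. The scanner presets shift the jitter
#' ranges dark ("scannerB", "scannerC") or light ("scannerD") to mimic the
#' appearance of those instruments; "none" applies unshifted jitter; "identity"
#' is a no-op.
#'
#' @param preset One of \code{"identity"}, \code{"none"}, \code{"scannerB"},
#'   \code{"scannerC"}, \code{"scannerD"}.
#' @param geometric Include the 8 dihedral orientations (4 rotations x flip).
#' @param n_color Number of color-jittered variants per orientation.
#' @param seed Integer seed for the jitter draws.
#' @return An \code{augmentation_config} object carrying the jitter ranges.
#' @export
augmentation_config <- function(preset = c("identity", "none", "scannerB",
                                           "scannerC", "scannerD"),
                                geometric = TRUE, n_color = 1L, seed = 1L) {
  preset <- match.arg(preset)
  ranges <- switch(preset,
    identity = NULL,
    none     = list(gain = c(0.9, 1.1), offset = c(-20, 20),
                    gamma = c(0.9, 1.1)),
    scannerB = list(gain = c(0.88, 1.00), offset = c(-20, 0),
                    gamma = c(1.00, 1.10)),
    scannerC = list(gain = c(0.84, 0.96), offset = c(-25, -5),
                    gamma = c(1.00, 1.15)),
    scannerD = list(gain = c(1.00, 1.12), offset = c(0, 20),
                    gamma = c(0.85, 1.00)))
  structure(list(preset = preset, geometric = isTRUE(geometric),
                 n_color = as.integer(n_color), ranges = ranges,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

rot90 <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

orient_rgb <- function(rgb, k, flip) {
  out <- array(0, c(if (k %% 2L) rev(dim(rgb)[1:2]) else dim(rgb)[1:2], 3L))
  for (ch in 1:3) {
    m <- rot90(rgb[, , ch], k)
    if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    out[, , ch] <- m
  }
  out
}

#' Augment a labeled patch
#'
#' @param patch A \code{labeled_patch} (from \code{\link{extract_patches}}).
#' @param cfg An \code{\link{augmentation_config}}.
#' @return List of augmented \code{labeled_patch}es (labels preserved). The
#'   identity preset returns the input patch unchanged.
#' @export
augment_patch <- function(patch, cfg) {
  stopifnot(inherits(patch, "labeled_patch"),
            inherits(cfg, "augmentation_config"))
  if (cfg$preset == "identity" && !isTRUE(cfg$geometric)) return(list(patch))
  if (cfg$preset == "identity") {
    orients <- expand.grid(k = 0:3, flip = c(FALSE, TRUE))
    return(lapply(seq_len(nrow(orients)), function(i) {
      p <- patch
      p$pixels <- orient_rgb(patch$pixels, orients$k[i], orients$flip[i])
      p
    }))
  }
  orients <- if (cfg$geometric) expand.grid(k = 0:3, flip = c(FALSE, TRUE))
             else data.frame(k = 0L, flip = FALSE)
  with_seed(cfg$seed, {
    out <- list()
    for (i in seq_len(nrow(orients))) {
      base <- orient_rgb(patch$pixels, orients$k[i], orients$flip[i])
      for (j in seq_len(cfg$n_color)) {
        style <- scanner_style(
          gain = stats::runif(3, cfg$ranges$gain[1], cfg$ranges$gain[2]),
          offset = stats::runif(3, cfg$ranges$offset[1], cfg$ranges$offset[2]),
          gamma = stats::runif(3, cfg$ranges$gamma[1], cfg$ranges$gamma[2]),
          name = cfg$preset)
        p <- patch
        p$pixels <- apply_scanner_style(labeled_image(base), style)$rgb
        out[[length(out) + 1L]] <- p
      }
    }
    out
  })
}

#' Inverse-frequency class weights
#'
#' Weights are inversely proportional to the per-class patch counts,
#' normalized so the mean weight over present classes is 1:
#' \code{w_i = (1/n_i) * K / sum_j(1/n_j)}. Classes with zero count are
#' excluded with a warning.
#'
#' @param counts Named non-negative counts (at least one positive).
#' @return Named numeric weights over the present classes.
#' @export
#' @examples
#' compute_class_weights(c(GP3 = 200, GP4 = 100))  # 2/3, 4/3
compute_class_weights <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!any(counts > 0)) stop("all class counts are zero", call. = FALSE)
  if (any(counts == 0)) {
    warning("classes with zero count excluded: ",
            paste(names(counts)[counts == 0], collapse = ", "))
    counts <- counts[counts > 0]
  }
  inv <- 1 / counts
  w <- inv * length(counts) / sum(inv)
  w
}
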