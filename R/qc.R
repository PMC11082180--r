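#' Tile-based whole-slide image quality control
#'
#' Automated assessment of the five common slide-quality issue categories:
#' out of focus, low contrast, saturation (clipped highlights/shadows),
#' artifacts (pen, dust, folds), and texture uniformity (too-flat texture
#' indicating a scan fault). A tile is "low quality" when at least
#' \code{issue_count_for_low_quality} (default 2) issues are flagged; a slide
#' summary reports the low-quality percentage over tissue tiles.
#'
#' @name quality_control
NULL

#' QC thresholds and configuration
#'
#' Scores and their flag conditions:
#' \describe{
#'   \item{focus}{log10 variance of the 3x3 Laplacian of the grayscale tile;
#'     flagged when \emph{below} \code{focus_min} (blur destroys gradient
#'     energy).}
#'   \item{contrast}{(P95 - P5)/255 of low-passed (sigma 2.5) grayscale
#'     tissue pixels, so the score measures intensity-distribution breadth
#'     independently of sharpness; flagged when below \code{contrast_min}.}
#'   \item{saturation}{fraction of clipped pixels (any channel >= 254 or all
#'     channels <= 2) among tissue-plus-clipped pixels; clipped highlights
#'     drop out of the tissue mask because they look like background, so
#'     they are added back into the denominator explicitly. Flagged when
#'     above \code{saturation_max}.}
#'   \item{artifact}{fraction of tissue pixels outside a robust H&E color
#'     envelope (very dark, or saturated with a hue outside the pink-purple
#'     band); flagged when above \code{artifact_max}.}
#'   \item{uniformity}{coefficient of variation of local (32 px block)
#'     grayscale variance; flagged when \emph{below} \code{uniformity_min}
#'     (too-flat texture).}
#' }
#' Defaults were calibrated once on the seeded synthetic fixture suite and
#' shipped here; every threshold is overridable (or loadable from YAML via
#' \code{\link{read_qc_config}}).
#'
#' @param focus_min Minimum focus score.
#' @param contrast_min Minimum contrast score.
#' @param saturation_max Maximum clipped-pixel fraction.
#' @param artifact_max Maximum artifact-pixel fraction.
#' @param uniformity_min Minimum local-variance CV.
#' @param tile_side Tile side in pixels.
#' @param issue_count_for_low_quality Number of flagged issues that makes a
#'   tile low quality (>= 1).
#' @param tissue_min Tiles with tissue fraction at or below this are treated
#'   as background and excluded from the summary.
#' @param hue_lo,hue_hi H&E hue envelope (HSV hue in [0,1], wrapped): hues in
#'   \code{[hue_lo, 1] U [0, hue_hi]} count as plausible H&E colors.
#' @return A \code{qc_thresholds} object.
#' @export
qc_thresholds <- function(focus_min = 0.9,
                          contrast_min = 0.14,
                          saturation_max = 0.05,
                          artifact_max = 0.05,
                          uniformity_min = 0.15,
                          tile_side = 512L,
                          issue_count_for_low_quality = 2L,
                          tissue_min = 0.10,
                          hue_lo = 0.62,
                          hue_hi = 0.10) {
  stopifnot(is.finite(focus_min), is.finite(contrast_min),
            is.finite(saturation_max), is.finite(artifact_max),
            is.finite(uniformity_min), tile_side >= 32,
            issue_count_for_low_quality >= 1)
  structure(list(focus_min = focus_min, contrast_min = contrast_min,
                 saturation_max = saturation_max, artifact_max = artifact_max,
                 uniformity_min = uniformity_min,
                 tile_side = as.integer(tile_side),
                 issue_count_for_low_quality =
                   as.integer(issue_count_for_low_quality),
                 tissue_min = tissue_min, hue_lo = hue_lo, hue_hi = hue_hi),
            class = "qc_thresholds")
}

#' Read QC thresholds from a YAML config
#' @param path YAML file; keys as in \code{\link{qc_thresholds}}.
#' @return A \code{qc_thresholds} object.
#' @export
read_qc_config <- function(path) {
  do.call(qc_thresholds, yaml::read_yaml(path))
}

#' Split an image into non-overlapping tiles
#'
#' @param img A \code{\link{labeled_image}}.
#' @param tile_side Tile side in pixels (>= 32).
#' @param partial \code{"drop"} (default) discards partial edge tiles;
#'   \code{"pad"} replicate-pads them to full size.
#' @return List of tiles, each a list with \code{img} (the crop) and 1-based
#'   origin \code{r0}, \code{c0}.
#' @export
tile_image <- function(img, tile_side = 512L, partial = c("drop", "pad")) {
  stopifnot(inherits(img, "labeled_image"), tile_side >= 32)
  partial <- match.arg(partial)
  h <- nrow(img$labels); w <- ncol(img$labels)
  if (h < tile_side || w < tile_side)
    stop("image smaller than one tile", call. = FALSE)
  starts <- function(n) {
    s <- seq.int(1L, n, by = tile_side)
    if (partial == "drop") s[s + tile_side - 1L <= n] else s
  }
  tiles <- list()
  for (r0 in starts(h)) for (c0 in starts(w)) {
    rows <- r0:min(h, r0 + tile_side - 1L)
    cols <- c0:min(w, c0 + tile_side - 1L)
    rgb <- img$rgb[rows, cols, , drop = FALSE]
    lab <- img$labels[rows, cols, drop = FALSE]
    if (partial == "pad" &&
        (length(rows) < tile_side || length(cols) < tile_side)) {
      ri <- c(seq_along(rows), rep(length(rows), tile_side - length(rows)))
      ci <- c(seq_along(cols), rep(length(cols), tile_side - length(cols)))
      rgb <- rgb[ri, ci, , drop = FALSE]
      lab <- lab[ri, ci, drop = FALSE]
    }
    tiles[[length(tiles) + 1L]] <-
      list(img = labeled_image(rgb, lab), r0 = r0, c0 = c0)
  }
  tiles
}

# Fraction of tissue pixels outside the H&E color envelope.
artifact_fraction <- function(rgb, mask, hue_lo, hue_hi) {
  r <- rgb[, , 1][mask]; g <- rgb[, , 2][mask]; b <- rgb[, , 3][mask]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  bad <- v < 0.18 | (s > 0.15 & !(h >= hue_lo | h <= hue_hi))
  mean(bad)
}

#' Compute the five quality scores and flags for one tile
#'
#' Tiles with tissue fraction at or below \code{thresholds$tissue_min} are
#' marked \code{background = TRUE} with \code{NA} scores (the slide summary
#' skips them). All scores are deterministic and invariant to 90-degree
#' rotations and flips of the tile (for tiles whose side is a multiple of
#' the 32 px uniformity block).
#'
#' @param tile A \code{\link{labeled_image}} tile (or a tile record from
#'   \code{\link{tile_image}}).
#' @param thresholds A \code{\link{qc_thresholds}}.
#' @param mask Optional tissue mask for the tile.
#' @return One-row data.frame: tissue fraction, five scores, five flags,
#'   \code{n_issues}, \code{low_quality}, \code{background}.
#' @export
compute_quality_metrics <- function(tile, thresholds = qc_thresholds(),
                                    mask = NULL) {
  if (!inherits(tile, "labeled_image") && is.list(tile) &&
      inherits(tile$img, "labeled_image")) tile <- tile$img
  stopifnot(inherits(tile, "labeled_image"))
  if (is.null(mask)) mask <- tissue_mask(tile)
  tf <- mean(mask)
  na_rec <- data.frame(tissue_fraction = tf, focus = NA_real_,
                       contrast = NA_real_, saturation = NA_real_,
                       artifact = NA_real_, uniformity = NA_real_,
                       flag_focus = NA, flag_contrast = NA, flag_saturation = NA,
                       flag_artifact = NA, flag_uniformity = NA,
                       n_issues = NA_integer_, low_quality = NA,
                       background = TRUE)
  if (tf <= thresholds$tissue_min) return(na_rec)
  gray <- rgb_to_gray(tile$rgb)

  focus <- log10(stats::var(as.vector(laplacian(gray))) + 1e-8)
  # contrast is measured on a low-passed copy so it reflects the breadth of
  # the intensity distribution, not sharpness (focus covers that)
  glp <- gauss_blur(gray, 2.5)
  q <- stats::quantile(glp[mask], c(0.05, 0.95), names = FALSE)
  contrast <- (q[2] - q[1]) / 255
  r <- tile$rgb[, , 1]; g <- tile$rgb[, , 2]; b <- tile$rgb[, , 3]
  clipped <- (r >= 254 | g >= 254 | b >= 254) | (r <= 2 & g <= 2 & b <= 2)
  saturation <- sum(clipped & (mask | clipped)) / sum(mask | clipped)
  artifact <- artifact_fraction(tile$rgb, mask, thresholds$hue_lo,
                                thresholds$hue_hi)
  bv <- block_variances(gray, 32L)
  uniformity <- if (mean(bv) > 0) stats::sd(bv) / mean(bv) else 0

  rec <- data.frame(tissue_fraction = tf, focus = focus, contrast = contrast,
                    saturation = saturation, artifact = artifact,
                    uniformity = uniformity)
  rec$flag_focus <- focus < thresholds$focus_min
  rec$flag_contrast <- contrast < thresholds$contrast_min
  rec$flag_saturation <- saturation > thresholds$saturation_max
  rec$flag_artifact <- artifact > thresholds$artifact_max
  rec$flag_uniformity <- uniformity < thresholds$uniformity_min
  rec$n_issues <- rec$flag_focus + rec$flag_contrast + rec$flag_saturation +
    rec$flag_artifact + rec$flag_uniformity
  rec$low_quality <- classify_tile_quality(rec, thresholds)
  rec$background <- FALSE
  rec
}

#' Classify a tile as low quality
#'
#' A tile is low quality when at least
#' \code{issue_count_for_low_quality} of its five issue flags are raised.
#'
#' @param record A metrics record from \code{\link{compute_quality_metrics}}.
#' @param thresholds A \code{\link{qc_thresholds}}.
#' @return Logical.
#' @export
classify_tile_quality <- function(record, thresholds = qc_thresholds()) {
  flags <- c(record$flag_focus, record$flag_contrast, record$flag_saturation,
             record$flag_artifact, record$flag_uniformity)
  sum(flags) >= thresholds$issue_count_for_low_quality
}

#' Summarize per-tile QC records at slide level
#'
#' @param records data.frame of per-tile records (rows from
#'   \code{\link{compute_quality_metrics}}).
#' @return List: tile counts, low-quality count and percentage (over
#'   non-background tiles).
#' @export
summarize_slide_quality <- function(records) {
  tissue <- records[!records$background, , drop = FALSE]
  if (!nrow(tissue)) stop("all tiles are background", call. = FALSE)
  n_low <- sum(tissue$low_quality)
  list(n_tiles = nrow(records), n_background = sum(records$background),
       n_tissue = nrow(tissue), n_low_quality = n_low,
       pct_low_quality = 100 * n_low / nrow(tissue))
}

#' Run QC over a whole image
#'
#' Tiles the image, scores every tile, and attaches the slide summary.
#'
#' @param img A \code{\link{labeled_image}}.
#' @param thresholds A \code{\link{qc_thresholds}}.
#' @return A \code{quality_report}: list with \code{tiles} (per-tile
#'   data.frame incl. tile origins) and \code{summary}.
#' @export
qc_image <- function(img, thresholds = qc_thresholds()) {
  tiles <- tile_image(img, thresholds$tile_side)
  recs <- do.call(rbind, lapply(tiles, function(t) {
    cbind(data.frame(r0 = t$r0, c0 = t$c0),
          compute_quality_metrics(t$img, thresholds))
  }))
  structure(list(tiles = recs, summary = summarize_slide_quality(recs),
                 thresholds = thresholds),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<quality_report> %d tiles (%d background); ",
                     "%d low quality (%.1f%% of %d tissue tiles)\n"),
              s$n_tiles, s$n_background, s$n_low_quality, s$pct_low_quality,
              s$n_tissue))
  invisible(x)
}

#' Write a QC report as CSV
#'
#' Stable column set: \code{r0, c0, tissue_fraction}, the five scores, the
#' five flags, \code{n_issues, low_quality, background}.
#'
#' @param report A \code{quality_report}.
#' @param path Output CSV path.
#' @export
write_qc_csv <- function(report, path) {
  utils::write.csv(report$tiles, path, row.names = FALSE)
  invisible(path)
}

#' Write a low-quality heatmap PNG
#'
#' One pixel block per tile: green = clean tissue, red = low quality,
#' gray = background.
#'
#' @param report A \code{quality_report}.
#' @param path Output PNG path.
#' @param block Pixels per tile in the heatmap.
#' @export
qc_heatmap <- function(report, path, block = 8L) {
  t <- report$tiles
  side <- report$thresholds$tile_side
  ri <- (t$r0 - 1L) %/% side + 1L
  ci <- (t$c0 - 1L) %/% side + 1L
  h <- max(ri); w <- max(ci)
  img <- array(0.8, c(h, w, 3))
  for (k in seq_len(nrow(t))) {
    col <- if (isTRUE(t$background[k])) c(0.8, 0.8, 0.8)
           else if (isTRUE(t$low_quality[k])) c(0.85, 0.2, 0.2)
           else c(0.2, 0.7, 0.3)
    img[ri[k], ci[k], ] <- col
  }
  img <- img[rep(seq_len(h), each = block), rep(seq_len(w), each = block), ,
             drop = FALSE]
  png::writePNG(img, target = path)
  invisible(path)
}
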