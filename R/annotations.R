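#' Polygon annotation sets
#'
#' An \code{annotation_set} is a list of labeled polygons in pixel
#' coordinates, mirroring how pathologists annotate regions of interest:
#' non-exhaustively, one class label per polygon. Polygons are stored as
#' two-column \code{(row, col)} matrices of 1-based pixel centers tracing the
#' region boundary; GeoJSON export uses 0-based \code{(x, y) = (col-1, row-1)}.
#'
#' @name annotations
NULL

annotation_set <- function(annotations = list()) {
  structure(list(annotations = annotations), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$annotations, `[[`, "", "label")
  cat(sprintf("<annotation_set> %d polygons\n", length(labs)))
  if (length(labs)) print(table(labs))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$annotations)

#' Extract partial polygon annotations from a label raster
#'
#' Traces connected single-class regions (contour tracing of connected
#' components, minimum region area 100 px to avoid slivers) and keeps a
#' seeded random subset whose total area approximates
#' \code{completeness} times the labeled area, emulating non-exhaustive
#' pathologist annotation.
#'
#' @param labels Integer label raster (codes per \code{\link{gleason_classes}},
#'   0 = unlabeled).
#' @param completeness Target fraction of labeled area to annotate, in (0, 1].
#' @param seed Integer seed for region selection.
#' @param min_region_area Minimum region area in pixels.
#' @return An \code{annotation_set}; empty when the raster has no labels.
#' @export
generate_annotation_set <- function(labels, completeness = 1, seed = 1L,
                                    min_region_area = 100L) {
  if (completeness <= 0 || completeness > 1)
    stop("'completeness' must lie in (0, 1]", call. = FALSE)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!any(labels > 0L)) return(annotation_set())

  regions <- list()
  for (code in sort(unique(labels[labels > 0L]))) {
    cls <- gleason_classes()[code]
    comp <- EBImage::bwlabel(labels == code)
    areas <- tabulate(comp[comp > 0])
    contours <- EBImage::ocontour(comp)
    for (i in seq_along(areas)) {
      if (areas[i] < min_region_area) next
      oc <- contours[[i]]  # 0-based (dim1, dim2) = (row-1, col-1)
      poly <- cbind(row = oc[, 1] + 1L, col = oc[, 2] + 1L)
      regions[[length(regions) + 1L]] <-
        list(label = cls, polygon = poly, area = areas[i])
    }
  }
  if (!length(regions)) return(annotation_set())

  total <- sum(labels > 0L)
  target <- completeness * total
  keep <- with_seed(seed, {
    ord <- sample.int(length(regions))
    cum <- 0; sel <- logical(length(regions))
    for (i in ord) {
      a <- regions[[i]]$area
      if (cum >= target * 0.98) break
      if (cum + a <= target * 1.08) { sel[i] <- TRUE; cum <- cum + a }
    }
    sel
  })
  if (completeness >= 1) keep[] <- TRUE
  annotation_set(regions[keep])
}

#' Rasterize a polygon to a logical pixel mask
#'
#' Even-odd scanline fill over pixel centers; boundary pixels are included.
#'
#' @param polygon Two-column \code{(row, col)} matrix of boundary pixel
#'   centers (closed implicitly).
#' @param h,w Raster extent.
#' @return Logical \code{h x w} matrix.
#' @export
rasterize_polygon <- function(polygon, h, w) {
  r <- polygon[, 1]; cc <- polygon[, 2]
  rn <- c(r[-1], r[1]); cn <- c(cc[-1], cc[1])
  out <- matrix(FALSE, h, w)
  for (row in seq.int(max(1L, floor(min(r))), min(h, ceiling(max(r))))) {
    cross <- (r <= row & rn > row) | (rn <= row & r > row)
    if (!any(cross)) next
    xs <- sort(cc[cross] + (row - r[cross]) * (cn[cross] - cc[cross]) /
                 (rn[cross] - r[cross]))
    for (k in seq.int(1L, length(xs) - 1L, by = 2L)) {
      lo <- max(1L, ceiling(xs[k])); hi <- min(w, floor(xs[k + 1L]))
      if (hi >= lo) out[row, lo:hi] <- TRUE
    }
  }
  bdry <- cbind(pmin(pmax(round(r), 1L), h), pmin(pmax(round(cc), 1L), w))
  out[bdry] <- TRUE
  out
}

#' Rasterize an annotation set to a class raster
#'
#' Later polygons overwrite earlier ones where they overlap (overlaps do not
#' arise from \code{\link{generate_annotation_set}}).
#'
#' @param ann An \code{annotation_set}.
#' @param h,w Raster extent.
#' @return Integer label raster (0 where unannotated).
#' @export
rasterize_annotations <- function(ann, h, w) {
  stopifnot(inherits(ann, "annotation_set"))
  out <- matrix(0L, h, w)
  for (a in ann$annotations)
    out[rasterize_polygon(a$polygon, h, w)] <- class_code(a$label)
  out
}

polygon_area_px <- function(ann, h, w) {
  sum(rasterize_annotations(ann, h, w) > 0L)
}

#' Read and write annotation sets as GeoJSON
#'
#' Polygons become GeoJSON \code{Polygon} features with a \code{label}
#' property; coordinates are 0-based \code{(x, y)} pixel positions.
#'
#' @param ann An \code{annotation_set}.
#' @param path File path.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
write_annotations_geojson <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  features <- lapply(ann$annotations, function(a) {
    coords <- cbind(a$polygon[, 2] - 1, a$polygon[, 1] - 1)  # (x, y)
    coords <- rbind(coords, coords[1, ])                     # close ring
    list(type = "Feature",
         properties = list(label = a$label),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(
                           seq_len(nrow(coords)),
                           function(i) unname(coords[i, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotations_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  anns <- lapply(g$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]
    poly <- cbind(row = xy[, 2] + 1, col = xy[, 1] + 1)
    list(label = f$properties$label, polygon = poly,
         area = NA_integer_)
  })
  annotation_set(anns)
}
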