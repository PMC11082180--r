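#' Slide inference with overlap voting
#'
#' A patch classifier is applied to every sliding window inside the tissue
#' region; each window's class-probability vector is added to all of its
#' pixels and its argmax class receives one vote there. Per-pixel fusion
#' then takes either the class with the most votes or the class with the
#' highest mean score. Pixels covered by no window are "unscored" (code 0)
#' and excluded from downstream metrics.
#'
#' @name wsi_inference
NULL

#' Vote fusion policy
#'
#' @param mode \code{"max_votes"} (class with most argmax votes) or
#'   \code{"max_mean_score"} (class with highest score sum / coverage).
#' @return A \code{vote_policy}. Ties are always broken the same way: first
#'   by higher mean score, then by the more severe class
#'   (GP5 > GP4 > GP3 > benign > stroma), so fusion is total.
#' @export
vote_policy <- function(mode = c("max_votes", "max_mean_score")) {
  structure(list(mode = match.arg(mode)), class = "vote_policy")
}

#' Score a slide with a sliding-window classifier
#'
#' Windows are enumerated over the tissue bounding box at the scale's
#' stride; windows with less than \code{min_tissue} tissue are skipped
#' (background safety). Accumulation is order-independent.
#'
#' @param img A \code{\link{labeled_image}}.
#' @param classifier A \code{\link{patch_classifier}} (or any object with a
#'   \code{predict} method returning a 5-class probability matrix).
#' @param scale A \code{\link{patch_scale}}.
#' @param mask Optional tissue mask (default computed); must be non-empty.
#' @param min_tissue Minimum tissue fraction for a window to be scored.
#' @return A \code{score_accumulator}: per-pixel per-class score sums and
#'   vote counts (\code{h x w x 5} arrays), per-pixel window coverage, the
#'   scored window table, and the per-window probability matrix.
#' @export
predict_slide <- function(img, classifier, scale, mask = NULL,
                          min_tissue = 0.5) {
  stopifnot(inherits(img, "labeled_image"), inherits(scale, "patch_scale"))
  if (is.null(mask)) mask <- tissue_mask(img)
  if (!any(mask)) stop("empty tissue mask", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  hit <- which(mask, arr.ind = TRUE)
  bb <- c(min(hit[, 1]), min(hit[, 2]), max(hit[, 1]), max(hit[, 2]))
  wins <- enumerate_windows(c(bb[3] - bb[1] + 1L, bb[4] - bb[2] + 1L), scale)
  if (!nrow(wins)) stop("tissue extent smaller than one window", call. = FALSE)
  wins$r0 <- wins$r0 + bb[1]  # 1-based absolute top-left row
  wins$c0 <- wins$c0 + bb[2]

  keep <- logical(nrow(wins))
  probs <- matrix(NA_real_, nrow(wins), 5L,
                  dimnames = list(NULL, gleason_classes()))
  feats <- NULL
  for (k in seq_len(nrow(wins))) {
    rows <- wins$r0[k]:(wins$r0[k] + scale$side_x - 1L)
    cols <- wins$c0[k]:(wins$c0[k] + scale$side_x - 1L)
    if (mean(mask[rows, cols]) < min_tissue) next
    keep[k] <- TRUE
    pix <- resize_area_rgb(img$rgb[rows, cols, , drop = FALSE],
                           scale$target_side, scale$target_side)
    feats <- rbind(feats, patch_features(pix))
  }
  if (!any(keep)) stop("no valid window inside the tissue region", call. = FALSE)
  probs[keep, ] <- predict(classifier, feats, type = "prob")
  wins <- wins[keep, , drop = FALSE]
  probs <- probs[keep, , drop = FALSE]

  scores <- array(0, c(h, w, 5L))
  votes <- array(0L, c(h, w, 5L))
  coverage <- matrix(0L, h, w)
  for (k in seq_len(nrow(wins))) {
    rows <- wins$r0[k]:(wins$r0[k] + scale$side_x - 1L)
    cols <- wins$c0[k]:(wins$c0[k] + scale$side_x - 1L)
    top <- which.max(probs[k, ])
    for (cl in 1:5)
      scores[rows, cols, cl] <- scores[rows, cols, cl] + probs[k, cl]
    votes[rows, cols, top] <- votes[rows, cols, top] + 1L
    coverage[rows, cols] <- coverage[rows, cols] + 1L
  }
  structure(list(scores = scores, votes = votes, coverage = coverage,
                 windows = wins, window_probs = probs,
                 classes = gleason_classes(), side = scale$side_x),
            class = "score_accumulator")
}

#' @export
print.score_accumulator <- function(x, ...) {
  cat(sprintf("<score_accumulator> %d x %d px, %d windows, max coverage %d\n",
              nrow(x$coverage), ncol(x$coverage), nrow(x$windows),
              max(x$coverage)))
  invisible(x)
}

# Vectorized argmax over the 5 class planes with the documented two-level
# tie-break (higher mean score, then severity). Classes are scanned in
# increasing severity with >=-replacement, so later (more severe) classes
# win exact ties.
fuse_argmax <- function(key, meanscore) {
  sev_order <- order(severity_rank())   # least to most severe class index
  h <- dim(key)[1]; w <- dim(key)[2]
  best_key <- matrix(-Inf, h, w); best_ms <- matrix(-Inf, h, w)
  best_cl <- matrix(0L, h, w)
  for (cl in sev_order) {
    k <- key[, , cl]; m <- meanscore[, , cl]
    take <- (k > best_key) | (k == best_key & m >= best_ms)
    best_key[take] <- k[take]; best_ms[take] <- m[take]
    best_cl[take] <- cl
  }
  best_cl
}

#' Fuse accumulated window predictions into a label raster
#'
#' @param acc A \code{score_accumulator}.
#' @param policy A \code{\link{vote_policy}}.
#' @return Integer label raster: class codes per
#'   \code{\link{gleason_classes}}, 0 where unscored (zero coverage).
#' @export
vote <- function(acc, policy = vote_policy("max_votes")) {
  stopifnot(inherits(acc, "score_accumulator"), inherits(policy, "vote_policy"))
  cov <- acc$coverage
  meanscore <- acc$scores
  for (cl in 1:5)
    meanscore[, , cl] <- ifelse(cov > 0, acc$scores[, , cl] / pmax(cov, 1L), 0)
  key <- if (policy$mode == "max_votes") {
    k <- array(as.numeric(acc$votes), dim(acc$votes)); k
  } else meanscore
  lab <- fuse_argmax(key, meanscore)
  lab[cov == 0L] <- 0L
  lab
}

# Majority (mode) filter within a square neighborhood, scored pixels only.
mode_filter <- function(lab, radius) {
  if (radius < 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  counts <- array(0, c(h, w, 5L))
  scored <- lab > 0L
  for (cl in 1:5) {
    m <- matrix(as.numeric(lab == cl), h, w)
    # box sum via shift-and-add with zero padding
    acc <- matrix(0, h, w)
    for (dr in -radius:radius) {
      rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
      rs_valid <- seq_len(h) + dr >= 1L & seq_len(h) + dr <= h
      row_m <- m[rs, , drop = FALSE]; row_m[!rs_valid, ] <- 0
      acc <- acc + row_m
    }
    acc2 <- matrix(0, h, w)
    for (dc in -radius:radius) {
      cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
      cs_valid <- seq_len(w) + dc >= 1L & seq_len(w) + dc <= w
      col_m <- acc[, cs, drop = FALSE]; col_m[, !cs_valid] <- 0
      acc2 <- acc2 + col_m
    }
    counts[, , cl] <- acc2
  }
  sev <- severity_rank()
  best <- matrix(0L, h, w); best_n <- matrix(-Inf, h, w)
  for (cl in order(sev)) {
    n <- counts[, , cl]
    take <- n > best_n | (n == best_n)   # severity breaks exact ties
    best[take] <- cl; best_n[take] <- n[take]
  }
  out <- lab
  out[scored] <- best[scored]
  out
}

#' Simplify a predicted label raster for pathologist review
#'
#' Raw per-pixel fusion output contains excess detail; for human review the
#' map is simplified: boundaries are smoothed with a majority filter and
#' regions smaller than \code{min_region_area} are absorbed into their
#' dominant neighbor. The smooth/merge cycle runs to a fixed point, so a
#' second pass changes nothing.
#'
#' @param lab Integer label raster (0 = unscored).
#' @param min_region_area Minimum region area in pixels.
#' @param smooth_radius Majority-filter radius in pixels (0 disables).
#' @param max_iter Safety cap on smooth/merge cycles.
#' @return List: \code{labels} (simplified raster) and \code{polygons}
#'   (an \code{annotation_set} tracing the simplified regions).
#' @export
simplify_prediction <- function(lab, min_region_area = 100L,
                                smooth_radius = 2L, max_iter = 10L) {
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  for (it in seq_len(max_iter)) {
    prev <- lab
    lab <- mode_filter(lab, smooth_radius)
    lab <- absorb_small_regions(lab, min_region_area)
    if (identical(lab, prev)) break
  }
  polys <- generate_annotation_set(lab, completeness = 1, seed = 1L,
                                   min_region_area = 1L)
  list(labels = lab, polygons = polys)
}

absorb_small_regions <- function(lab, min_area) {
  h <- nrow(lab); w <- ncol(lab)
  repeat {
    changed <- FALSE
    for (cl in sort(unique(lab[lab > 0L]))) {
      comp <- EBImage::bwlabel(lab == cl)
      areas <- tabulate(comp[comp > 0L])
      for (i in which(areas < min_area)) {
        px <- which(comp == i, arr.ind = TRUE)
        # neighbor class with the largest shared boundary
        nb <- integer(0)
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- cbind(px[, 1] + d[1], px[, 2] + d[2])
          ok <- q[, 1] >= 1 & q[, 1] <= h & q[, 2] >= 1 & q[, 2] <= w
          q <- q[ok, , drop = FALSE]
          vals <- lab[q]
          nb <- c(nb, vals[vals > 0L & vals != cl])
        }
        if (!length(nb)) next
        tab <- tabulate(nb, nbins = 5L)
        top <- max(tab)
        cand <- which(tab == top)
        target <- cand[which.max(severity_rank()[cand])]
        lab[px] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}
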