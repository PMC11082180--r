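#' Synthetic tissue-image fixtures
#'
#' Seeded generators that emulate H&E prostatectomy slides at desk scale:
#' tissue-like images with exhaustive label rasters, scanner-style color
#' shifts, controlled quality degradations, and partial polygon annotations.
#' Textures are procedural and only intended to be *separable* by a simple
#' classifier, not histologically realistic: benign tissue gets ring/gland
#' motifs, GP3 small well-separated discs, GP4 fused irregular blobs, GP5
#' diffuse fine speckle, stroma a smooth low-frequency pink field, and
#' background is near-white with slight noise.
#'
#' @name synthetic_fixtures
NULL

#' Specify a synthetic tissue layout
#'
#' @param image_side Image side in pixels (square image, >= 64).
#' @param class_fractions Named numeric vector of target area fractions over
#'   (a subset of) \code{\link{gleason_classes}}.
#' @param background_fraction Fraction of white background. Together with
#'   \code{class_fractions} must sum to 1 (tolerance 1e-9).
#' @param seed Integer seed; the whole layout and all textures derive from it.
#' @param block_side Side of the layout blocks the image is built from
#'   (must divide \code{image_side}); smaller blocks give more, smaller
#'   connected regions per class.
#' @return A \code{tissue_layout_spec} object.
#' @export
#' @examples
#' spec <- tissue_layout_spec(256, c(GP3 = 0.3, benign = 0.3, stroma = 0.2),
#'                            background_fraction = 0.2, seed = 1)
#' img <- generate_tissue_image(spec)
tissue_layout_spec <- function(image_side,
                               class_fractions,
                               background_fraction = 0,
                               seed = 1L,
                               block_side = max(16L, image_side %/% 16L)) {
  if (image_side < 64) stop("'image_side' must be >= 64", call. = FALSE)
  if (length(class_fractions)) {
    if (is.null(names(class_fractions)) ||
        !all(names(class_fractions) %in% gleason_classes()))
      stop("'class_fractions' must be named with tissue classes", call. = FALSE)
  }
  fr <- c(class_fractions, background = background_fraction)
  if (any(fr < -1e-9) || any(fr > 1 + 1e-9) || abs(sum(fr) - 1) > 1e-9)
    stop("fractions must lie in [0,1] and sum to 1 (incl. background)",
         call. = FALSE)
  if (image_side %% block_side != 0)
    stop("'block_side' must divide 'image_side'", call. = FALSE)
  structure(list(image_side = as.integer(image_side),
                 class_fractions = class_fractions,
                 background_fraction = background_fraction,
                 seed = as.integer(seed),
                 block_side = as.integer(block_side)),
            class = "tissue_layout_spec")
}

# Largest-remainder apportionment of n items to fractions.
apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Serpentine (boustrophedon) order over an nb x nb block grid, so consecutive
# blocks are always 4-adjacent and runs form connected regions.
serpentine_order <- function(nb) {
  idx <- matrix(seq_len(nb * nb), nb, nb)
  cols <- lapply(seq_len(nb), function(j) if (j %% 2L) idx[, j] else rev(idx[, j]))
  unlist(cols)
}

#' Generate a seeded tissue-like image with exhaustive labels
#'
#' Lays out connected class regions on a block grid (realized area fractions
#' match the spec up to block rounding), then renders a per-class procedural
#' texture. Bit-identical output under the same spec.
#'
#' @param spec A \code{\link{tissue_layout_spec}}.
#' @return A \code{\link{labeled_image}} with an exhaustive label raster.
#' @export
generate_tissue_image <- function(spec) {
  stopifnot(inherits(spec, "tissue_layout_spec"))
  with_seed(spec$seed, {
    side <- spec$image_side; bs <- spec$block_side
    nb <- side %/% bs
    fr <- c(spec$class_fractions, background = spec$background_fraction)
    counts <- apportion(fr, nb * nb)
    names(counts) <- names(fr)

    # Split each class's block allocation into chunks of 3-8 blocks and lay
    # the shuffled chunk sequence along a serpentine path: several connected
    # regions per class, exact block counts.
    chunks <- list()
    for (cls in names(counts)) {
      n <- counts[[cls]]
      while (n > 0L) {
        take <- min(n, sample(3:8, 1L))
        chunks[[length(chunks) + 1L]] <- list(class = cls, n = take)
        n <- n - take
      }
    }
    chunks <- chunks[sample.int(length(chunks))]
    path <- serpentine_order(nb)
    block_class <- character(nb * nb)
    pos <- 1L
    for (ch in chunks) {
      block_class[path[pos:(pos + ch$n - 1L)]] <- ch$class
      pos <- pos + ch$n
    }
    block_mat <- matrix(block_class, nb, nb)

    codes <- matrix(0L, nb, nb)
    present <- names(counts)[counts > 0 & names(counts) != "background"]
    for (cls in present) codes[block_mat == cls] <- class_code(cls)
    labels <- codes[rep(seq_len(nb), each = bs), rep(seq_len(nb), each = bs)]

    rgb <- render_textures(labels, side)
    labeled_image(rgb, labels)
  })
}

# ---- procedural texture rendering (seeded by the caller) -------------------

tissue_palette <- function() {
  list(background = c(246, 245, 243),
       stroma     = c(232, 190, 200),
       benign     = c(228, 185, 198),
       GP3        = c(225, 178, 194),
       GP4        = c(218, 170, 190),
       GP5        = c(210, 165, 185),
       gland_rim  = c(125,  85, 150),
       gland_lumen = c(240, 232, 238),
       gp3_disc   = c(135,  92, 162),
       gp4_blob   = c(112,  72, 142),
       gp5_dot    = c( 92,  60, 125))
}

# Fill `color` into rgb at pixels where both `where` and a disc around
# (r0, c0) hold.
draw_disc <- function(rgb, where, r0, c0, radius, color) {
  h <- nrow(where); w <- ncol(where)
  rr <- max(1L, r0 - radius):min(h, r0 + radius)
  cc <- max(1L, c0 - radius):min(w, c0 + radius)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  hit <- d2 <= radius^2 & where[rr, cc, drop = FALSE]
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    px <- cbind(rr[idx[, 1]], cc[idx[, 2]])
    for (ch in 1:3) rgb[cbind(px, ch)] <- color[ch]
  }
  rgb
}

draw_annulus <- function(rgb, where, r0, c0, r_out, r_in, rim, lumen) {
  h <- nrow(where); w <- ncol(where)
  rr <- max(1L, r0 - r_out):min(h, r0 + r_out)
  cc <- max(1L, c0 - r_out):min(w, c0 + r_out)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  msk <- where[rr, cc, drop = FALSE]
  ring <- d2 <= r_out^2 & d2 > r_in^2 & msk
  core <- d2 <= r_in^2 & msk
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    sub <- plane[rr, cc, drop = FALSE]
    sub[ring] <- rim[ch]; sub[core] <- lumen[ch]
    plane[rr, cc] <- sub
    rgb[, , ch] <- plane
  }
  rgb
}

# Jittered-grid centers restricted to a class mask.
mask_centers <- function(mask, spacing, jitter) {
  hits <- which(mask, arr.ind = TRUE)
  if (!nrow(hits)) return(matrix(integer(), 0, 2))
  rs <- seq(min(hits[, 1]), max(hits[, 1]), by = spacing)
  cs <- seq(min(hits[, 2]), max(hits[, 2]), by = spacing)
  grid <- expand.grid(r = rs, c = cs)
  grid$r <- pmax(1L, pmin(nrow(mask), grid$r + sample(-jitter:jitter, nrow(grid), TRUE)))
  grid$c <- pmax(1L, pmin(ncol(mask), grid$c + sample(-jitter:jitter, nrow(grid), TRUE)))
  keep <- mask[cbind(grid$r, grid$c)]
  as.matrix(grid[keep, , drop = FALSE])
}

low_freq_field <- function(side, cell = 32L, amplitude = 1) {
  nc <- max(2L, side %/% cell)
  coarse <- gauss_blur(matrix(stats::runif(nc * nc, -1, 1), nc, nc), 1)
  # bilinear upsample of the coarse grid to full resolution
  pos <- (seq_len(side) - 0.5) / side * (nc - 1) + 1
  i0 <- pmin(floor(pos), nc - 1L); f <- pos - i0
  rows0 <- coarse[i0, , drop = FALSE]; rows1 <- coarse[i0 + 1L, , drop = FALSE]
  m <- rows0 * (1 - f) + rows1 * f
  cols0 <- m[, i0, drop = FALSE]; cols1 <- m[, i0 + 1L, drop = FALSE]
  fw <- matrix(f, nrow(m), side, byrow = TRUE)
  amplitude * (cols0 * (1 - fw) + cols1 * fw)
}

render_textures <- function(labels, side) {
  pal <- tissue_palette()
  rgb <- array(0, c(side, side, 3L))
  for (ch in 1:3) rgb[, , ch] <- pal$background[ch]

  for (cls in gleason_classes()) {
    mask <- labels == class_code(cls)
    if (!any(mask)) next
    base <- pal[[cls]]
    for (ch in 1:3) {
      plane <- rgb[, , ch]; plane[mask] <- base[ch]; rgb[, , ch] <- plane
    }
    if (cls == "stroma") {
      # smooth low-frequency field plus oriented fibrous striations
      f <- low_freq_field(side, amplitude = 28)
      theta <- stats::runif(1, 0, pi)
      ri <- matrix(seq_len(side), side, side)
      ci <- matrix(seq_len(side), side, side, byrow = TRUE)
      stria <- 14 * sin(2 * pi * (cos(theta) * ri + sin(theta) * ci) / 24)
      wgt <- c(1, 0.85, 0.95)
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[mask] <- plane[mask] + wgt[ch] * (f[mask] + stria[mask])
        rgb[, , ch] <- plane
      }
    } else if (cls == "benign") {
      ctr <- mask_centers(mask, spacing = 24L, jitter = 6L)
      for (i in seq_len(nrow(ctr))) {
        r_out <- sample(8:11, 1L)
        rgb <- draw_annulus(rgb, mask, ctr[i, 1], ctr[i, 2], r_out, r_out - 3L,
                            pal$gland_rim, pal$gland_lumen)
      }
    } else if (cls == "GP3") {
      ctr <- mask_centers(mask, spacing = 14L, jitter = 3L)
      for (i in seq_len(nrow(ctr)))
        rgb <- draw_disc(rgb, mask, ctr[i, 1], ctr[i, 2], sample(3:5, 1L),
                         pal$gp3_disc)
    } else if (cls == "GP4") {
      ctr <- mask_centers(mask, spacing = 11L, jitter = 4L)
      for (i in seq_len(nrow(ctr)))
        rgb <- draw_disc(rgb, mask, ctr[i, 1], ctr[i, 2], sample(6:10, 1L),
                         pal$gp4_blob)
    } else if (cls == "GP5") {
      n <- sum(mask)
      dots <- which(mask)[stats::runif(n) < 0.10]
      for (ch in 1:3) {
        plane <- rgb[, , ch]; plane[dots] <- pal$gp5_dot[ch]; rgb[, , ch] <- plane
      }
    }
  }
  # Smooth stain-density inhomogeneity over all tissue (every real slide has
  # it; it also keeps low-pass contrast meaningful for fine textures).
  tissue <- labels > 0L
  if (any(tissue)) {
    stain <- low_freq_field(side, cell = 20L, amplitude = 14)
    wgt <- c(1, 0.9, 0.95)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[tissue] <- plane[tissue] + wgt[ch] * stain[tissue]
      rgb[, , ch] <- plane
    }
  }
  # Slight optical softening, a shared low-frequency illumination field and
  # per-pixel sensor noise: keeps per-channel intensity histograms smooth and
  # quasi-continuous, as on real scanners.
  illum <- low_freq_field(side, cell = 32L, amplitude = 5)
  noise <- matrix(stats::rnorm(side * side, 0, 8), side, side)
  for (ch in 1:3)
    rgb[, , ch] <- clip255(gauss_blur(rgb[, , ch], 0.7) + illum + noise)
  rgb
}

# ---- scanner styles --------------------------------------------------------

#' Define a scanner appearance style
#'
#' A per-channel intensity transform emulating inter-scanner appearance
#' differences: \code{v' = clip(gain * (v/255)^gamma * 255 + offset)}.
#'
#' @param gain Per-channel multiplicative factor (> 0; length 1 or 3).
#' @param offset Per-channel additive intensity (length 1 or 3).
#' @param gamma Per-channel exponent (> 0; length 1 or 3).
#' @param name Style label.
#' @return A \code{scanner_style} object.
#' @export
scanner_style <- function(gain = 1, offset = 0, gamma = 1, name = "custom") {
  as3 <- function(x) if (length(x) == 1L) rep(x, 3L) else x
  gain <- as3(gain); offset <- as3(offset); gamma <- as3(gamma)
  stopifnot(length(gain) == 3L, length(offset) == 3L, length(gamma) == 3L)
  if (any(gain <= 0) || any(gamma <= 0))
    stop("'gain' and 'gamma' must be positive", call. = FALSE)
  structure(list(gain = gain, offset = offset, gamma = gamma, name = name),
            class = "scanner_style")
}

#' Built-in scanner style presets
#'
#' Emulates the study setting where some scanners produce darker images
#' (styles "scannerB", "scannerC") and one lighter images ("scannerD")
#' relative to the baseline ("identity").
#'
#' @param name One of \code{"identity"}, \code{"scannerB"}, \code{"scannerC"},
#'   \code{"scannerD"}.
#' @return A \code{\link{scanner_style}}.
#' @export
scanner_style_preset <- function(name = c("identity", "scannerB", "scannerC",
                                          "scannerD")) {
  name <- match.arg(name)
  switch(name,
    identity = scanner_style(1, 0, 1, "identity"),
    scannerB = scanner_style(gain = c(0.97, 0.96, 0.98), offset = -10,
                             gamma = 1.02, name = "scannerB"),
    scannerC = scanner_style(gain = c(0.96, 0.95, 0.96), offset = -18,
                             gamma = 1.03, name = "scannerC"),
    scannerD = scanner_style(gain = 1, offset = c(6, 7, 6),
                             gamma = 0.99, name = "scannerD"))
}

#' Apply a scanner style to an image
#'
#' Appearance-only transform: the label raster is returned unchanged.
#'
#' @param img A \code{\link{labeled_image}}.
#' @param style A \code{\link{scanner_style}}.
#' @return A \code{\link{labeled_image}}.
#' @export
apply_scanner_style <- function(img, style) {
  stopifnot(inherits(img, "labeled_image"), inherits(style, "scanner_style"))
  rgb <- img$rgb
  for (ch in 1:3)
    rgb[, , ch] <- clip255(style$gain[ch] * (rgb[, , ch] / 255)^style$gamma[ch] *
                             255 + style$offset[ch])
  labeled_image(rgb, img$labels)
}

# ---- quality degradations --------------------------------------------------

#' Specify a quality degradation
#'
#' @param kind One of \code{"blur"}, \code{"low_contrast"},
#'   \code{"saturation_clip"}, \code{"artifact"}, \code{"uniform_patch"}.
#' @param magnitude Kind-specific parameter: blur sigma in pixels (> 0);
#'   contrast scale factor in (0, 1]; clipped-area fraction in (0, 1];
#'   artifact stroke width in pixels (>= 1); ignored for
#'   \code{uniform_patch}.
#' @param region Optional sub-rectangle \code{c(r0, c0, r1, c1)} (1-based,
#'   inclusive); default the whole image.
#' @param seed Integer seed for the (deterministic) placement randomness.
#' @return A \code{degradation_spec} object.
#' @export
degradation_spec <- function(kind, magnitude = 1, region = NULL, seed = 1L) {
  kinds <- c("blur", "low_contrast", "saturation_clip", "artifact",
             "uniform_patch")
  if (!kind %in% kinds)
    stop("unknown degradation kind: ", kind, call. = FALSE)
  ok <- switch(kind,
    blur = magnitude > 0,
    low_contrast = magnitude > 0 && magnitude <= 1,
    saturation_clip = magnitude > 0 && magnitude <= 1,
    artifact = magnitude >= 1,
    uniform_patch = TRUE)
  if (!ok) stop("'magnitude' out of range for kind ", kind, call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude, region = region,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Seeded QC fixture suite
#'
#' Generates a set of tissue tiles with known injected quality degradations
#' for calibrating and validating the QC module: about half the tiles stay
#' for calibrating and validating the QC module: one sixth of the tiles stay
#' clean and the rest receive one degradation each (blur sigma 3, contrast
#' scale 0.2, 12% clipped area, a 6 px dark pen stroke, or a flat
#' uniform-texture fault), in equal shares.
#'
#' @param n_tiles Number of tiles.
#' @param tile_side Tile side in pixels (multiple of 32).
#' @param seed Integer seed.
#' @return List of records: \code{img} (a \code{\link{labeled_image}} tile)
#'   and \code{kind} (\code{"clean"} or the injected degradation kind).
#' @export
qc_fixture_suite <- function(n_tiles = 200L, tile_side = 128L, seed = 1L) {
  kinds <- c("blur", "low_contrast", "saturation_clip", "artifact",
             "uniform_patch")
  mags <- c(blur = 3, low_contrast = 0.2, saturation_clip = 0.12,
            artifact = 6, uniform_patch = 60)
  with_seed(seed, {
    per_slide <- 16L
    n_slides <- ceiling(n_tiles / per_slide)
    assign_kind <- sample(rep(c("clean", kinds),
                              length.out = n_tiles)[sample.int(n_tiles)])
    out <- vector("list", n_tiles)
    idx <- 0L
    for (s in seq_len(n_slides)) {
      spec <- tissue_layout_spec(4L * tile_side,
                                 c(GP3 = 0.22, GP4 = 0.2, GP5 = 0.12,
                                   benign = 0.22, stroma = 0.19),
                                 background_fraction = 0.05,
                                 seed = sample.int(1e6, 1L),
                                 block_side = tile_side %/% 2L)
      slide <- generate_tissue_image(spec)
      tiles <- tile_image(slide, tile_side)
      for (t in tiles) {
        idx <- idx + 1L
        if (idx > n_tiles) break
        kind <- assign_kind[idx]
        img <- t$img
        if (kind != "clean")
          img <- apply_degradation(img, degradation_spec(
            kind, mags[[kind]], seed = sample.int(1e6, 1L)))
        out[[idx]] <- list(img = img, kind = kind)
      }
    }
    out[seq_len(min(idx, n_tiles))]
  })
}

#' Inject a quality degradation into an image
#'
#' Emulates the five slide-quality issue categories assessed by the QC
#' module: out-of-focus blur, low contrast, clipped saturation, foreign
#' artifacts (a dark pen stroke), and texture-uniformity faults (a flat
#' patch). Deterministic given the spec's seed; confined to \code{region}
#' when one is given. Labels are unchanged.
#'
#' @param img A \code{\link{labeled_image}}.
#' @param spec A \code{\link{degradation_spec}}.
#' @return A \code{\link{labeled_image}}.
#' @export
apply_degradation <- function(img, spec) {
  stopifnot(inherits(img, "labeled_image"), inherits(spec, "degradation_spec"))
  h <- nrow(img$labels); w <- ncol(img$labels)
  reg <- if (is.null(spec$region)) c(1L, 1L, h, w) else as.integer(spec$region)
  rows <- reg[1]:reg[3]; cols <- reg[2]:reg[4]
  rgb <- img$rgb
  with_seed(spec$seed, {
    if (spec$kind == "blur") {
      for (ch in 1:3)
        rgb[rows, cols, ch] <- gauss_blur(rgb[rows, cols, ch, drop = TRUE],
                                          spec$magnitude)
    } else if (spec$kind == "low_contrast") {
      for (ch in 1:3) {
        sub <- rgb[rows, cols, ch, drop = TRUE]
        rgb[rows, cols, ch] <- mean(sub) + spec$magnitude * (sub - mean(sub))
      }
    } else if (spec$kind == "saturation_clip") {
      # clip a square sub-block covering `magnitude` of the region area
      side <- round(sqrt(spec$magnitude * length(rows) * length(cols)))
      side_r <- min(side, length(rows)); side_c <- min(side, length(cols))
      r0 <- rows[1] + sample.int(length(rows) - side_r + 1L, 1L) - 1L
      c0 <- cols[1] + sample.int(length(cols) - side_c + 1L, 1L) - 1L
      rgb[r0:(r0 + side_r - 1L), c0:(c0 + side_c - 1L), ] <- 255
    } else if (spec$kind == "artifact") {
      # dark pen stroke across the region diagonal
      width <- spec$magnitude
      t <- seq(0, 1, length.out = 4L * max(length(rows), length(cols)))
      pr <- rows[1] + t * (length(rows) - 1L)
      pc <- cols[1] + t * (length(cols) - 1L) * 0.8 + 0.1 * length(cols)
      ink <- c(25, 45, 55)
      for (k in seq_along(t)) {
        rr <- max(1L, round(pr[k] - width / 2)):min(h, round(pr[k] + width / 2))
        cc <- max(1L, round(pc[k] - width / 2)):min(w, round(pc[k] + width / 2))
        for (ch in 1:3) rgb[rr, cc, ch] <- ink[ch]
      }
    } else if (spec$kind == "uniform_patch") {
      # scan-fault-like flat texture: mean color plus a smooth intensity
      # ramp (amplitude = magnitude) and weak sensor noise, so local
      # variance is spatially uniform while brightness, contrast and
      # sharpness stay plausible
      amp <- if (spec$magnitude > 1) spec$magnitude else 60
      nr <- length(rows); ncl <- length(cols)
      theta <- stats::runif(1, 0, 2 * pi)
      ri <- matrix(seq_len(nr) / nr, nr, ncl)
      ci <- matrix(seq_len(ncl) / ncl, nr, ncl, byrow = TRUE)
      ramp <- amp * (cos(theta) * ri + sin(theta) * ci -
                       (cos(theta) + sin(theta)) / 2)
      noise <- matrix(stats::rnorm(nr * ncl, 0, 5), nr, ncl)
      for (ch in 1:3)
        rgb[rows, cols, ch] <- mean(rgb[rows, cols, ch]) + ramp + noise
    }
  })
  labeled_image(clip255(rgb), img$labels)
}
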