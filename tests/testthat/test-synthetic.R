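test_that("tissue generation is seeded-deterministic and hits target fractions", {
  spec <- tissue_layout_spec(256, c(GP3 = 0.3, benign = 0.3, stroma = 0.2),
                             background_fraction = 0.2, seed = 7)
  a <- generate_tissue_image(spec)
  b <- generate_tissue_image(spec)
  expect_identical(a, b)
  expect_gte(mean(a$labels == class_code("GP3")), 0.25)
  expect_lte(mean(a$labels == class_code("GP3")), 0.35)
  # every requested fraction realized within 5 percentage points
  for (cls in names(spec$class_fractions))
    expect_lt(abs(mean(a$labels == class_code(cls)) -
                    spec$class_fractions[[cls]]), 0.05)
  expect_lt(abs(mean(a$labels == 0L) - 0.2), 0.05)
})

test_that("degenerate and invalid layouts are handled", {
  white <- generate_tissue_image(
    tissue_layout_spec(64, numeric(0), background_fraction = 1, seed = 1))
  expect_true(all(white$labels == 0L))
  expect_gt(mean(white$rgb), 235)
  expect_error(tissue_layout_spec(256, c(GP3 = 0.5), 0.6), "sum to 1")
  expect_error(tissue_layout_spec(256, c(GP3 = -0.1), 1.1), "sum to 1")
  expect_error(tissue_layout_spec(32, c(GP3 = 1)), ">= 64")
  expect_error(tissue_layout_spec(250, c(GP3 = 1)), "divide")
})

test_that("scanner styles transform intensities but never labels", {
  img <- mixed_slide(3, side = 192, block_side = 48)
  ident <- apply_scanner_style(img, scanner_style(1, 0, 1))
  expect_equal(ident$rgb, img$rgb)
  darker <- apply_scanner_style(img, scanner_style(1, -30, 1))
  expect_lt(mean(darker$rgb), mean(img$rgb))
  expect_identical(darker$labels, img$labels)
  for (preset in c("scannerB", "scannerC", "scannerD")) {
    st <- scanner_style_preset(preset)
    out <- apply_scanner_style(img, st)
    expect_identical(out$labels, img$labels)
  }
  expect_lt(mean(apply_scanner_style(img,
    scanner_style_preset("scannerC"))$rgb), mean(img$rgb))
  expect_gt(mean(apply_scanner_style(img,
    scanner_style_preset("scannerD"))$rgb), mean(img$rgb))
  expect_error(scanner_style(gain = -1), "positive")
})

test_that("two scanner styles separate into distinct channel-mean clusters", {
  styles <- list(scanner_style_preset("identity"),
                 scanner_style_preset("scannerC"))
  pts <- list()
  for (sd in 1:10) {
    img <- mixed_slide(sd, side = 192, block_side = 48)
    for (si in 1:2) {
      out <- apply_scanner_style(img, styles[[si]])
      m <- tissue_mask(out)
      pts[[length(pts) + 1L]] <- c(style = si,
                                   vapply(1:3, function(ch)
                                     mean(out$rgb[, , ch][m]), 0))
    }
  }
  pts <- do.call(rbind, pts)
  centers <- rbind(colMeans(pts[pts[, 1] == 1, -1, drop = FALSE]),
                   colMeans(pts[pts[, 1] == 2, -1, drop = FALSE]))
  inter <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  intra <- max(vapply(1:2, function(si) {
    p <- pts[pts[, 1] == si, -1, drop = FALSE]
    max(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
  }, 0))
  expect_gt(inter, 2 * intra)
})

test_that("degradations change images as specified and stay in-region", {
  img <- mixed_slide(5, side = 192, block_side = 48)
  thr <- qc_thresholds(tile_side = 128)
  tile <- labeled_image(img$rgb[1:128, 1:128, , drop = FALSE],
                        img$labels[1:128, 1:128])
  rec0 <- compute_quality_metrics(tile, thr)

  blur <- apply_degradation(tile, degradation_spec("blur", 3))
  expect_lt(compute_quality_metrics(blur, thr)$focus, rec0$focus)

  lc <- apply_degradation(tile, degradation_spec("low_contrast", 0.5))
  rng <- function(x) diff(stats::quantile(rgb_to_gray(x$rgb), c(0.05, 0.95)))
  ratio <- rng(lc) / rng(tile)
  expect_gt(ratio, 0.45); expect_lt(ratio, 0.55)

  pen <- apply_degradation(tile, degradation_spec("artifact", 6))
  expect_true(compute_quality_metrics(pen, thr)$flag_artifact)

  reg <- c(10L, 10L, 60L, 60L)
  loc <- apply_degradation(tile, degradation_spec("uniform_patch", 60,
                                                  region = reg))
  outside <- loc$rgb[100:128, 100:128, ]
  expect_equal(outside, tile$rgb[100:128, 100:128, ])

  expect_error(degradation_spec("vignetting", 1), "unknown")
  same <- apply_degradation(tile, degradation_spec("artifact", 6, seed = 3))
  same2 <- apply_degradation(tile, degradation_spec("artifact", 6, seed = 3))
  expect_identical(same, same2)
})

test_that("annotation extraction respects completeness and round-trips classes", {
  img <- mixed_slide(11, side = 256, block_side = 32)
  full <- generate_annotation_set(img$labels, completeness = 1, seed = 2)
  ras_full <- rasterize_annotations(full, 256, 256)
  # every labeled region of at least the minimum area has a polygon
  expect_gt(sum(ras_full > 0L) / sum(img$labels > 0L), 0.95)
  # rasterized polygons give back the source class almost everywhere
  agree <- mean(img$labels[ras_full > 0L] == ras_full[ras_full > 0L])
  expect_gte(agree, 0.95)

  half <- generate_annotation_set(img$labels, completeness = 0.5, seed = 2)
  ratio <- sum(rasterize_annotations(half, 256, 256) > 0L) /
    sum(img$labels > 0L)
  expect_gte(ratio, 0.4); expect_lte(ratio, 0.6)

  labs <- vapply(half$annotations, `[[`, "", "label")
  expect_true(all(labs %in% gleason_classes()))

  expect_identical(length(generate_annotation_set(matrix(0L, 64, 64), 1)), 0L)
  expect_error(generate_annotation_set(img$labels, completeness = 0), "0, 1")
})

test_that("annotation sets survive a GeoJSON round-trip", {
  img <- mixed_slide(13, side = 192, block_side = 48)
  ann <- generate_annotation_set(img$labels, completeness = 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_annotations_geojson(ann, path)
  back <- read_annotations_geojson(path)
  expect_identical(length(back), length(ann))
  expect_identical(vapply(back$annotations, `[[`, "", "label"),
                   vapply(ann$annotations, `[[`, "", "label"))
  r1 <- rasterize_annotations(ann, 192, 192)
  r2 <- rasterize_annotations(back, 192, 192)
  expect_identical(r1, r2)
})

test_that("image and label rasters round-trip through PNG", {
  img <- mixed_slide(17, side = 128, block_side = 32)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, p1)
  back <- read_image_png(p1)
  expect_equal(back$rgb, round(img$rgb), tolerance = 1e-8)
  write_label_png(img$labels, p2)
  expect_identical(read_label_png(p2), img$labels)
})
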