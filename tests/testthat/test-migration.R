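test_that("tissue masks separate background and survive scanner styles", {
  white <- labeled_image(array(250, c(64, 64, 3)))
  expect_false(any(tissue_mask(white)))

  img <- mixed_slide(31, side = 256, block_side = 64, background = 0.2,
                     fractions = c(GP3 = 0.2, GP4 = 0.2, benign = 0.2,
                                   stroma = 0.2, GP5 = 0))
  m <- tissue_mask(img)
  truth <- img$labels > 0L
  iou <- sum(m & truth) / sum(m | truth)
  expect_gte(iou, 0.9)

  ident <- apply_scanner_style(img, scanner_style_preset("identity"))
  expect_identical(tissue_mask(ident), m)
})

test_that("reference PDF is the per-image average of normalized histograms", {
  # constant tissue image: point mass at its intensity
  const <- labeled_image(array(100, c(64, 64, 3)))
  ref <- estimate_reference_pdf(list(const),
                                masks = list(matrix(TRUE, 64, 64)))
  expect_equal(ref$r[101], 1)
  expect_equal(sum(ref$g), 1)

  # two toy images: average of per-image PDFs, not pooled pixels
  a <- labeled_image(array(10, c(4, 4, 3)))
  b_rgb <- array(20, c(2, 2, 3)); b_rgb[1, 1, ] <- 40
  b <- labeled_image(b_rgb)
  ref2 <- estimate_reference_pdf(list(a, b),
                                 masks = list(matrix(TRUE, 4, 4),
                                              matrix(TRUE, 2, 2)))
  # hand-computed: image a -> all mass at 10; image b -> 3/4 at 20, 1/4 at 40
  expect_equal(ref2$r[11], 0.5)
  expect_equal(ref2$r[21], 0.375)
  expect_equal(ref2$r[41], 0.125)
  expect_equal(sum(ref2$b), 1)

  expect_error(estimate_reference_pdf(list(a),
                                      masks = list(matrix(FALSE, 4, 4))),
               "empty")
})

test_that("histogram intersection behaves as a bounded symmetric overlap", {
  p <- list(r = c(0.5, 0.5, rep(0, 254)), g = c(0.5, 0.5, rep(0, 254)),
            b = c(0.5, 0.5, rep(0, 254)))
  q <- list(r = c(0.25, 0.25, 0.5, rep(0, 253)),
            g = c(0.25, 0.25, 0.5, rep(0, 253)),
            b = c(0.25, 0.25, 0.5, rep(0, 253)))
  expect_equal(histogram_intersection(p, p)$mean, 1)
  expect_equal(histogram_intersection(p, q)$mean, 0.5)
  expect_equal(histogram_intersection(p, q)$r,
               histogram_intersection(q, p)$r)
  disjoint <- list(r = c(rep(0, 128), rep(1 / 128, 128)),
                   g = c(rep(0, 128), rep(1 / 128, 128)),
                   b = c(rep(0, 128), rep(1 / 128, 128)))
  other <- list(r = c(rep(1 / 128, 128), rep(0, 128)),
                g = c(rep(1 / 128, 128), rep(0, 128)),
                b = c(rep(1 / 128, 128), rep(0, 128)))
  expect_equal(histogram_intersection(disjoint, other)$mean, 0)
})

test_that("migration is monotone, near-identity on self, and label-preserving", {
  img <- mixed_slide(33, side = 256, block_side = 64)
  ref <- estimate_reference_pdf(list(img))
  self <- migrate_image(img, ref)
  expect_identical(self$labels, img$labels)
  hi <- histogram_intersection(estimate_reference_pdf(list(self)), ref)
  expect_gte(hi$mean, 0.99)
  # rank order of tissue intensities is preserved per channel
  m <- tissue_mask(img)
  for (ch in 1:3) {
    v0 <- img$rgb[, , ch][m]; v1 <- self$rgb[, , ch][m]
    ord <- order(v0)
    expect_true(all(diff(v1[ord]) >= 0))
  }
})

test_that("migration recovers the reference appearance from a scanner shift", {
  ref_imgs <- lapply(101:104, function(s) mixed_slide(s, 256, 64))
  ref <- estimate_reference_pdf(ref_imgs)
  img <- mixed_slide(41, side = 256, block_side = 64)
  for (preset in c("scannerB", "scannerC", "scannerD")) {
    sh <- apply_scanner_style(img, scanner_style_preset(preset))
    before <- histogram_intersection(estimate_reference_pdf(list(sh)),
                                     ref)$mean
    mig <- migrate_image(sh, ref)
    after <- histogram_intersection(estimate_reference_pdf(list(mig)),
                                    ref)$mean
    expect_gt(after, before)
    # idempotence: a second migration moves channel means by < 1 unit
    mig2 <- migrate_image(mig, ref)
    shift <- max(abs(apply(mig$rgb, 3, mean) - apply(mig2$rgb, 3, mean)))
    expect_lt(shift, 1)
  }
})

test_that("a constant channel maps to the reference median with a warning", {
  img <- mixed_slide(35, side = 128, block_side = 32)
  ref <- estimate_reference_pdf(list(img))
  flat <- img
  flat$rgb[, , 2] <- 77
  expect_warning(out <- migrate_image(flat, ref), "constant channel")
  med <- which(cumsum(ref$g) >= 0.5)[1] - 1L
  expect_lte(max(abs(out$rgb[, , 2] - med)), 1)
})

test_that("channel-mean compactness shrinks after migration", {
  base <- mixed_slide(37, side = 192, block_side = 48)
  styles <- list(scanner_style_preset("identity"),
                 scanner_style_preset("scannerC"),
                 scanner_style_preset("scannerD"))
  imgs <- lapply(styles, function(s) apply_scanner_style(base, s))
  expect_equal(channel_mean_summary(list(base, base))$compactness, 0)
  pre <- channel_mean_summary(imgs)
  expect_equal(channel_mean_summary(rev(imgs))$compactness, pre$compactness)
  ref <- estimate_reference_pdf(lapply(101:104, function(s)
    mixed_slide(s, 192, 48)))
  post <- channel_mean_summary(lapply(imgs, migrate_image, ref = ref))
  expect_lt(post$compactness, pre$compactness)
})

test_that("reference PDFs round-trip through JSON", {
  ref <- estimate_reference_pdf(list(mixed_slide(39, 128, 32)))
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_pdf(ref, path)
  back <- read_reference_pdf(path)
  expect_equal(back$r, ref$r)
  expect_equal(back$b, ref$b)
  expect_s3_class(back, "reference_pdf")
})
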