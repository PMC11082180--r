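# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Standard mixed-tissue composition used across fixture slides.
mixed_fractions <- c(GP3 = 0.25, GP4 = 0.2, GP5 = 0.1,
                     benign = 0.25, stroma = 0.2)

mixed_slide <- function(seed, side = 384L, block_side = 96L,
                        fractions = mixed_fractions, background = 0) {
  generate_tissue_image(tissue_layout_spec(
    side, fractions, background_fraction = background,
    seed = seed, block_side = block_side))
}

# Pure-class patches: one slide per (class, seed), windows extracted at the
# 101 px test scale. Split by slide seed, never by patch.
class_patches <- function(seeds, image_side = 256L, window_side = 101L) {
  out <- list()
  for (cls in gleason_classes()) {
    for (sd in seeds) {
      img <- generate_tissue_image(tissue_layout_spec(
        image_side, stats::setNames(1, cls), 0,
        seed = sd + 100L * class_code(cls)))
      out <- c(out, extract_patches(img, img$labels, patch_scale(window_side)))
    }
  }
  out
}

fixture_train_patches <- function() memo("train_patches", class_patches(1:4))
fixture_test_patches <- function() memo("test_patches", class_patches(8:9))

fixture_classifier <- function() memo("classifier", {
  train_patch_classifier(fixture_train_patches())
})

patch_labels <- function(patches) vapply(patches, `[[`, "", "label")

# Independent gather-based fusion oracle: recomputes every pixel's fused
# label from the covering-window set (contiguous start ranges + prefix sums
# over the window grid), as opposed to the package's scatter accumulation.
oracle_fuse <- function(acc, mode) {
  wins <- acc$windows; probs <- acc$window_probs; side <- acc$side
  h <- nrow(acc$coverage); w <- ncol(acc$coverage)
  rs <- sort(unique(wins$r0)); cs <- sort(unique(wins$c0))
  wi <- match(wins$r0, rs); wj <- match(wins$c0, cs)
  nr <- length(rs); nc <- length(cs)
  onehot <- matrix(0, nrow(wins), 5L)
  onehot[cbind(seq_len(nrow(wins)), max.col(probs, ties.method = "first"))] <- 1

  # covering start-range per pixel coordinate (starts are 1-based origins)
  range_of <- function(pos, starts) {
    lo <- findInterval(pos - side, starts) + 1L     # first start > pos - side
    hi <- findInterval(pos, starts)                 # last start <= pos
    cbind(lo, hi)
  }
  rr <- range_of(seq_len(h), rs)
  cr <- range_of(seq_len(w), cs)

  # prefix sums over the window grid, one plane per class
  prefix <- function(vals) {
    G <- matrix(0, nr + 1L, nc + 1L)
    M <- matrix(0, nr, nc)
    M[cbind(wi, wj)] <- vals
    G[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
    G
  }
  plane_sum <- function(G) {
    # sum over window-index rectangle [rlo..rhi] x [clo..chi] per pixel
    A <- G[rr[, 2] + 1L, cr[, 2] + 1L, drop = FALSE]
    B <- G[rr[, 1], cr[, 2] + 1L, drop = FALSE]
    C <- G[rr[, 2] + 1L, cr[, 1], drop = FALSE]
    D <- G[rr[, 1], cr[, 1], drop = FALSE]
    A - B - C + D
  }
  score <- array(0, c(h, w, 5L)); votes <- array(0, c(h, w, 5L))
  for (cl in 1:5) {
    score[, , cl] <- plane_sum(prefix(probs[, cl]))
    votes[, , cl] <- plane_sum(prefix(onehot[, cl]))
  }
  cov <- plane_sum(prefix(rep(1, nrow(wins))))

  n <- h * w
  K1 <- matrix(0, n, 5L); K2 <- matrix(0, n, 5L)
  for (cl in 1:5) {
    K2[, cl] <- as.vector(score[, , cl] / pmax(cov, 1))
    K1[, cl] <- if (mode == "max_votes") as.vector(votes[, , cl]) else K2[, cl]
  }
  rmax <- function(M) do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))
  cand1 <- K1 == rmax(K1)
  M2 <- ifelse(cand1, K2, -Inf)
  cand2 <- M2 == rmax(M2)
  lab <- integer(n)
  for (cl in order(severity_rank())) lab[cand2[, cl]] <- cl
  out <- matrix(lab, h, w)
  out[cov == 0] <- 0L
  out
}

# Minimal stand-in classifier emitting seeded random probabilities; used to
# exercise fusion with arbitrary per-window predictions.
random_prob_classifier <- function(seed) {
  structure(list(seed = seed), class = "random_prob_classifier")
}

predict.random_prob_classifier <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else length(newdata)
  set.seed(object$seed + n)
  P <- matrix(stats::rexp(n * 5L), n, 5L)
  P <- P / rowSums(P)
  colnames(P) <- gleason_classes()
  P
}
registerS3method("predict", "random_prob_classifier",
                 predict.random_prob_classifier)
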