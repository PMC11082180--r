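# Internal numeric helpers shared across modules.

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded generators never perturb user code.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Luma weights as in ITU-R BT.601.
rgb_to_gray <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Separable Gaussian blur with replicate padding (shift-and-add; exact,
# deterministic, and valid for images smaller than the kernel support).
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  K <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-K, K), sd = sigma)
  k <- k / sum(k)
  pad <- function(n) c(rep(1L, K), seq_len(n), rep(n, K))
  h <- nrow(mat); w <- ncol(mat)
  m <- mat[pad(h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k))
    out <- out + k[i] * m[i:(i + h - 1L), , drop = FALSE]
  m <- out[, pad(w), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k))
    out <- out + k[i] * m[, i:(i + w - 1L), drop = FALSE]
  out
}

# 3x3 Laplacian (4-neighbour) with replicate padding.
laplacian <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  up    <- mat[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- mat[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  left  <- mat[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- mat[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
  4 * mat - up - down - left - right
}

# Exact area-average resize via bilinear interpolation of the integral image
# (the integral of a cell-wise constant image is piecewise bilinear, so the
# averages over fractional rectangles are computed exactly).
resize_area <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == out_h && w == out_w) return(mat)
  II <- matrix(0, h + 1L, w + 1L)
  II[-1L, -1L] <- t(apply(apply(mat, 2L, cumsum), 1L, cumsum))
  ii_at <- function(ys, xs) {
    # bilinear sample of II at fractional (ys, xs); returns length(ys) x length(xs)
    y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
    fy <- ys - y0; fx <- xs - x0
    iy <- as.integer(y0) + 1L; ix <- as.integer(x0) + 1L
    a <- II[iy, ix, drop = FALSE];        b <- II[iy, ix + 1L, drop = FALSE]
    c2 <- II[iy + 1L, ix, drop = FALSE];  d <- II[iy + 1L, ix + 1L, drop = FALSE]
    wy1 <- 1 - fy; wx1 <- 1 - fx
    outer(wy1, wx1) * a + outer(wy1, fx) * b + outer(fy, wx1) * c2 + outer(fy, fx) * d
  }
  ys <- seq(0, h, length.out = out_h + 1L)
  xs <- seq(0, w, length.out = out_w + 1L)
  F <- ii_at(ys, xs)
  n1 <- seq_len(out_h); n2 <- seq_len(out_w)
  num <- F[n1 + 1L, n2 + 1L] - F[n1, n2 + 1L] - F[n1 + 1L, n2] + F[n1, n2]
  num / ((h / out_h) * (w / out_w))
}

resize_area_rgb <- function(rgb, out_h, out_w) {
  out <- array(0, c(out_h, out_w, 3L))
  # clip away float residue from the prefix-sum differences
  for (ch in 1:3) out[, , ch] <- clip255(resize_area(rgb[, , ch], out_h, out_w))
  out
}

# Mean block variance map: variance of gray values within non-overlapping
# block_side x block_side blocks (truncates ragged edges).
block_variances <- function(mat, block_side) {
  h <- (nrow(mat) %/% block_side) * block_side
  w <- (ncol(mat) %/% block_side) * block_side
  if (h < block_side || w < block_side) return(stats::var(as.vector(mat)))
  m <- mat[seq_len(h), seq_len(w), drop = FALSE]
  bi <- rep(seq_len(h %/% block_side), each = block_side)
  bj <- rep(seq_len(w %/% block_side), each = block_side)
  idx <- outer(bi, (bj - 1L) * max(bi), `+`)
  n <- block_side^2
  s1 <- tapply(m, idx, sum)
  s2 <- tapply(m^2, idx, sum)
  as.numeric((s2 - s1^2 / n) / (n - 1))
}
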