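#' Baseline patch classifier
#'
#' A deliberately lightweight stand-in for a CNN patch classifier: a fixed,
#' hand-designed feature map (color histograms plus texture statistics)
#' followed by a weighted multinomial-logistic "head" over the five tissue
#' classes. Per-sample class weights scale the loss, mirroring a weighted
#' classification layer used to rebalance skewed patch counts. The split
#' into a frozen feature map and a convex linear head is what makes
#' head-only incremental updating (\code{\link{incremental_update}})
#' well-posed: the anchored refit has a unique optimum, so sequential and
#' combined updates agree. Any external model exposing class probabilities
#' can replace it behind the same \code{predict} interface.
#'
#' @name patch_classifier
NULL

# Fixed feature map: 8-bin per-channel histograms, channel moments, gradient
# and Laplacian energy, local-variance statistics, hue/saturation summary,
# near-white and dark fractions. 41 dimensions.
patch_features <- function(rgb) {
  gray <- rgb_to_gray(rgb)
  f <- numeric(0)
  for (ch in 1:3) {
    v <- as.vector(rgb[, , ch])
    f <- c(f, tabulate(pmin(floor(v / 32), 7) + 1, nbins = 8) / length(v),
           mean(v) / 255, stats::sd(v) / 255)
  }
  lap <- laplacian(gray)
  dx <- gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE]
  dy <- gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE]
  gmag <- mean(abs(dx)) + mean(abs(dy))
  bv <- block_variances(gray, 16L)
  r <- as.vector(rgb[, , 1]); g <- as.vector(rgb[, , 2])
  b <- as.vector(rgb[, , 3])
  v <- pmax(r, g, b); mn <- pmin(r, g, b)
  s <- ifelse(v > 0, (v - mn) / v, 0)
  c(f,
    log10(stats::var(as.vector(lap)) + 1e-8),
    gmag / 255,
    mean(abs(dx) > 20),
    log10(mean(bv) + 1e-8),
    log10(stats::sd(bv) + 1e-8),
    stats::sd(bv) / (mean(bv) + 1e-8) / 10,
    mean(s), stats::sd(s),
    mean(v >= 240 & s < 0.08),
    mean(v < 115))
}

features_of <- function(patches) {
  t(vapply(patches, function(p) patch_features(p$pixels),
           numeric(length(patch_features(patches[[1]]$pixels)))))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Weighted multinomial NLL + penalty; X has intercept column. W is K x d.
# anchor: NULL (ridge toward 0, intercept unpenalized) or a K x d matrix.
mlr_obj <- function(wvec, X, Y, sw, lambda, anchor, K) {
  W <- matrix(wvec, K)
  P <- softmax_rows(X %*% t(W))
  nll <- -sum(sw * log(pmax(rowSums(Y * P), 1e-300))) / sum(sw)
  pen <- if (is.null(anchor)) {
    Wp <- W; Wp[, 1] <- 0
    lambda * sum(Wp^2)
  } else lambda * sum((W - anchor)^2)
  nll + pen
}

mlr_grad <- function(wvec, X, Y, sw, lambda, anchor, K) {
  W <- matrix(wvec, K)
  P <- softmax_rows(X %*% t(W))
  G <- t((P - Y) * (sw / sum(sw))) %*% X
  if (is.null(anchor)) {
    Wp <- W; Wp[, 1] <- 0
    G <- G + 2 * lambda * Wp
  } else G <- G + 2 * lambda * (W - anchor)
  as.vector(G)
}

fit_head <- function(X, y_idx, sw, lambda, anchor = NULL, W0 = NULL,
                     K = 5L) {
  Y <- matrix(0, nrow(X), K)
  Y[cbind(seq_len(nrow(X)), y_idx)] <- 1
  W0 <- W0 %||% matrix(0, K, ncol(X))
  fit <- stats::optim(as.vector(W0), mlr_obj, mlr_grad, X = X, Y = Y,
                      sw = sw, lambda = lambda, anchor = anchor, K = K,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  matrix(fit$par, K)
}

#' Train the baseline patch classifier
#'
#' @param patches List of \code{labeled_patch}es (at least two classes).
#' @param weights Optional named class weights (e.g. from
#'   \code{\link{compute_class_weights}}); default all 1. Weights scale each
#'   sample's loss contribution.
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   recorded and used for any resampling by callers).
#' @param lambda Ridge penalty on the head coefficients.
#' @return A \code{patch_classifier} with a \code{\link[stats]{predict}}
#'   method (\code{type = "prob"} or \code{"class"}).
#' @export
train_patch_classifier <- function(patches, weights = NULL, seed = 1L,
                                   lambda = 1e-3) {
  labels <- vapply(patches, `[[`, "", "label")
  y <- class_code(labels)
  if (length(unique(y)) < 2L)
    stop("training requires at least two classes", call. = FALSE)
  X <- features_of(patches)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd); scale[scale < 1e-9] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, center), 2, scale, "/"))
  w <- rep(1, length(y))
  if (!is.null(weights)) {
    miss <- setdiff(unique(labels), names(weights))
    if (length(miss)) stop("no weight for class: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    w <- unname(weights[labels])
  }
  W <- fit_head(Xs, y, w, lambda)
  structure(list(classes = gleason_classes(), W = W, center = center,
                 scale = scale, lambda = lambda, seed = as.integer(seed),
                 update_buffer = NULL, W_base = W,
                 feature_version = 1L),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  nb <- if (is.null(x$update_buffer)) 0L else nrow(x$update_buffer$X)
  cat(sprintf(paste0("<patch_classifier> %d features -> %d classes ",
                     "(multinomial head; %d buffered corrections)\n"),
              length(x$center), length(x$classes), nb))
  invisible(x)
}

prepare_features <- function(object, newdata) {
  X <- if (is.matrix(newdata)) newdata
       else if (is.list(newdata) && !inherits(newdata, "labeled_patch"))
         features_of(newdata)
       else features_of(list(newdata))
  cbind(1, sweep(sweep(X, 2, object$center), 2, object$scale, "/"))
}

#' Predict class probabilities for patches
#'
#' @param object A \code{patch_classifier}.
#' @param newdata A \code{labeled_patch}, a list of them, or a raw feature
#'   matrix.
#' @param type \code{"prob"} for the class-probability matrix, \code{"class"}
#'   for hard labels.
#' @param ... Unused.
#' @export
predict.patch_classifier <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  P <- softmax_rows(prepare_features(object, newdata) %*% t(object$W))
  colnames(P) <- object$classes
  if (type == "prob") P else object$classes[max.col(P, ties.method = "first")]
}

#' Incrementally update a classifier from corrected patches
#'
#' Head-only learning from pathologist corrections: the feature map stays
#' frozen and only the linear head is refit. New corrections are appended to
#' the classifier's correction buffer and the head is refit on the buffer
#' with a quadratic anchor toward the base head, warm-started from the
#' current parameters. The original training patches are not needed, and
#' because the anchored refit is strictly convex, two sequential updates
#' give the same head as one combined update.
#'
#' @param classifier A trained \code{patch_classifier}.
#' @param patches Corrected \code{labeled_patch}es (possibly empty: the
#'   classifier is returned unchanged).
#' @param seed Integer seed (recorded; the refit is deterministic).
#' @param alpha Anchor strength toward the base head.
#' @return The updated \code{patch_classifier}.
#' @export
incremental_update <- function(classifier, patches, seed = 1L,
                               alpha = 5e-3) {
  stopifnot(inherits(classifier, "patch_classifier"))
  if (!length(patches)) return(classifier)
  labels <- vapply(patches, `[[`, "", "label")
  y <- class_code(labels)  # errors on labels outside the vocabulary
  Xs <- prepare_features(classifier, patches)
  buf <- classifier$update_buffer
  buf <- list(X = rbind(buf$X, Xs), y = c(buf$y, y))
  W <- fit_head(buf$X, buf$y, rep(1, length(buf$y)), alpha,
                anchor = classifier$W_base, W0 = classifier$W)
  classifier$W <- W
  classifier$update_buffer <- buf
  classifier$seed <- as.integer(seed)
  classifier
}

#' Serialize a classifier to JSON
#'
#' Text-based round-trip of the fitted head, standardization and correction
#' buffer, with a format version tag.
#'
#' @param classifier A \code{patch_classifier}.
#' @param path File path.
#' @name classifier_io
NULL

#' @rdname classifier_io
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "patch_classifier"))
  x <- unclass(classifier)
  x$format <- "wsigrade-classifier-1"
  jsonlite::write_json(x, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname classifier_io
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "wsigrade-classifier-1"))
    stop("unrecognized classifier format", call. = FALSE)
  buf <- x$update_buffer
  buf <- if (!is.null(buf) && length(buf))
    list(X = as.matrix(buf$X), y = as.integer(buf$y)) else NULL
  structure(list(classes = x$classes, W = x$W, center = x$center,
                 scale = x$scale, lambda = x$lambda, seed = x$seed,
                 update_buffer = buf, W_base = x$W_base,
                 feature_version = x$feature_version),
            class = "patch_classifier")
}
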