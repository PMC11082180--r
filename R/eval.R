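#' Grading evaluation
#'
#' Annotation-level and slide-level evaluation: majority-area reconciliation
#' of pixel predictions against annotated instances, one-vs-rest
#' classification metrics with a malignant/non-malignant binary grouping,
#' Gleason score and Grade Group derivation from predicted pattern areas,
#' quadratic weighted kappa for observer agreement, and timing summaries for
#' annotation-efficiency comparisons.
#'
#' @name grading_eval
NULL

MALIGNANT <- c("GP3", "GP4", "GP5")

#' Majority-area label for an annotated instance
#'
#' For an instance polygon, the reconciled label is the predicted class
#' covering the largest pixel area inside it; exact area ties go to the more
#' severe class. Pixels with code 0 are unscored; an instance that is fully
#' unscored is an error, and the unscored fraction is returned so callers
#' can apply the >50%-unscored exclusion guard.
#'
#' @param pred Integer predicted label raster (0 = unscored).
#' @param polygon Two-column \code{(row, col)} boundary matrix (or a logical
#'   mask of the instance).
#' @return List: \code{label}, \code{areas} (named pixel counts),
#'   \code{unscored_fraction}.
#' @export
reconcile_instance_label <- function(pred, polygon) {
  msk <- if (is.matrix(polygon) && is.logical(polygon)) polygon
         else rasterize_polygon(polygon, nrow(pred), ncol(pred))
  vals <- pred[msk]
  if (!length(vals)) stop("empty instance polygon", call. = FALSE)
  unscored <- mean(vals == 0L)
  vals <- vals[vals > 0L]
  if (!length(vals)) stop("instance polygon is fully unscored", call. = FALSE)
  areas <- tabulate(vals, nbins = 5L)
  names(areas) <- gleason_classes()
  top <- max(areas)
  cand <- which(areas == top)
  pick <- cand[which.max(severity_rank()[cand])]
  list(label = gleason_classes()[pick], areas = areas,
       unscored_fraction = unscored)
}

binary_group <- function(labels) {
  ifelse(labels %in% MALIGNANT, "Malignant", "Non-malignant")
}

#' Classification metrics table
#'
#' Per-class one-vs-rest precision, sensitivity and F1 with their macro
#' (arithmetic-mean) F1, plus binary metrics after grouping GP3/GP4/GP5 as
#' "Malignant" and benign/stroma as "Non-malignant": sensitivity,
#' specificity, PPV and NPV.
#'
#' @param gt,pred Equal-length character vectors of class labels.
#' @return A \code{metric_table}: list with \code{per_class} (data.frame),
#'   \code{macro_f1} and \code{binary}.
#' @export
classification_metrics <- function(gt, pred) {
  stopifnot(length(gt) == length(pred))
  classes <- gleason_classes()
  present <- classes[classes %in% union(gt, pred)]
  absent <- setdiff(classes, present)
  if (length(absent))
    warning("classes absent from both gt and pred excluded from macro mean: ",
            paste(absent, collapse = ", "))
  per <- do.call(rbind, lapply(present, function(cl) {
    tp <- sum(gt == cl & pred == cl)
    fp <- sum(gt != cl & pred == cl)
    fn <- sum(gt == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + sensitivity > 0)
      2 * precision * sensitivity / (precision + sensitivity) else 0
    data.frame(class = cl, n_gt = tp + fn, precision = precision,
               sensitivity = sensitivity, f1 = f1)
  }))
  gtb <- binary_group(gt); prb <- binary_group(pred)
  tp <- sum(gtb == "Malignant" & prb == "Malignant")
  tn <- sum(gtb == "Non-malignant" & prb == "Non-malignant")
  fp <- sum(gtb == "Non-malignant" & prb == "Malignant")
  fn <- sum(gtb == "Malignant" & prb == "Non-malignant")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(per_class = per, macro_f1 = mean(per$f1),
                 binary = list(sensitivity = safe(tp, tp + fn),
                               specificity = safe(tn, tn + fp),
                               ppv = safe(tp, tp + fp),
                               npv = safe(tn, tn + fn))),
            class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat("<metric_table>\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("macro F1: %.4f\n", x$macro_f1))
  b <- x$binary
  cat(sprintf("binary: sens %.3f spec %.3f PPV %.3f NPV %.3f\n",
              b$sensitivity, b$specificity, b$ppv, b$npv))
  invisible(x)
}

#' Gleason Grade Group from primary and secondary patterns
#'
#' Grade Groups partition Gleason scores: GG1 = score 6, GG2 = 3+4,
#' GG3 = 4+3, GG4 = score 8, GG5 = score 9 or 10.
#'
#' @param primary,secondary Gleason patterns in \{3, 4, 5\}.
#' @return A \code{grade_group}: list with \code{group}, \code{primary},
#'   \code{secondary}, \code{gleason_score}.
#' @export
#' @examples
#' grade_group(3, 4)$group  # 2
grade_group <- function(primary, secondary) {
  stopifnot(primary %in% 3:5, secondary %in% 3:5)
  score <- primary + secondary
  group <- if (score == 6) 1L
    else if (score == 7 && primary == 3) 2L
    else if (score == 7) 3L
    else if (score == 8) 4L
    else 5L
  structure(list(group = group, primary = as.integer(primary),
                 secondary = as.integer(secondary),
                 gleason_score = as.integer(score)),
            class = "grade_group")
}

#' @export
print.grade_group <- function(x, ...) {
  if (is.na(x$group)) cat("<grade_group> benign (no malignant pattern)\n")
  else cat(sprintf("<grade_group> GG%d (Gleason %d + %d = %d)\n", x$group,
                   x$primary, x$secondary, x$gleason_score))
  invisible(x)
}

#' Slide-level Gleason score and Grade Group from a prediction raster
#'
#' The primary pattern is the malignant pattern (GP3/GP4/GP5) with the
#' largest predicted area; the secondary is the next-largest pattern whose
#' area is at least \code{secondary_min_fraction} of the total malignant
#' area (else the primary is doubled). A raster with no malignant pixels
#' maps to no group (benign slide).
#'
#' @param pred Integer predicted label raster.
#' @param secondary_min_fraction Area floor for the secondary pattern as a
#'   fraction of the malignant area (clinical convention 0.05).
#' @return A \code{grade_group} (with \code{group = NA} for a benign slide).
#' @export
slide_gleason <- function(pred, secondary_min_fraction = 0.05) {
  areas <- vapply(3:5, function(p)
    sum(pred == class_code(paste0("GP", p))), 0L)
  names(areas) <- 3:5
  total <- sum(areas)
  if (total == 0L)
    return(structure(list(group = NA_integer_, primary = NA_integer_,
                          secondary = NA_integer_,
                          gleason_score = NA_integer_),
                     class = "grade_group"))
  ord <- order(areas, decreasing = TRUE)
  primary <- as.integer(names(areas)[ord[1]])
  secondary <- primary
  for (k in ord[-1]) {
    if (areas[k] >= secondary_min_fraction * total) {
      secondary <- as.integer(names(areas)[k]); break
    }
  }
  grade_group(primary, secondary)
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement between two raters over \code{k} ordered
#' categories, penalizing disagreements by squared category distance:
#' \code{kappa = 1 - sum(w * O) / sum(w * E)} with
#' \code{w_ij = (i - j)^2 / (k - 1)^2}, \code{O} the observed joint
#' proportions and \code{E} the outer product of the marginals.
#'
#' @param labels_a,labels_b Equal-length integer vectors with values in
#'   \code{1..k}.
#' @param k Number of categories (>= 2).
#' @return Kappa in \code{[-1, 1]}; 1 when the raters agree perfectly.
#' @export
quadratic_weighted_kappa <- function(labels_a, labels_b, k) {
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 2,
            all(labels_a %in% seq_len(k)), all(labels_b %in% seq_len(k)))
  O <- table(factor(labels_a, seq_len(k)), factor(labels_b, seq_len(k)))
  O <- O / sum(O)
  marg_a <- rowSums(O); marg_b <- colSums(O)
  E <- outer(marg_a, marg_b)
  W <- outer(seq_len(k), seq_len(k), function(i, j) (i - j)^2) / (k - 1)^2
  den <- sum(W * E)
  if (den == 0) return(1)   # both raters constant and identical
  1 - sum(W * O) / den
}

#' Timing summary for two annotation conditions
#'
#' Compares per-item times under a "before" condition (e.g. fully manual
#' annotation) and an "after" condition (e.g. semi-automatic annotation):
#' means, fold speedup \code{mean_before / mean_after} (1 decimal), percent
#' reduction \code{100 * (1 - mean_after / mean_before)} (integer), and a
#' paired two-sided t-test p-value when the conditions pair up.
#'
#' @param times_before,times_after Positive per-item times in seconds.
#' @return A \code{timing_summary}: means, \code{fold_speedup},
#'   \code{percent_reduction}, and \code{p_value} (NA, with a warning, when
#'   lengths differ or are too short to pair).
#' @export
#' @examples
#' timing_summary(1267, 508)$fold_speedup        # 2.5
#' timing_summary(c(148, 147), 84)$percent_reduction  # 43
timing_summary <- function(times_before, times_after) {
  if (any(times_before <= 0) || any(times_after <= 0))
    stop("times must be positive", call. = FALSE)
  mb <- mean(times_before); ma <- mean(times_after)
  p <- NA_real_
  if (length(times_before) == length(times_after) &&
      length(times_before) >= 2) {
    p <- tryCatch(stats::t.test(times_before, times_after,
                                paired = TRUE)$p.value,
                  error = function(e) NA_real_)  # constant differences
  } else if (length(times_before) != length(times_after)) {
    warning("unequal condition lengths; paired p-value omitted")
  }
  structure(list(mean_before = mb, mean_after = ma,
                 fold_speedup = round(mb / ma, 1),
                 percent_reduction = as.integer(round(100 * (1 - ma / mb))),
                 p_value = p),
            class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  cat(sprintf(paste0("<timing_summary> %.1f s -> %.1f s: %.1fx speedup, ",
                     "%d%% reduction"), x$mean_before, x$mean_after,
              x$fold_speedup, x$percent_reduction))
  if (!is.na(x$p_value)) cat(sprintf(" (paired t-test p = %.2g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Annotation-level evaluation of a prediction raster
#'
#' Reconciles every annotated instance against the prediction
#' (majority-area rule), applies the >50%-unscored exclusion guard, and
#' computes the metric table.
#'
#' @param pred Integer predicted label raster.
#' @param ann Ground-truth \code{annotation_set}.
#' @param max_unscored Instances with a larger unscored fraction are
#'   excluded.
#' @return List: \code{instances} (data.frame gt/pred label per instance)
#'   and \code{metrics} (\code{\link{classification_metrics}}).
#' @export
evaluate_annotations <- function(pred, ann, max_unscored = 0.5) {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- list()
  for (a in ann$annotations) {
    rec <- tryCatch(reconcile_instance_label(pred, a$polygon),
                    error = function(e) NULL)
    if (is.null(rec) || rec$unscored_fraction > max_unscored) next
    rows[[length(rows) + 1L]] <-
      data.frame(gt = a$label, pred = rec$label,
                 unscored = rec$unscored_fraction)
  }
  if (!length(rows)) stop("no scorable instances", call. = FALSE)
  inst <- do.call(rbind, rows)
  list(instances = inst,
       metrics = classification_metrics(inst$gt, inst$pred))
}
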