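#' ROC curve of a saliency map against ground truth
#'
#' Treats the saliency map as a pixel classifier: for every threshold t in
#' the set of unique saliency values (plus +Inf), a pixel is called salient
#' when `S >= t`. TPR is the fraction of ground-truth positive pixels called
#' salient, FPR the fraction of negatives. The returned points start at
#' (0, 0) and end at (1, 1) and are non-decreasing in both coordinates.
#' Ties share a single threshold (all tied pixels switch together).
#'
#' A continuous ground-truth map is binarised at `gt_threshold`
#' (strictly greater than; default 0).
#'
#' @param sm Saliency matrix (or vector).
#' @param gt Ground truth: logical/0-1 mask or continuous map, same size.
#' @param gt_threshold Binarisation threshold for continuous ground truth.
#' @return A data frame with columns `fpr` and `tpr`.
#' @export
roc_curve <- function(sm, gt, gt_threshold = 0) {
  s <- as.vector(sm)
  g <- .binarize_gt(gt, gt_threshold)
  if (length(s) != length(g)) stop("saliency map and ground truth differ in size")
  np <- sum(g); nn <- sum(!g)
  if (np == 0) stop("ground truth has no positive pixels")
  if (nn == 0) stop("ground truth has no negative pixels")
  ord <- order(s, decreasing = TRUE)
  sv <- s[ord]; gv <- g[ord]
  last <- !duplicated(sv, fromLast = TRUE)   # last occurrence of each value
  tp <- cumsum(gv)[last]
  fp <- cumsum(!gv)[last]
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

.binarize_gt <- function(gt, threshold = 0) {
  g <- as.vector(gt)
  if (!all(is.finite(g))) stop("non-finite ground truth")
  if (is.logical(g)) return(g)
  g > threshold
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over FPR. A map identical to the
#' ground-truth mask scores 1; a constant map scores 0.5 (the chance
#' diagonal). AUC is invariant under any strictly increasing transform of
#' the saliency values.
#'
#' @param sm Saliency matrix, or a ROC data frame from [roc_curve()].
#' @param gt Ground truth (ignored when `sm` is already a ROC curve).
#' @param gt_threshold See [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(sm, gt = NULL, gt_threshold = 0) {
  roc <- if (is.data.frame(sm) && all(c("fpr", "tpr") %in% names(sm))) sm
         else roc_curve(sm, gt, gt_threshold)
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' Linear correlation coefficient between a saliency map and ground truth
#'
#' Pearson correlation over all pixels, for continuous fixation maps as well
#' as binary masks. Values near +1/-1 indicate a (anti-)linear
#' relationship.
#'
#' @param sm Saliency matrix.
#' @param gt_map Ground-truth map, same size.
#' @return CC in \[-1, 1\].
#' @export
cc_score <- function(sm, gt_map) {
  s <- as.vector(sm); g <- as.vector(gt_map)
  if (length(s) != length(g)) stop("saliency map and ground truth differ in size")
  if (stats::sd(s) == 0) stop("CC undefined: saliency map has zero variance")
  if (stats::sd(g) == 0) stop("CC undefined: ground truth has zero variance")
  stats::cor(s, g)
}

#' Normalized scanpath saliency
#'
#' The saliency map is standardised to zero mean and unit standard deviation
#' over all pixels; NSS is the mean standardised saliency over the fixated
#' (ground-truth positive) pixels. Scores above 1 mean fixated locations are
#' substantially more salient than average. Invariant to affine rescaling of
#' the map.
#'
#' @param sm Saliency matrix.
#' @param fixations Binary fixation mask (continuous maps are binarised at
#'   `gt_threshold`).
#' @param gt_threshold Binarisation threshold.
#' @return The NSS score.
#' @export
nss_score <- function(sm, fixations, gt_threshold = 0) {
  s <- as.vector(sm)
  f <- .binarize_gt(fixations, gt_threshold)
  if (length(s) != length(f)) stop("saliency map and fixations differ in size")
  if (sum(f) < 1) stop("no fixated pixels")
  sdv <- stats::sd(s)
  if (sdv == 0) stop("NSS undefined: saliency map has zero variance")
  z <- (s - mean(s)) / sdv
  mean(z[f])
}

#' Evaluate a saliency map against ground truth
#'
#' Convenience wrapper computing the ROC curve, AUC, CC and NSS for one
#' (map, ground truth) pair.
#'
#' @param sm Saliency matrix.
#' @param gt Ground truth mask or map.
#' @param gt_threshold Binarisation threshold for ROC/NSS.
#' @return A list of class `"v1_eval"` with `roc`, `auc`, `cc`, `nss`,
#'   `n_pos`.
#' @export
evaluate_saliency <- function(sm, gt, gt_threshold = 0) {
  roc <- roc_curve(sm, gt, gt_threshold)
  structure(list(roc = roc, auc = auc_score(roc),
                 cc = tryCatch(cc_score(sm, gt), error = function(e) NA_real_),
                 nss = nss_score(sm, gt, gt_threshold),
                 n_pos = sum(.binarize_gt(gt, gt_threshold))),
            class = "v1_eval")
}

#' @export
print.v1_eval <- function(x, ...) {
  cat(sprintf("saliency evaluation: AUC %.4f | CC %.4f | NSS %.4f (%d positive pixels)\n",
              x$auc, x$cc, x$nss, x$n_pos))
  invisible(x)
}
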