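#' Voxelwise confusion counts between two masks
#'
#' @param pred,gt [seg_mask()] objects (or bare binary arrays) of identical
#'   shape.
#' @return Named numeric vector `(tp, fp, fn, tn)`; the four sum to the voxel
#'   count.
#' @export
confusion_counts <- function(pred, gt) {
  p <- mask_data(pred); g <- mask_data(gt)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  c(tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn)
}

mask_data <- function(m) {
  if (inherits(m, "seg_mask")) m$data
  else { if (!all(m %in% c(0, 1))) stop("mask voxels must be 0/1"); m }
}

mask_spacing <- function(m, spacing) {
  if (!is.null(spacing)) return(as.numeric(spacing))
  if (inherits(m, "seg_mask")) m$spacing else c(1, 1, 1)
}

#' Overlap metrics between predicted and reference masks
#'
#' `dice = 2TP/(2TP+FP+FN)`, `jaccard = TP/(TP+FP+FN)`,
#' `tpr = TP/(TP+FN)` (sensitivity), `fpr = FP/(FP+TN)`. The FPR denominator
#' is every non-tumor voxel of the volume, which is why reported FPRs on
#' whole head volumes are near zero. Conventions: with both masks empty,
#' `dice = jaccard = 1` and `fpr = 0`; `tpr` is `NA` whenever the reference
#' is empty.
#'
#' @inheritParams confusion_counts
#' @return Scalar in \[0,1\] (or `NA` where undefined).
#' @export
dice <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  den <- 2 * cc["tp"] + cc["fp"] + cc["fn"]
  if (den == 0) return(1)  # both empty
  unname(2 * cc["tp"] / den)
}

#' @rdname dice
#' @export
jaccard <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  den <- cc["tp"] + cc["fp"] + cc["fn"]
  if (den == 0) return(1)
  unname(cc["tp"] / den)
}

#' @rdname dice
#' @export
tpr <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  if (cc["tp"] + cc["fn"] == 0) return(NA_real_)
  unname(cc["tp"] / (cc["tp"] + cc["fn"]))
}

#' @rdname dice
#' @export
fpr <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  if (cc["fp"] + cc["tn"] == 0) return(NA_real_)
  unname(cc["fp"] / (cc["fp"] + cc["tn"]))
}

boundary_voxels <- function(m) {
  b <- m - erode6(m)  # 6-connectivity; image border counts as background
  which(b == 1, arr.ind = TRUE)
}

#' Directed surface distances between two masks
#'
#' Boundary voxels are foreground voxels with at least one background
#' 6-neighbour (the image border counts as background). Distances are
#' Euclidean in mm, scaled by the voxel spacing, from every boundary voxel of
#' one mask to the nearest boundary voxel of the other, in both directions.
#'
#' @inheritParams confusion_counts
#' @param spacing Spacing triple in mm; defaults to the masks' own spacing.
#' @return `list(pred_to_gt = , gt_to_pred = )`, two numeric vectors in mm,
#'   or `NULL` if either mask is empty.
#' @export
surface_distances <- function(pred, gt, spacing = NULL) {
  p <- mask_data(pred); g <- mask_data(gt)
  if (!identical(dim(p), dim(g))) stop("mask shapes differ")
  if (sum(p) == 0 || sum(g) == 0) return(NULL)
  sp <- mask_spacing(pred, spacing)
  bp <- boundary_voxels(p); bg <- boundary_voxels(g)
  list(pred_to_gt = as.numeric(.cpp_directed_distances(bp * 1.0, bg * 1.0, sp)),
       gt_to_pred = as.numeric(.cpp_directed_distances(bg * 1.0, bp * 1.0, sp)))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile (linear interpolation) of the pooled multiset of both
#' directed surface-distance sets. `NA` when either mask is empty.
#'
#' @inheritParams surface_distances
#' @param probs Percentile to report, default 0.95 (1 gives the classic
#'   Hausdorff distance).
#' @param pooled Pool both directions before taking the percentile (default);
#'   `FALSE` takes the maximum of the two directed percentiles instead.
#' @return Distance in mm, or `NA`.
#' @export
hd95 <- function(pred, gt, spacing = NULL, probs = 0.95, pooled = TRUE) {
  sd_ <- surface_distances(pred, gt, spacing)
  if (is.null(sd_)) return(NA_real_)
  if (pooled)
    unname(stats::quantile(c(sd_$pred_to_gt, sd_$gt_to_pred), probs, type = 7))
  else
    max(stats::quantile(sd_$pred_to_gt, probs, type = 7),
        stats::quantile(sd_$gt_to_pred, probs, type = 7))
}

#' Mask volume in milliliters
#'
#' `foreground voxel count x sx sy sz / 1000`.
#'
#' @param mask A [seg_mask()] or binary array.
#' @param spacing Spacing in mm; defaults to the mask's own.
#' @return Volume in mL.
#' @export
volume_ml <- function(mask, spacing = NULL) {
  sp <- mask_spacing(mask, spacing)
  sum(mask_data(mask)) * prod(sp) / 1000
}

#' Evaluate one case: all per-case metrics as a single row
#'
#' Metrics are computed on the full 3D stacked volume of the case, not
#' averaged over slices.
#'
#' @inheritParams surface_distances
#' @param case_id Case identifier for the row.
#' @param seconds_elapsed Optional processing time to record.
#' @return A one-row `data.frame`: `case_id, dsc, jaccard, tpr, fpr, hd95_mm,
#'   pred_volume_ml, gt_volume_ml, seconds_elapsed`.
#' @export
evaluate_case <- function(pred, gt, spacing = NULL, case_id = "case",
                          seconds_elapsed = NA_real_) {
  sp <- mask_spacing(pred, spacing)
  data.frame(case_id = case_id,
             dsc = dice(pred, gt),
             jaccard = jaccard(pred, gt),
             tpr = tpr(pred, gt),
             fpr = fpr(pred, gt),
             hd95_mm = hd95(pred, gt, sp),
             pred_volume_ml = volume_ml(pred, sp),
             gt_volume_ml = volume_ml(gt, sp),
             seconds_elapsed = seconds_elapsed,
             stringsAsFactors = FALSE)
}
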