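#' Achievable segmentation accuracy (ASA)
#'
#' Upper-bound overlap of a predicted partition with ground-truth regions:
#' every predicted cluster is credited with its largest overlap against any
#' ground-truth region, `ASA = sum_k max_i |c_k ∩ g_i| / sum_i |g_i|`.
#' Label 0 marks background/ignored elements in both grids.
#'
#' @param pred integer grid of predicted cluster labels.
#' @param gt integer grid of ground-truth region labels.
#' @return ASA in `[0, 1]`.
#' @export
asa <- function(pred, gt) {
  stopifnot(length(pred) == length(gt))
  gi <- gt[gt > 0]
  if (length(gi) == 0L) stop("ground truth has no labeled regions")
  keep <- pred > 0 & gt > 0
  num <- 0
  if (any(keep)) {
    ov <- table(pred[keep], gt[keep])
    num <- sum(apply(ov, 1, max))
  }
  num / length(gi)
}

#' Majority-rule lesion labeling of predicted clusters
#'
#' A predicted cluster is called a lesion cluster iff strictly more than
#' half of its constituent elements lie inside the ground-truth lesion; an
#' exact tie is called background (conservative under class imbalance).
#'
#' @param pred integer grid of predicted cluster labels (0 = background).
#' @param gt_lesion logical/0-1 grid of the ground-truth lesion.
#' @return integer vector of cluster labels called lesion (possibly empty).
#' @export
label_clusters_majority <- function(pred, gt_lesion) {
  stopifnot(length(pred) == length(gt_lesion))
  lesion <- as.logical(gt_lesion)
  ks <- as.integer(sort(unique(pred[pred > 0])))
  if (length(ks) == 0L) return(integer(0))
  inside <- vapply(ks, function(k) sum(lesion[pred == k]), 0)
  total <- vapply(ks, function(k) sum(pred == k), 0)
  ks[inside > total / 2]
}

#' Lesion-focused Dice-like ASA
#'
#' The Dice-normalized, lesion-restricted ASA variant: predicted clusters
#' are first called lesion/background by majority rule, then
#' `ASA_Dice(L) = 2 * sum_{k in L} max_{i in G_L} |c_k ∩ g_i| /
#' (sum_{k in L} |c_k| + sum_{i in G_L} |g_i|)`. Unlike plain ASA this
#' penalizes both false positives (over-called clusters inflate the
#' denominator) and false negatives (missed lesion inflates it too).
#'
#' @param pred integer grid of predicted cluster labels (0 = background).
#' @param gt_lesion integer grid of ground-truth lesion regions (0 =
#'   non-lesion); a logical mask is treated as a single region.
#' @param lesion_clusters optional precomputed lesion cluster set; defaults
#'   to [label_clusters_majority()] against `gt_lesion > 0`.
#' @return ASA_Dice(L) in `[0, 1]`. Returns 1 with a warning when both the
#'   lesion cluster set and the ground-truth lesion are empty.
#' @export
asa_dice <- function(pred, gt_lesion, lesion_clusters = NULL) {
  stopifnot(length(pred) == length(gt_lesion))
  gt_lesion <- if (is.logical(gt_lesion)) as.integer(gt_lesion)
               else as.integer(gt_lesion)
  L <- if (is.null(lesion_clusters))
    label_clusters_majority(pred, gt_lesion > 0) else lesion_clusters
  gl_size <- sum(gt_lesion > 0)
  if (length(L) == 0L && gl_size == 0L) {
    warning("both lesion cluster set and ground-truth lesion are empty; ",
            "returning 1 (vacuously perfect)")
    return(1)
  }
  if (length(L) == 0L) return(0)
  in_L <- pred %in% L
  cl_size <- sum(in_L)
  num <- 0
  keep <- in_L & gt_lesion > 0
  if (any(keep)) {
    ov <- table(pred[keep], gt_lesion[keep])
    num <- sum(apply(ov, 1, max))
  }
  2 * num / (cl_size + gl_size)
}

#' Confusion counts of a binary segmentation
#'
#' @param pred,gt logical/0-1 grids of equal shape.
#' @return list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, gt) {
  stopifnot(length(pred) == length(gt))
  p <- as.logical(pred); g <- as.logical(gt)
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g)),
            class = "confusion_counts")
}

#' Confusion-matrix segmentation metrics
#'
#' Dice `2TP/(2TP+FP+FN)`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, accuracy `(TP+TN)/(TP+TN+FP+FN)` and specificity
#' `TN/(TN+FP)`. A `0/0` ratio is undefined and reported as `NA`, not 0.
#'
#' @param counts a [confusion_counts()] (or a list with TP, TN, FP, FN).
#' @return named list with the five metrics.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    list(dice = ratio(2 * TP, 2 * TP + FP + FN),
         precision = ratio(TP, TP + FP),
         sensitivity = ratio(TP, TP + FN),
         accuracy = ratio(TP + TN, TP + TN + FP + FN),
         specificity = ratio(TN, TN + FP))
  })
}

# boundary = mask minus its single-element erosion (face-connected
# structuring element; outside the grid counts as background)
.mask_boundary <- function(mask) {
  dm <- dim(mask) %||% length(mask)
  mask <- array(as.logical(mask), dim = dm)
  er <- mask
  nd <- length(dm)
  for (axis in seq_len(nd)) {
    n <- dm[axis]
    idx_lo <- lapply(seq_len(nd), function(a)
      if (a == axis) c(1L, seq_len(n - 1L)) else seq_len(dm[a]))
    idx_hi <- lapply(seq_len(nd), function(a)
      if (a == axis) c(seq_len(n - 1L) + 1L, n) else seq_len(dm[a]))
    shift_lo <- do.call(`[`, c(list(mask), idx_lo, list(drop = FALSE)))
    shift_hi <- do.call(`[`, c(list(mask), idx_hi, list(drop = FALSE)))
    # grid-edge elements have an implicit outside neighbor
    edge <- array(FALSE, dm)
    idx_first <- lapply(seq_len(nd), function(a)
      if (a == axis) 1L else seq_len(dm[a]))
    idx_last <- lapply(seq_len(nd), function(a)
      if (a == axis) n else seq_len(dm[a]))
    edge <- do.call(`[<-`, c(list(edge), idx_first, list(value = TRUE)))
    edge <- do.call(`[<-`, c(list(edge), idx_last, list(value = TRUE)))
    er <- er & array(shift_lo, dm) & array(shift_hi, dm) & !edge
  }
  which(mask & !er)
}

#' 95th-percentile Hausdorff distance
#'
#' Boundary points are extracted from each mask as the mask minus its
#' single-element erosion. For each direction the 95th percentile (linear
#' interpolation) of the point-to-nearest-opposite-boundary distances is
#' taken; the reported value is the maximum of the two directed values,
#' in physical units given the per-axis `spacing`.
#'
#' @param pred,gt non-empty logical/0-1 grids of equal shape.
#' @param spacing physical element spacing per axis (recycled; default 1).
#' @param probs percentile (default 0.95).
#' @return the Hausdorff-95 distance (0 for identical masks).
#' @export
hausdorff95 <- function(pred, gt, spacing = 1, probs = 0.95) {
  dm <- dim(pred) %||% length(pred)
  if (!identical(as.integer(dm), as.integer(dim(gt) %||% length(gt))))
    stop("masks must share shape")
  if (!any(as.logical(pred)) || !any(as.logical(gt)))
    stop("both masks must be non-empty")
  nd <- length(dm)
  spacing <- rep(spacing, length.out = nd)
  bp <- arrayInd(.mask_boundary(pred), .dim = dm)
  bg <- arrayInd(.mask_boundary(gt), .dim = dm)
  bp <- sweep(bp, 2, spacing, "*")
  bg <- sweep(bg, 2, spacing, "*")
  directed <- function(a, b) {
    # min distance from each row of a to the point set b
    mins <- vapply(seq_len(nrow(a)), function(i) {
      sqrt(min(colSums((t(b) - a[i, ])^2)))
    }, 0)
    stats::quantile(mins, probs, names = FALSE, type = 7)
  }
  max(directed(bp, bg), directed(bg, bp))
}
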