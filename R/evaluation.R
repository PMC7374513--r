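#' @title Tracking evaluation
#' @description
#' Scores identified tracks against ground truth with mutual-nearest
#' matching gated by the ground-truth body length. Because exactly N poses
#' are predicted in every frame, every unmatched prediction is both a false
#' positive and a false negative, so precision always equals recall.
#' @name evaluation
NULL

#' Pose error between a ground-truth and a predicted pose
#'
#' Sum of the shoulder-to-shoulder and tail-to-tail Euclidean distances.
#'
#' @param gt,pred Poses: lists with `shoulder` and `tail` coordinates.
#' @return Non-negative error.
#' @export
pose_error <- function(gt, pred) {
  .pt_dist(gt$shoulder, pred$shoulder) + .pt_dist(gt$tail, pred$tail)
}

#' Ground-truth body length
#'
#' Shoulder-to-tail distance of a ground-truth pose; the match gate adapts
#' to animal size through this quantity.
#'
#' @param gt Pose with `shoulder` and `tail` coordinates.
#' @return Positive length.
#' @export
gt_length <- function(gt) {
  l <- .pt_dist(gt$shoulder, gt$tail)
  if (l == 0) stop("ground-truth body length is zero")
  l
}

#' Match one frame of predictions against ground truth
#'
#' In `location_id` mode prediction i matches iff ground truth i and
#' prediction i are mutually nearest (in [pose_error()] terms) and their
#' error is below the ground-truth body length. In `location` mode the
#' mutual-nearest pair `(k, i)` may have differing indices and the gate is
#' the error between the paired ground truth k and prediction i against
#' `gt_length(k)` -- identity labels are ignored. Equidistant ties resolve
#' toward the lower index.
#'
#' @param gt_frame Ground-truth frame (`identity`, `shoulders`, `tails`;
#'   row n = identity n).
#' @param pred_frame Predicted frame in the same layout.
#' @param mode `"location_id"` or `"location"`.
#' @return Logical vector: whether each of the N predictions matched.
#' @export
match_frame <- function(gt_frame, pred_frame,
                        mode = c("location_id", "location")) {
  mode <- match.arg(mode)
  N <- nrow(gt_frame$shoulders)
  if (nrow(pred_frame$shoulders) != N) {
    stop("prediction and ground truth must contain the same number of targets")
  }
  D <- .pose_error_matrix(gt_frame$shoulders, gt_frame$tails,
                          pred_frame$shoulders, pred_frame$tails)
  ell <- sqrt(rowSums((gt_frame$shoulders - gt_frame$tails)^2))
  if (any(ell == 0)) stop("ground-truth body length is zero")
  nearest_gt <- apply(D, 2L, which.min)    # for each prediction i
  nearest_pred <- apply(D, 1L, which.min)  # for each ground truth j
  if (mode == "location_id") {
    i <- seq_len(N)
    nearest_gt == i & nearest_pred == i & D[cbind(i, i)] < ell
  } else {
    vapply(seq_len(N), function(i) {
      k <- nearest_gt[[i]]
      nearest_pred[[k]] == i && D[k, i] < ell[[k]]
    }, logical(1))
  }
}

#' Precision and recall of identified tracks
#'
#' Pools matches over all frames. With fixed cardinality the number of
#' false positives equals the number of false negatives, so precision and
#' recall coincide: `TP / (N T)`.
#'
#' @param gt List of ground-truth frames (see [read_ground_truth()]).
#' @param pred A `pentrack_result`, or a list of predicted frames in the
#'   ground-truth layout (see [identified_poses()]).
#' @param mode `"location_id"` or `"location"`.
#' @param scenario Optional scenario label carried into the result.
#' @return Object of class `scenario_result` with counts and
#'   `precision == recall`.
#' @export
precision_recall <- function(gt, pred, mode = c("location_id", "location"),
                             scenario = NULL) {
  mode <- match.arg(mode)
  if (inherits(pred, "pentrack_result")) {
    if (is.null(scenario)) scenario <- pred$scenario
    pred <- identified_poses(pred)
  }
  if (length(gt) != length(pred)) {
    stop("ground truth covers ", length(gt), " frames but predictions ",
         length(pred))
  }
  N <- nrow(gt[[1L]]$shoulders)
  T_ <- length(gt)
  tp <- 0L
  for (t in seq_len(T_)) {
    if (gt[[t]]$t != pred[[t]]$t) {
      stop("frame misalignment at position ", t)
    }
    tp <- tp + sum(match_frame(gt[[t]], pred[[t]], mode))
  }
  total <- N * T_
  structure(
    list(scenario = scenario, mode = mode, n_targets = N, n_frames = T_,
         true_positives = tp, false_positives = total - tp,
         false_negatives = total - tp,
         precision = tp / total, recall = tp / total),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Tracking evaluation (", x$mode, " matching",
      if (!is.null(x$scenario)) paste0(", ", x$scenario, " scenario"),
      ")\n", sep = "")
  cat("  targets:", x$n_targets, " frames:", x$n_frames, "\n")
  cat("  TP:", x$true_positives, " FP = FN:", x$false_positives, "\n")
  cat("  precision = recall =",
      format(x$precision, digits = 4), "\n")
  invisible(x)
}

#' @export
as.list.scenario_result <- function(x, ...) unclass(x)
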