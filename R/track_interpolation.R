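#' @title Fixed-cardinality track interpolation
#' @description
#' The per-frame detector misses animals (occlusion) and fires on clutter,
#' so raw frames carry a variable number of instances. Because the number
#' of animals in the pen is a known constant N, detection counts are first
#' limited to at most N per frame by removing the highest-cost instances,
#' then turned into exactly N continuous tracks: a forward scan duplicates
#' any previous-frame entry the Hungarian association leaves unmatched, a
#' backward scan does the same in reverse, and finally every duplicated
#' position is replaced by time-weighted linear interpolation between its
#' nearest flanking real detections.
#' @name track_interpolation
NULL

#' Detection confidence cost
#'
#' Cost of a single instance, used to discard the least trustworthy
#' detections when a frame holds more than N. The back-and-forth error of
#' the part-association estimates is normalised by twice the body length
#' and divided by the sum of the two part scores:
#' \deqn{C(x) = \frac{|(t \to s) - s| + |(s \to t) - t|}{2\,|s - t|\,(score_s + score_t)}.}
#' Perfect association estimates give cost 0; since scores live in
#' `[0.25, 1]`, the score term scales the cost by between 1/2 (two perfect
#' scores) and 2 (two minimal scores).
#'
#' @param d An [instance_detection()].
#' @param score_reading How the score sum enters: `"divide"` (default;
#'   consistent with low scores increasing the cost) or `"multiply"`.
#' @return Non-negative cost.
#' @export
instance_cost <- function(d, score_reading = c("divide", "multiply")) {
  score_reading <- match.arg(score_reading)
  stopifnot(inherits(d, "instance_detection"))
  body <- .pt_dist(d$shoulder, d$tail)
  if (body == 0) stop("shoulder == tail: cost undefined")
  base <- (.pt_dist(d$est_shoulder_from_tail, d$shoulder) +
             .pt_dist(d$est_tail_from_shoulder, d$tail)) / (2 * body)
  s <- d$shoulder_score + d$tail_score
  if (score_reading == "divide") base / s else base * s
}

#' Limit a frame to at most N instances
#'
#' When a frame holds more than N instances, keeps the N with the lowest
#' [instance_cost()]; ties keep the earlier-listed instance. Ear
#' observations are untouched.
#'
#' @param frame A [frame_detections()].
#' @param N Number of housed animals.
#' @param score_reading Passed to [instance_cost()].
#' @return The (possibly reduced) `frame_detections`.
#' @export
prune_frame <- function(frame, N, score_reading = "divide") {
  stopifnot(inherits(frame, "frame_detections"), N >= 1)
  if (length(frame$instances) <= N) return(frame)
  costs <- vapply(frame$instances, instance_cost, numeric(1),
                  score_reading = score_reading)
  keep <- sort(order(costs)[seq_len(N)])
  frame$instances <- frame$instances[keep]
  frame
}

# pose displacement between two (shoulder, tail) pairs, Euclidean in the
# 4-dimensional joint space: sqrt(|s_a - s_b|^2 + |t_a - t_b|^2)
.pose_delta_matrix <- function(sx1, sy1, tx1, ty1, sx2, sy2, tx2, ty2) {
  d2 <- outer(sx1, sx2, "-")^2 + outer(sy1, sy2, "-")^2 +
    outer(tx1, tx2, "-")^2 + outer(ty1, ty2, "-")^2
  sqrt(d2)
}

#' Associate instances between adjacent frames
#'
#' Minimum-total-cost bipartite matching of size
#' `min(length(prev), length(next_))` between two frames' poses, with the
#' pose displacement (root of summed squared shoulder and tail distances,
#' see [slot_distance()]) as cost. No distance gate is applied: with fixed
#' cardinality a far match is preferable to none.
#'
#' @param prev,next_ Lists of poses, each a list with `shoulder` and `tail`
#'   coordinates (an [instance_detection()] qualifies).
#' @return List with `pairs` (two-column matrix of prev/next indices),
#'   `unmatched_prev` and `unmatched_next` index vectors.
#' @export
associate_adjacent <- function(prev, next_) {
  np <- length(prev)
  nn <- length(next_)
  if (np == 0L || nn == 0L) {
    return(list(pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("prev", "next"))),
                unmatched_prev = seq_len(np), unmatched_next = seq_len(nn)))
  }
  get <- function(lst, part, i) vapply(lst, function(p) p[[part]][[i]],
                                       numeric(1))
  cost <- .pose_delta_matrix(
    get(prev, "shoulder", 1), get(prev, "shoulder", 2),
    get(prev, "tail", 1), get(prev, "tail", 2),
    get(next_, "shoulder", 1), get(next_, "shoulder", 2),
    get(next_, "tail", 1), get(next_, "tail", 2)
  )
  if (np <= nn) {
    a <- solve_assignment(cost)
    pairs <- cbind(prev = seq_len(np), next. = a)
  } else {
    a <- solve_assignment(t(cost))
    pairs <- cbind(prev = a, next. = seq_len(nn))
  }
  colnames(pairs) <- c("prev", "next")
  list(pairs = pairs,
       unmatched_prev = setdiff(seq_len(np), pairs[, 1L]),
       unmatched_next = setdiff(seq_len(nn), pairs[, 2L]))
}

#' Build exactly N continuous tracks from pruned detections
#'
#' Two-pass duplication followed by interpolation. Pass 1 scans frames
#' forward; every previous-frame entry that the Hungarian association
#' leaves unmatched is copied into the current frame and flagged as a
#' duplicate. Pass 2 scans backward and mirrors the rule: entries with no
#' predecessor are copied into the previous frame. All association links
#' are kept, so afterwards the entries form disjoint chains spanning all
#' frames. Each duplicate's shoulder and tail are then replaced by the
#' time-weighted linear interpolation between the nearest flanking real
#' detections on its chain,
#' `x(t) = ((t2 - t) x(t1) + (t - t1) x(t2)) / (t2 - t1)`; a duplicate with
#' detections on one side only holds the nearest detected position.
#'
#' In the pathological case where no frame ever reaches N detections, the
#' chains are padded to N by cloning the first chain, so the fixed
#' cardinality contract holds for any dropout pattern.
#'
#' @param frames List of `frame_detections`, pruned so no frame exceeds N
#'   instances (see [prune_frame()]).
#' @param N Number of housed animals.
#' @return Object of class `track_set`: a list with `N`, `T`, the `T x N`
#'   coordinate matrices `shoulder_x`, `shoulder_y`, `tail_x`, `tail_y`,
#'   the origin matrix (`"detected"`, `"duplicate_raw"` before
#'   interpolation, `"interpolated"` after) and `det_index`, the index of
#'   the raw detection occupying each slot (`NA` for fabricated entries).
#' @export
build_tracks <- function(frames, N) {
  T_ <- length(frames)
  stopifnot(T_ >= 1L, N >= 1L)
  counts <- vapply(frames, function(f) length(f$instances), integer(1))
  if (all(counts == 0L)) stop("no detections in any frame: nothing to track")
  if (any(counts > N)) {
    stop("frame ", which(counts > N)[[1L]], " has more than N instances; ",
         "prune first")
  }

  # per-frame growable entry sets
  sx <- vector("list", T_); sy <- vector("list", T_)
  tx <- vector("list", T_); ty <- vector("list", T_)
  origin <- vector("list", T_); det <- vector("list", T_)
  prev_link <- vector("list", T_)
  for (t in seq_len(T_)) {
    ins <- frames[[t]]$instances
    sx[[t]] <- vapply(ins, function(d) d$shoulder[[1L]], numeric(1))
    sy[[t]] <- vapply(ins, function(d) d$shoulder[[2L]], numeric(1))
    tx[[t]] <- vapply(ins, function(d) d$tail[[1L]], numeric(1))
    ty[[t]] <- vapply(ins, function(d) d$tail[[2L]], numeric(1))
    origin[[t]] <- rep("detected", length(ins))
    det[[t]] <- seq_along(ins)
    prev_link[[t]] <- rep(NA_integer_, length(ins))
  }

  pose_list <- function(t) {
    lapply(seq_along(sx[[t]]), function(i) {
      list(shoulder = c(sx[[t]][[i]], sy[[t]][[i]]),
           tail = c(tx[[t]][[i]], ty[[t]][[i]]))
    })
  }

  # pass 1: forward duplication
  for (t in seq_len(T_)[-1L]) {
    assoc <- associate_adjacent(pose_list(t - 1L), pose_list(t))
    if (nrow(assoc$pairs) > 0L) {
      prev_link[[t]][assoc$pairs[, "next"]] <- assoc$pairs[, "prev"]
    }
    for (j in assoc$unmatched_prev) {
      sx[[t]] <- c(sx[[t]], sx[[t - 1L]][[j]])
      sy[[t]] <- c(sy[[t]], sy[[t - 1L]][[j]])
      tx[[t]] <- c(tx[[t]], tx[[t - 1L]][[j]])
      ty[[t]] <- c(ty[[t]], ty[[t - 1L]][[j]])
      origin[[t]] <- c(origin[[t]], "duplicate_raw")
      det[[t]] <- c(det[[t]], NA_integer_)
      prev_link[[t]] <- c(prev_link[[t]], j)
    }
  }

  # pass 2: backward duplication -- every entry of frame t already has a
  # forward successor, so an entry of frame t with no predecessor simply
  # spawns a copy of itself in frame t - 1
  if (T_ >= 2L) {
    for (t in rev(seq_len(T_)[-1L])) {
      for (j in which(is.na(prev_link[[t]]))) {
        sx[[t - 1L]] <- c(sx[[t - 1L]], sx[[t]][[j]])
        sy[[t - 1L]] <- c(sy[[t - 1L]], sy[[t]][[j]])
        tx[[t - 1L]] <- c(tx[[t - 1L]], tx[[t]][[j]])
        ty[[t - 1L]] <- c(ty[[t - 1L]], ty[[t]][[j]])
        origin[[t - 1L]] <- c(origin[[t - 1L]], "duplicate_raw")
        det[[t - 1L]] <- c(det[[t - 1L]], NA_integer_)
        prev_link[[t - 1L]] <- c(prev_link[[t - 1L]], NA_integer_)
        prev_link[[t]][[j]] <- length(sx[[t - 1L]])
      }
    }
  }

  M <- length(sx[[1L]])
  # follow links to assign chain (slot) labels
  chain <- vector("list", T_)
  chain[[1L]] <- seq_len(M)
  if (T_ >= 2L) {
    for (t in seq_len(T_)[-1L]) {
      chain[[t]] <- chain[[t - 1L]][prev_link[[t]]]
    }
  }

  n_slots <- max(M, N)
  mk <- function() matrix(NA_real_, nrow = T_, ncol = n_slots)
  Sx <- mk(); Sy <- mk(); Tx <- mk(); Ty <- mk()
  Or <- matrix(NA_character_, nrow = T_, ncol = n_slots)
  Di <- matrix(NA_integer_, nrow = T_, ncol = n_slots)
  for (t in seq_len(T_)) {
    idx <- cbind(t, chain[[t]])
    Sx[idx] <- sx[[t]]; Sy[idx] <- sy[[t]]
    Tx[idx] <- tx[[t]]; Ty[idx] <- ty[[t]]
    Or[idx] <- origin[[t]]; Di[idx] <- det[[t]]
  }
  if (M < N) {
    # pad to N chains by cloning chain 1 (degenerate dropout pattern)
    for (s in seq.int(M + 1L, N)) {
      Sx[, s] <- Sx[, 1L]; Sy[, s] <- Sy[, 1L]
      Tx[, s] <- Tx[, 1L]; Ty[, s] <- Ty[, 1L]
      Or[, s] <- "duplicate_raw"; Di[, s] <- NA_integer_
    }
  }

  # interpolation: per chain, replace duplicates by linear interpolation
  # through the detected knots; constant extrapolation holds the ends
  for (s in seq_len(n_slots)) {
    det_t <- which(Or[, s] == "detected")
    gap_t <- which(Or[, s] != "detected")
    if (length(gap_t) == 0L) next
    if (length(det_t) == 0L) {
      # padded clone of an undetected chain: keep copied positions
      Or[gap_t, s] <- "interpolated"
      next
    }
    if (length(det_t) == 1L) {
      Sx[gap_t, s] <- Sx[det_t, s]; Sy[gap_t, s] <- Sy[det_t, s]
      Tx[gap_t, s] <- Tx[det_t, s]; Ty[gap_t, s] <- Ty[det_t, s]
    } else {
      Sx[gap_t, s] <- approx(det_t, Sx[det_t, s], xout = gap_t, rule = 2)$y
      Sy[gap_t, s] <- approx(det_t, Sy[det_t, s], xout = gap_t, rule = 2)$y
      Tx[gap_t, s] <- approx(det_t, Tx[det_t, s], xout = gap_t, rule = 2)$y
      Ty[gap_t, s] <- approx(det_t, Ty[det_t, s], xout = gap_t, rule = 2)$y
    }
    Or[gap_t, s] <- "interpolated"
  }

  structure(
    list(N = as.integer(n_slots), T = T_,
         shoulder_x = Sx, shoulder_y = Sy, tail_x = Tx, tail_y = Ty,
         origin = Or, det_index = Di),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  n_interp <- sum(x$origin != "detected")
  cat("track_set: ", x$N, " tracks x ", x$T, " frames; ",
      n_interp, " interpolated entries (",
      format(100 * n_interp / (x$N * x$T), digits = 3), "%)\n", sep = "")
  invisible(x)
}
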