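#' @title Ear-tag marker evidence
#' @description
#' Each animal wears a uniquely coloured ear tag. Whenever an ear is
#' detected, an upstream classifier supplies a probability vector over the
#' N housed identities. Rather than hard-assigning ears to instances, every
#' ear is *softly* linked to every instance through the back-and-forth
#' distance of the detector's ear/shoulder association vectors, and the
#' instance's identity likelihood is the product over ears of a
#' link-weighted blend of the tag vector with the uniform distribution.
#' These likelihoods form the per-frame emission tensor consumed by the
#' forward-backward smoother.
#' @name marker_model
NULL

#' Normalised back-and-forth ear-shoulder distance
#'
#' \deqn{d = \frac{|(e \to s) - s| + |(s \to e) - e|}{2\,|s - e|}:}
#' the average of the two association-vector errors, normalised by the
#' actual ear-shoulder distance so the quantity is scale-free. A missing
#' estimate (`NULL`) contributes a zero error term.
#'
#' @param shoulder Instance shoulder coordinates.
#' @param est_ear The instance's estimated ear position for the relevant
#'   side, or `NULL`.
#' @param ear Observed ear coordinates.
#' @param est_shoulder The ear's estimated shoulder position, or `NULL`.
#' @return Non-negative distance.
#' @export
ear_shoulder_distance <- function(shoulder, est_ear, ear, est_shoulder) {
  shoulder <- .as_point(shoulder, "shoulder")
  ear <- .as_point(ear, "ear")
  sep <- .pt_dist(shoulder, ear)
  if (sep == 0) stop("shoulder == ear: distance undefined")
  e1 <- if (is.null(est_shoulder)) 0 else
    .pt_dist(.as_point(est_shoulder), shoulder)
  e2 <- if (is.null(est_ear)) 0 else .pt_dist(.as_point(est_ear), ear)
  (e1 + e2) / (2 * sep)
}

#' Probability that an ear belongs to an instance
#'
#' Decaying exponential of the normalised back-and-forth distance,
#' `max(1e-6, exp(-10 d))`; the floor keeps a single over-confident
#' association from zeroing out evidence entirely.
#'
#' @param d Non-negative distance from [ear_shoulder_distance()].
#' @return Link probability in `[1e-6, 1]`.
#' @export
link_probability <- function(d) {
  d <- as.numeric(d)
  if (anyNA(d) || any(d < 0)) stop("d must be non-negative")
  pmax(1e-6, exp(-10 * d))
}

#' Identity likelihood of one instance from the frame's ear observations
#'
#' For each identity n, the product over all ear observations j of
#' \eqn{p(s \to e_j)\,p(e_j \to n) + (1 - p(s \to e_j))/N}, normalised over
#' n. A strongly linked, confidently classified ear drives the vector
#' toward that ear's tag distribution; with no linked ears the vector is
#' uniform. Normalisation absorbs the constant factors contributed by ears
#' belonging to other animals, realising both limiting behaviours exactly.
#'
#' @param instance An [instance_detection()].
#' @param ears List of [ear_observation()]s for the frame (all of them;
#'   unlinked ears wash out).
#' @param N Number of housed animals; each ear's `tag_probs` must have
#'   length N.
#' @return Probability vector of length N summing to 1.
#' @export
instance_id_likelihood <- function(instance, ears, N) {
  stopifnot(inherits(instance, "instance_detection"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  v <- rep(1, N)
  for (e in ears) {
    if (length(e$tag_probs) != N) {
      stop("ear tag_probs length ", length(e$tag_probs),
           " does not match N = ", N)
    }
    est_ear <- if (e$side == "left") instance$est_left_ear else
      instance$est_right_ear
    d <- ear_shoulder_distance(instance$shoulder, est_ear,
                               e$location, e$est_shoulder)
    p <- link_probability(d)
    v <- v * (p * e$tag_probs + (1 - p) / N)
  }
  s <- sum(v)
  if (s <= 0 || !is.finite(s)) return(rep(1 / N, N))
  v / s
}

#' Assemble the emission tensor
#'
#' For every frame t and track slot i, the log likelihood of the frame's
#' observations given that identity n occupies the slot. Slots backed by a
#' real detection get [instance_id_likelihood()]; fabricated (interpolated)
#' entries carry a uniform row, since no detector association vectors exist
#' for invented geometry. Rows are floored at `floor_prob` before
#' normalisation, mirroring the over-confidence guard of the link model.
#'
#' When first-frame annotations are supplied (the "initialized" scenario),
#' the annotations are matched to slots by Hungarian assignment on the pose
#' error ([pose_error()]) and the frame-1 rows are overwritten with
#' near-one-hot distributions (`1 - (N-1) eps` at the matched identity,
#' `eps = 1e-6` elsewhere).
#'
#' @param tracks A `track_set` from [build_tracks()].
#' @param frames The detection frames the tracks were built from.
#' @param N Number of housed animals.
#' @param init Optional ground-truth frame (see [read_ground_truth()]) with
#'   first-frame identity annotations.
#' @param floor_prob Lower bound applied to emission probabilities.
#' @return `T x N x N` array `log_e[t, slot, identity]` of log
#'   probabilities; each `(t, slot)` row exponentiates to a probability
#'   vector.
#' @export
build_emissions <- function(tracks, frames, N, init = NULL,
                            floor_prob = 1e-6) {
  stopifnot(inherits(tracks, "track_set"))
  N <- as.integer(N)
  T_ <- tracks$T
  if (length(frames) != T_) stop("tracks and frames must cover the same t")
  log_e <- array(log(1 / N), dim = c(T_, tracks$N, N))
  for (t in seq_len(T_)) {
    f <- frames[[t]]
    ne <- length(f$ears)
    if (ne == 0L) next
    # vectorise the frame's ear geometry once
    ear_loc <- t(vapply(f$ears, `[[`, numeric(2), "location"))
    ear_est_s <- t(vapply(f$ears, function(e) {
      if (is.null(e$est_shoulder)) c(NA_real_, NA_real_) else e$est_shoulder
    }, numeric(2)))
    ear_left <- vapply(f$ears, function(e) e$side == "left", logical(1))
    tag <- t(vapply(f$ears, `[[`, numeric(N), "tag_probs"))
    dim(tag) <- c(ne, N)
    for (i in seq_len(tracks$N)) {
      di <- tracks$det_index[t, i]
      if (is.na(di)) next
      ins <- f$instances[[di]]
      s <- ins$shoulder
      est_ear <- matrix(NA_real_, ne, 2L)
      if (!is.null(ins$est_left_ear) && any(ear_left)) {
        est_ear[ear_left, 1L] <- ins$est_left_ear[[1L]]
        est_ear[ear_left, 2L] <- ins$est_left_ear[[2L]]
      }
      if (!is.null(ins$est_right_ear) && any(!ear_left)) {
        est_ear[!ear_left, 1L] <- ins$est_right_ear[[1L]]
        est_ear[!ear_left, 2L] <- ins$est_right_ear[[2L]]
      }
      sep <- sqrt((ear_loc[, 1L] - s[[1L]])^2 + (ear_loc[, 2L] - s[[2L]])^2)
      if (any(sep == 0)) stop("shoulder == ear: distance undefined")
      e1 <- sqrt((ear_est_s[, 1L] - s[[1L]])^2 +
                   (ear_est_s[, 2L] - s[[2L]])^2)
      e1[is.na(e1)] <- 0
      e2 <- sqrt((est_ear[, 1L] - ear_loc[, 1L])^2 +
                   (est_ear[, 2L] - ear_loc[, 2L])^2)
      e2[is.na(e2)] <- 0
      p <- pmax(1e-6, exp(-10 * (e1 + e2) / (2 * sep)))
      v <- exp(colSums(log(p * tag + (1 - p) / N)))
      sv <- sum(v)
      v <- if (sv > 0 && is.finite(sv)) v / sv else rep(1 / N, N)
      v <- pmax(v, floor_prob)
      log_e[t, i, ] <- log(v / sum(v))
    }
  }
  if (!is.null(init)) {
    if (length(init$identity) != N) {
      stop("init annotations carry ", length(init$identity),
           " identities but N = ", N)
    }
    eps <- 1e-6
    # cost[n, i]: pose error between annotation n and slot i at t = 1
    cost <- .pose_error_matrix(
      init$shoulders, init$tails,
      cbind(tracks$shoulder_x[1L, ], tracks$shoulder_y[1L, ]),
      cbind(tracks$tail_x[1L, ], tracks$tail_y[1L, ])
    )
    slot_of <- solve_assignment(cost)  # identity n -> slot
    row <- matrix(eps, nrow = tracks$N, ncol = N)
    for (n in seq_len(N)) row[slot_of[[n]], n] <- 1 - (N - 1) * eps
    log_e[1L, , ] <- log(row)
  }
  log_e
}

# matrix of pose errors Delta (sum of shoulder and tail Euclidean
# distances) between two sets of poses given as n x 2 matrices
.pose_error_matrix <- function(s1, t1, s2, t2) {
  ds <- sqrt(outer(s1[, 1L], s2[, 1L], "-")^2 +
               outer(s1[, 2L], s2[, 2L], "-")^2)
  dt <- sqrt(outer(t1[, 1L], t2[, 1L], "-")^2 +
               outer(t1[, 2L], t2[, 2L], "-")^2)
  ds + dt
}
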