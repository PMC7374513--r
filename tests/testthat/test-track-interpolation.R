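test_that("instance cost matches hand-computed values", {
  perfect <- instance_detection(c(0, 0), c(20, 0),
                                shoulder_score = 0.6, tail_score = 0.9)
  expect_equal(instance_cost(perfect), 0)

  d <- instance_detection(c(0, 0), c(20, 0), shoulder_score = 1,
                          tail_score = 1,
                          est_shoulder_from_tail = c(4, 0),
                          est_tail_from_shoulder = c(20, 0))
  # (4 + 0) / (2 * 20) / (1 + 1)
  expect_equal(instance_cost(d), 0.05)

  d2 <- instance_detection(c(0, 0), c(20, 0), shoulder_score = 0.25,
                           tail_score = 0.25,
                           est_shoulder_from_tail = c(4, 0),
                           est_tail_from_shoulder = c(20, 0))
  # minimal scores double the mid-score cost of 0.1
  expect_equal(instance_cost(d2), 0.2)
  # the multiplication reading is available but not the default
  expect_equal(instance_cost(d2, score_reading = "multiply"), 0.05)
})

test_that("pruning keeps the N lowest-cost instances, ties to lower index", {
  mk <- function(err) {
    instance_detection(c(0, 0), c(20, 0),
                       est_shoulder_from_tail = c(err, 0))
  }
  frame <- frame_detections(1, list(mk(3), mk(0), mk(5), mk(1), mk(2)),
                            ears = list(ear_observation("left", c(2, 2),
                                                        c(1, 0))))
  out <- prune_frame(frame, 4)
  expect_length(out$instances, 4L)
  # the err = 5 instance (index 3) is dropped; order preserved
  errs <- vapply(out$instances, function(d) d$est_shoulder_from_tail[[1L]],
                 numeric(1))
  expect_equal(errs, c(3, 0, 1, 2))
  expect_length(out$ears, 1L)

  expect_identical(prune_frame(frame_detections(1, list(mk(1))), 4)$instances,
                   list(mk(1)))

  tied <- frame_detections(1, list(mk(1), mk(1), mk(0)))
  out2 <- prune_frame(tied, 2)
  errs2 <- vapply(out2$instances, function(d) d$est_shoulder_from_tail[[1L]],
                  numeric(1))
  expect_equal(errs2, c(1, 0))  # first of the tied pair survives
})

test_that("adjacent-frame association matches brute force", {
  pose <- function(x, y) list(shoulder = c(x, y), tail = c(x + 10, y))
  same <- list(pose(0, 0), pose(50, 50), pose(100, 0))
  out <- associate_adjacent(same, same)
  expect_equal(out$pairs[, "prev"], 1:3)
  expect_equal(out$pairs[, "next"], 1:3)
  expect_length(out$unmatched_prev, 0L)

  prev <- list(pose(0, 0), pose(100, 0))
  nxt <- list(pose(95, 1))
  out2 <- associate_adjacent(prev, nxt)
  expect_equal(unname(out2$pairs[, "prev"]), 2L)
  expect_equal(out2$unmatched_prev, 1L)

  # random 3x3 cases equal the permutation-enumeration oracle
  set.seed(99)
  for (rep in 1:20) {
    a <- lapply(1:3, function(i) pose(runif(1, 0, 100), runif(1, 0, 100)))
    b <- lapply(1:3, function(i) pose(runif(1, 0, 100), runif(1, 0, 100)))
    out3 <- associate_adjacent(a, b)
    cost <- outer(seq_along(a), seq_along(b), Vectorize(function(i, j) {
      slot_distance(a[[i]], b[[j]])
    }))
    got <- sum(cost[out3$pairs])
    expect_equal(got, perm_min_cost(cost), tolerance = 1e-12)
  }
})

test_that("a one-frame gap is filled by the midpoint of its neighbours", {
  # four targets over three frames; target 4 missed in frame 2
  base <- cbind(c(0, 100, 0, 100), c(0, 0, 100, 100))
  p1 <- cbind(base, base + 12)
  p2 <- cbind(base + 2, base + 14)
  p3 <- cbind(base + 4, base + 16)
  tracks <- build_tracks(frames_from_positions(list(p1, p2[1:3, ], p3)), 4)
  expect_equal(tracks$N, 4L)
  expect_equal(sum(tracks$origin == "interpolated"), 1L)
  slot <- which(tracks$origin[2L, ] == "interpolated")
  expect_equal(tracks$shoulder_x[2L, slot], (100 + 104) / 2)
  expect_equal(tracks$tail_y[2L, slot], (112 + 116) / 2)
})

test_that("multi-frame gaps interpolate linearly and edges hold", {
  # single target detected at t = 1 and t = 5 only
  pos <- list(cbind(0, 0, 10, 0), NULL, NULL, NULL, cbind(8, 0, 18, 0))
  tracks <- build_tracks(frames_from_positions(pos), 1)
  expect_equal(tracks$shoulder_x[, 1L], c(0, 2, 4, 6, 8))
  expect_equal(tracks$tail_x[, 1L], c(10, 12, 14, 16, 18))
  expect_equal(tracks$origin[, 1L],
               c("detected", rep("interpolated", 3), "detected"))

  # leading gap: frames 1..3 hold the t = 4 position
  pos2 <- list(NULL, NULL, NULL, cbind(5, 5, 15, 5), cbind(6, 5, 16, 5))
  tracks2 <- build_tracks(frames_from_positions(pos2), 1)
  expect_equal(tracks2$shoulder_x[1:3, 1L], rep(5, 3))
  expect_equal(tracks2$origin[1:3, 1L], rep("interpolated", 3))
})

test_that("clean input is reproduced exactly with nothing flagged", {
  set.seed(5)
  N <- 5
  cur <- cbind(runif(N, 0, 500), runif(N, 0, 300))
  pos <- lapply(1:20, function(t) {
    cur <<- cur + matrix(rnorm(2 * N, 0, 2), ncol = 2)
    cbind(cur, cur + 20)
  })
  tracks <- build_tracks(frames_from_positions(pos), N)
  expect_true(all(tracks$origin == "detected"))
  for (t in c(1L, 10L, 20L)) {
    # every input detection appears in frame t (slots may permute)
    expect_setequal(round(tracks$shoulder_x[t, ], 9),
                    round(pos[[t]][, 1L], 9))
  }
})

test_that("fixed cardinality holds under heavy random dropout", {
  set.seed(31)
  for (rep in 1:5) {
    N <- sample(3:6, 1)
    T_ <- 25
    cur <- cbind(runif(N, 0, 400), runif(N, 0, 400))
    pos <- lapply(seq_len(T_), function(t) {
      cur <<- cur + matrix(rnorm(2 * N, 0, 3), ncol = 2)
      keep <- runif(N) > 0.4
      if (!any(keep)) keep[1L] <- TRUE
      cbind(cur, cur + 18)[keep, , drop = FALSE]
    })
    tracks <- build_tracks(frames_from_positions(pos), N)
    expect_equal(tracks$N, N)
    expect_false(anyNA(tracks$shoulder_x))
    expect_false(anyNA(tracks$tail_y))
    expect_true(all(tracks$origin %in% c("detected", "interpolated")))
    # interpolated entries lie within the bounding box of their chain's
    # detected positions (componentwise convex combination)
    for (s in seq_len(N)) {
      det_t <- tracks$origin[, s] == "detected"
      if (!any(det_t)) next
      rng <- range(tracks$shoulder_x[det_t, s])
      expect_true(all(tracks$shoulder_x[!det_t, s] >= rng[1L] - 1e-9))
      expect_true(all(tracks$shoulder_x[!det_t, s] <= rng[2L] + 1e-9))
    }
  }
})

test_that("degenerate inputs error or pad as documented", {
  empty <- frames_from_positions(list(NULL, NULL))
  expect_error(build_tracks(empty, 3), "no detections")
  # a sequence that never reaches N detections still yields N chains
  pos <- list(cbind(0, 0, 10, 0), cbind(1, 0, 11, 0))
  tracks <- build_tracks(frames_from_positions(pos), 3)
  expect_equal(tracks$N, 3L)
  expect_false(anyNA(tracks$shoulder_x))
})
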