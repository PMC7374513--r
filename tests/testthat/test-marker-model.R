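test_that("ear-shoulder distance matches hand arithmetic and is symmetric", {
  expect_equal(ear_shoulder_distance(c(0, 0), c(10, 0), c(10, 0), c(0, 0)), 0)
  # |est_shoulder - shoulder| = 2, |est_ear - ear| = 0, |s - e| = 10
  expect_equal(
    ear_shoulder_distance(c(0, 0), c(10, 0), c(10, 0), c(2, 0)), 0.1)
  # swapping which side carries the error leaves d unchanged
  expect_equal(
    ear_shoulder_distance(c(0, 0), c(12, 0), c(10, 0), c(0, 0)),
    ear_shoulder_distance(c(0, 0), c(10, 0), c(10, 0), c(2, 0)))
  expect_error(ear_shoulder_distance(c(1, 1), c(1, 1), c(1, 1), c(1, 1)),
               "undefined")
  # NULL estimates contribute zero error
  expect_equal(ear_shoulder_distance(c(0, 0), NULL, c(10, 0), NULL), 0)
})

test_that("link probability decays exponentially with a 1e-6 floor", {
  expect_equal(link_probability(0), 1)
  expect_equal(link_probability(0.2), exp(-2))
  expect_equal(link_probability(2), 1e-6)  # exp(-20) < floor
  expect_error(link_probability(-0.1), "non-negative")
})

test_that("identity likelihood realises both limiting behaviours", {
  N <- 4
  ins <- instance_detection(c(0, 0), c(-30, 0), est_left_ear = c(10, 5),
                            est_right_ear = c(10, -5))
  # no ears: uniform
  expect_equal(instance_id_likelihood(ins, list(), N), rep(1 / N, N))

  # one perfectly linked ear with a one-hot tag: one-hot output
  ear <- ear_observation("left", c(10, 5), c(0, 0, 1, 0),
                         est_shoulder = c(0, 0))
  out <- instance_id_likelihood(ins, list(ear), N)
  expect_equal(which.max(out), 3L)
  expect_gt(out[[3L]], 0.999)

  # a far, unlinked ear contributes only a constant factor
  far <- ear_observation("right", c(500, 500), c(1, 0, 0, 0),
                         est_shoulder = c(480, 500))
  out2 <- instance_id_likelihood(ins, list(ear, far), N)
  expect_equal(out2, out, tolerance = 1e-4)

  # two ears, N = 2: linked (0.8, 0.2) tag with an unlinked companion
  ins2 <- instance_detection(c(0, 0), c(-30, 0), est_left_ear = c(10, 5))
  e1 <- ear_observation("left", c(10, 5), c(0.8, 0.2),
                        est_shoulder = c(0, 0))
  e2 <- ear_observation("right", c(900, 900), c(0.3, 0.7),
                        est_shoulder = c(-5000, 900))
  expect_equal(instance_id_likelihood(ins2, list(e1, e2), 2), c(0.8, 0.2),
               tolerance = 1e-4)
})

test_that("identity likelihood is permutation-equivariant and monotone", {
  set.seed(21)
  N <- 5
  ins <- instance_detection(c(0, 0), c(-40, 0), est_left_ear = c(8, 4),
                            est_right_ear = c(8, -4))
  mk_ears <- function(tags) {
    lapply(seq_len(nrow(tags)), function(j) {
      ear_observation(sample(c("left", "right"), 1),
                      c(runif(1, 0, 30), runif(1, -10, 10)),
                      tags[j, ], est_shoulder = c(rnorm(1), rnorm(1)))
    })
  }
  for (rep in 1:10) {
    tags <- matrix(runif(3 * N), 3, N)
    tags <- tags / rowSums(tags)
    ears <- mk_ears(tags)
    base <- instance_id_likelihood(ins, ears, N)
    perm <- sample(N)
    ears_p <- lapply(ears, function(e) {
      ear_observation(e$side, e$location, e$tag_probs[perm], e$est_shoulder)
    })
    expect_equal(instance_id_likelihood(ins, ears_p, N), base[perm],
                 tolerance = 1e-12)
  }
  # raising a linked ear's mass at identity n never lowers output at n
  e <- ear_observation("left", c(8, 4), c(0.3, 0.3, 0.2, 0.1, 0.1),
                       est_shoulder = c(0.5, 0.2))
  lo <- instance_id_likelihood(ins, list(e), N)[[1L]]
  e_hi <- ear_observation("left", c(8, 4), c(0.5, 0.2, 0.15, 0.1, 0.05),
                          est_shoulder = c(0.5, 0.2))
  hi <- instance_id_likelihood(ins, list(e_hi), N)[[1L]]
  expect_gte(hi, lo)
})

test_that("emission rows are probability vectors; interpolated rows uniform", {
  set.seed(12)
  cfg <- simulation_config(N = 4, T = 30, seed = 12, dropout_prob = 0.2,
                           ear_visibility_prob = 0.5)
  sim <- simulate_pen(cfg)
  pruned <- lapply(sim$frames, prune_frame, N = 4)
  tracks <- build_tracks(pruned, 4)
  log_e <- build_emissions(tracks, pruned, 4)
  sums <- apply(log_e, c(1, 2), function(r) sum(exp(r)))
  expect_true(all(abs(sums - 1) < 1e-9))
  interp <- which(tracks$origin != "detected", arr.ind = TRUE)
  for (r in seq_len(min(nrow(interp), 20L))) {
    expect_equal(log_e[interp[r, 1L], interp[r, 2L], ], rep(log(1 / 4), 4))
  }
})

test_that("emissions agree with the standalone likelihood computation", {
  set.seed(13)
  cfg <- simulation_config(N = 3, T = 10, seed = 13, dropout_prob = 0,
                           fp_rate = 0, ear_visibility_prob = 0.8)
  sim <- simulate_pen(cfg)
  tracks <- build_tracks(sim$frames, 3)
  log_e <- build_emissions(tracks, sim$frames, 3)
  for (t in c(2L, 5L, 9L)) {
    for (i in 1:3) {
      di <- tracks$det_index[t, i]
      v <- instance_id_likelihood(sim$frames[[t]]$instances[[di]],
                                  sim$frames[[t]]$ears, 3)
      v <- pmax(v, 1e-6); v <- v / sum(v)
      expect_equal(log_e[t, i, ], log(v), tolerance = 1e-9)
    }
  }
})

test_that("first-frame annotations overwrite frame-1 emissions", {
  set.seed(14)
  cfg <- simulation_config(N = 3, T = 8, seed = 14, dropout_prob = 0,
                           fp_rate = 0, reversal_prob = 0,
                           assoc_noise_sd = 0, ear_visibility_prob = 0)
  sim <- simulate_pen(cfg)
  tracks <- build_tracks(sim$frames, 3)
  log_e <- build_emissions(tracks, sim$frames, 3, init = sim$gt[[1L]])
  p1 <- exp(log_e[1L, , ])
  # near-one-hot rows forming a permutation matrix
  expect_true(all(apply(p1, 1L, max) > 1 - 3e-6))
  expect_equal(sort(apply(p1, 1L, which.max)), 1:3)
  # matched by pose: slot i holds the annotation it coincides with
  for (i in 1:3) {
    n <- which.max(p1[i, ])
    expect_equal(c(tracks$shoulder_x[1L, i], tracks$shoulder_y[1L, i]),
                 unname(sim$gt[[1L]]$shoulders[n, ]))
  }
  # later frames untouched (uniform here)
  expect_equal(log_e[2L, 1L, ], rep(log(1 / 3), 3))
  # wrong N errors
  bad <- sim$gt[[1L]]
  bad$identity <- 1:2
  expect_error(build_emissions(tracks, sim$frames, 3, init = bad), "N = 3")
})
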