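test_that("slot distance is the root of summed squared part distances", {
  a <- list(shoulder = c(0, 0), tail = c(10, 0))
  expect_equal(slot_distance(a, a), 0)
  b <- list(shoulder = c(3, 0), tail = c(10, 4))
  expect_equal(slot_distance(a, b), 5)
  expect_equal(slot_distance(b, a), slot_distance(a, b))
})

test_that("transition density matches the printed mixture", {
  expect_equal(transition_density(0), 0.6 * 0.9 + 0.3 / 6 + 0.1 / 30)
  expect_equal(transition_density(10),
               0.6 * 0.9 * exp(-9) + 0.05 * exp(-10 / 6) +
                 (0.1 / 30) * exp(-1 / 3))
  expect_error(transition_density(-1), "non-negative")
  # strictly decreasing and integrates to 1
  grid <- seq(0, 200, by = 0.5)
  vals <- transition_density(grid)
  expect_true(all(diff(vals) < 0))
  expect_equal(integrate(transition_density, 0, Inf)$value, 1,
               tolerance = 1e-6)
})

test_that("log_sum_exp handles extremes", {
  expect_equal(log_sum_exp(5), 5)
  expect_equal(log_sum_exp(c(-1000, -1000)), -1000 + log(2))
  expect_equal(log_sum_exp(c(0, -Inf)), 0)
  expect_equal(log_sum_exp(c(-Inf, -Inf)), -Inf)
  expect_error(log_sum_exp(numeric(0)), "non-empty")
})

test_that("forward and backward passes match exp-space hand computation", {
  tracks <- random_tracks(2, 2, seed = 17)
  set.seed(17)
  log_e <- random_emissions(2, 2, 2)
  lt <- pentrack:::.log_transition_matrices(tracks, motion_model(), TRUE)
  P <- exp(lt[[1L]])
  for (n in 1:2) {
    la <- forward_pass(log_e, tracks, motion_model(), n)
    expect_equal(la[1L, ], log_e[1L, , n])
    a2 <- exp(log_e[2L, , n]) * as.vector(P %*% exp(log_e[1L, , n]))
    expect_equal(la[2L, ], log(a2), tolerance = 1e-12)
    lb <- backward_pass(log_e, tracks, motion_model(), n)
    expect_equal(lb[2L, ], c(0, 0))
    b1 <- as.vector(t(P) %*% exp(log_e[2L, , n]))
    expect_equal(lb[1L, ], log(b1), tolerance = 1e-12)
    # forward-backward consistency: total likelihood constant in t
    tot <- apply(la + lb, 1L, log_sum_exp)
    expect_equal(tot[1L], tot[2L], tolerance = 1e-12)
  }
})

test_that("posterior marginals equal exhaustive path enumeration", {
  set.seed(18)
  for (rep in 1:10) {
    T_ <- sample(2:5, 1)
    N <- sample(2:3, 1)
    tracks <- random_tracks(T_, N, seed = 100 + rep)
    log_e <- random_emissions(T_, N, N)
    for (norm in c(TRUE, FALSE)) {
      post <- posterior_marginals(log_e, tracks, motion_model(),
                                  normalize_transitions = norm)$log_post
      oracle <- enum_posterior(log_e, tracks, motion_model(), norm)
      expect_lt(max(abs(post - oracle)), 1e-9)
    }
  }
})

test_that("uniform emissions give identity-independent posteriors", {
  tracks <- random_tracks(6, 3, seed = 19)
  log_e <- array(log(1 / 3), c(6, 3, 3))
  post <- posterior_marginals(log_e, tracks)$log_post
  expect_equal(post[, , 1L], post[, , 2L])
  expect_equal(post[, , 1L], post[, , 3L])
})

test_that("a single confident sighting pins an identity to its chain", {
  # three static, well-separated animals; identity 2 sighted once at t = 5
  pos <- lapply(1:12, function(t) {
    cbind(c(0, 200, 400), c(0, 0, 0), c(30, 230, 430), c(0, 0, 0))
  })
  tracks <- build_tracks(frames_from_positions(pos), 3)
  log_e <- array(log(1 / 3), c(12, 3, 3))
  v <- c(0.001, 0.998, 0.001)
  log_e[5L, 3L, ] <- log(v)  # slot 3 looks like identity 2 at t = 5
  post <- posterior_marginals(log_e, tracks)
  expect_true(all(apply(post$log_post[, , 2L], 1L, which.max) == 3L))
})

test_that("identity evidence survives a 10,000-frame gap where naive
           exp-space recursion underflows", {
  T_ <- 10000L
  pos <- lapply(seq_len(T_), function(t) {
    cbind(c(0, 300, 600), c(0, 0, 0), c(40, 340, 640), c(0, 0, 0))
  })
  tracks <- build_tracks(frames_from_positions(pos), 3)
  eps <- 1e-6
  row <- c(0.9, eps, 0.1 - eps)
  log_e <- array(NA_real_, c(T_, 3, 3))
  for (i in 1:3) {
    for (n in 1:3) log_e[, i, n] <- log(row[1 + ((n - i) %% 3)])
  }
  post <- posterior_marginals(log_e, tracks)
  expect_true(all(is.finite(post$log_post)))
  expect_true(all(is.finite(post$log_alpha)))
  expect_true(all(apply(post$log_post[, , 1L], 1L, which.max) == 1L))
  # the same input drives the plain exp-space recursion below the normal
  # floating-point range: every entry is zero or denormal
  naive <- pentrack:::.forward_pass_naive(log_e, tracks, motion_model(), 1L)
  expect_true(all(naive[T_, ] < 1e-300))
})

test_that("per-frame Hungarian on marginals recovers the permutation", {
  lp <- array(NA_real_, c(1, 2, 2))
  lp[1, , ] <- -rbind(c(1, 2), c(2, 1))
  expect_equal(assign_identities(lp)[1L, ], 1:2)

  set.seed(20)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    cost <- matrix(runif(N * N, 0, 5), N, N)
    lp <- array(NA_real_, c(1, N, N))
    lp[1, , ] <- -cost
    a <- assign_identities(lp)[1L, ]
    expect_equal(sum(cost[cbind(seq_len(N), a)]), perm_min_cost(cost),
                 tolerance = 1e-12)
  }

  sym <- array(log(1 / 3), c(2, 3, 3))
  expect_equal(assign_identities(sym), rbind(1:3, 1:3))
})

test_that("end-to-end scenarios behave on clean simulations", {
  # perfect detections and tags: exact recovery
  sim <- simulate_pen(noiseless_config(5, 80, seed = 23))
  res <- track_identities(sim$frames, N = 5, scenario = "uninitialized")
  expect_equal(precision_recall(sim$gt, res, "location_id")$precision, 1)

  # no tags, uninitialized: temporally consistent arbitrary labels
  cfg <- simulation_config(N = 5, T = 80, seed = 24, dropout_prob = 0,
                           fp_rate = 0, reversal_prob = 0,
                           assoc_noise_sd = 0, ear_visibility_prob = 0)
  sim2 <- simulate_pen(cfg)
  res2 <- track_identities(sim2$frames, N = 5, scenario = "uninitialized")
  expect_true(all(res2$ids[-1L, ] == res2$ids[-80L, ]))
  expect_equal(precision_recall(sim2$gt, res2, "location")$precision, 1)

  # no tags, initialized: ground truth recovered from frame 1 alone
  res3 <- track_identities(sim2$frames, N = 5, scenario = "initialized",
                           init = sim2$gt[[1L]])
  expect_equal(precision_recall(sim2$gt, res3, "location_id")$precision, 1)
  expect_error(track_identities(sim2$frames, N = 5, scenario = "initialized"),
               "init")
})
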