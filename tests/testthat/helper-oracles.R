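# Independent oracles and fixture builders used across the suite.

# all permutations of 1..n as an (n! x n) matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# brute-force minimum assignment cost over all permutations (square matrix)
perm_min_cost <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  min(vapply(seq_len(nrow(perms)), function(r) {
    sum(cost[cbind(seq_len(n), perms[r, ])])
  }, numeric(1)))
}

# exhaustive-path posterior marginals: enumerates all N^T slot paths per
# identity and sums their joint probabilities, normalised per frame
enum_posterior <- function(log_e, tracks, m, normalize_transitions = TRUE) {
  T_ <- dim(log_e)[[1L]]; N <- dim(log_e)[[2L]]; Nid <- dim(log_e)[[3L]]
  lt <- pentrack:::.log_transition_matrices(tracks, m, normalize_transitions)
  out <- array(NA_real_, dim(log_e))
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  for (n in seq_len(Nid)) {
    lp <- vapply(seq_len(nrow(paths)), function(r) {
      p <- paths[r, ]
      v <- log_e[1L, p[[1L]], n]
      for (t in seq_len(T_)[-1L]) {
        v <- v + lt[[t - 1L]][p[[t]], p[[t - 1L]]] + log_e[t, p[[t]], n]
      }
      v
    }, numeric(1))
    for (t in seq_len(T_)) {
      for (i in seq_len(N)) {
        out[t, i, n] <- log_sum_exp(lp[paths[, t] == i])
      }
      out[t, , n] <- out[t, , n] - log_sum_exp(out[t, , n])
    }
  }
  out
}

# frames with exact detections at given positions; pos[[t]] is an n_t x 4
# matrix of (shoulder_x, shoulder_y, tail_x, tail_y)
frames_from_positions <- function(pos) {
  lapply(seq_along(pos), function(t) {
    p <- pos[[t]]
    ins <- if (is.null(p) || nrow(p) == 0L) list() else {
      lapply(seq_len(nrow(p)), function(i) {
        instance_detection(shoulder = p[i, 1:2], tail = p[i, 3:4])
      })
    }
    frame_detections(t, instances = ins)
  })
}

# a normalised random emission tensor
random_emissions <- function(T_, n_slots, n_id) {
  log_e <- array(log(runif(T_ * n_slots * n_id, 0.01, 1)),
                 c(T_, n_slots, n_id))
  for (t in seq_len(T_)) {
    for (i in seq_len(n_slots)) {
      log_e[t, i, ] <- log_e[t, i, ] - log_sum_exp(log_e[t, i, ])
    }
  }
  log_e
}

# random well-formed track_set built from random-walk detections
random_tracks <- function(T_, N, seed) {
  set.seed(seed)
  pos <- vector("list", T_)
  cur <- cbind(runif(N, 0, 200), runif(N, 0, 200))
  for (t in seq_len(T_)) {
    cur <- cur + matrix(rnorm(2 * N, 0, 3), ncol = 2)
    pos[[t]] <- cbind(cur, cur + 15)
  }
  build_tracks(frames_from_positions(pos), N)
}

# noiseless simulation configuration: detections equal ground truth
noiseless_config <- function(N, T, seed, ...) {
  simulation_config(N = N, T = T, seed = seed, dropout_prob = 0,
                    fp_rate = 0, reversal_prob = 0, assoc_noise_sd = 0,
                    ear_visibility_prob = 1, tag_confusion = diag(N),
                    unknown_tag_prob = 0, ...)
}
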