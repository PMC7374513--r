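#' @title Identity inference by forward-backward smoothing
#' @description
#' Given N continuous track slots and per-slot identity emissions, each
#' identity's occupancy over slots is modelled as a hidden Markov chain
#' whose transition weight between a slot in frame t-1 and a slot in frame
#' t is the stay-put exponential-mixture density of their pose
#' displacement. Posterior marginals are computed per identity with the
#' log-sum-exp-stabilised forward-backward algorithm, and the per-frame
#' slot-to-identity map is the Hungarian assignment minimising the summed
#' negative log posteriors.
#' @name map_inference
NULL

#' Pose displacement between track entries
#'
#' Root of the summed squared shoulder and tail Euclidean distances between
#' two (shoulder, tail) poses -- the displacement fed to the stay-put
#' motion model.
#'
#' @param a,b Poses: lists with `shoulder` and `tail` length-2 coordinates.
#' @return Non-negative displacement.
#' @export
slot_distance <- function(a, b) {
  sqrt(.pt_dist(a$shoulder, b$shoulder)^2 + .pt_dist(a$tail, b$tail)^2)
}

# list of T-1 log transition matrices; element t has [i, j] =
# log p(slot i at t+1 | slot j at t). With normalize = TRUE each source
# slot's outgoing weights form a distribution over destination slots, so a
# fast-moving chain is not penalised against a resting one; FALSE keeps
# the raw density values.
.log_transition_matrices <- function(tracks, m, normalize = TRUE) {
  T_ <- tracks$T
  out <- vector("list", max(T_ - 1L, 0L))
  for (t in seq_len(T_ - 1L)) {
    delta <- .pose_delta_matrix(
      tracks$shoulder_x[t + 1L, ], tracks$shoulder_y[t + 1L, ],
      tracks$tail_x[t + 1L, ], tracks$tail_y[t + 1L, ],
      tracks$shoulder_x[t, ], tracks$shoulder_y[t, ],
      tracks$tail_x[t, ], tracks$tail_y[t, ]
    )
    lt <- log(transition_density(delta, m))
    dim(lt) <- dim(delta)
    if (normalize) {
      lt <- lt - rep(.row_lse(t(lt)), each = nrow(lt))
    }
    out[[t]] <- lt
  }
  out
}

# log-space matrix-vector product: returns vector r with
# r[i] = log sum_j exp(M[i, j] + a[j]), stabilised per row
.log_mat_vec <- function(M, a) {
  .row_lse(M + rep(a, each = nrow(M)))
}

#' Forward pass for one identity
#'
#' Computes `log alpha[t, i] = log p(I_1:t, slot i at t | identity n)` by
#' the stabilised recursion: `log alpha_1 = log e_1`, then
#' `log alpha_t(i) = log e_t(i) + LSE_j(log alpha_{t-1}(j) + log p(i | j))`,
#' where the log-sum-exp subtracts the running maximum so centuries-long
#' sequences of small probabilities stay in range.
#'
#' @param emissions `T x N x N` log emission array from
#'   [build_emissions()].
#' @param tracks The `track_set` the emissions were built on.
#' @param m A [motion_model()].
#' @param n Identity index.
#' @param log_trans Optional precomputed list of log transition matrices
#'   (shared across identities by [posterior_marginals()]).
#' @param normalize_transitions Normalise each source slot's outgoing
#'   transition weights to a distribution over destination slots (default).
#'   `FALSE` uses the raw mixture density values; note that raw densities
#'   systematically favour chains that move little, so identity evidence
#'   decays toward resting animals during stretches without tag sightings.
#' @return `T x N` matrix of log forward probabilities.
#' @export
forward_pass <- function(emissions, tracks, m = motion_model(), n,
                         log_trans = NULL, normalize_transitions = TRUE) {
  T_ <- dim(emissions)[[1L]]
  N_slots <- dim(emissions)[[2L]]
  if (is.null(log_trans)) {
    log_trans <- .log_transition_matrices(tracks, m, normalize_transitions)
  }
  la <- matrix(NA_real_, nrow = T_, ncol = N_slots)
  la[1L, ] <- emissions[1L, , n]
  for (t in seq_len(T_)[-1L]) {
    la[t, ] <- emissions[t, , n] + .log_mat_vec(log_trans[[t - 1L]],
                                                la[t - 1L, ])
  }
  la
}

#' Backward pass for one identity
#'
#' `log beta[T, i] = 0` (terminal condition), then
#' `log beta_t(i) = LSE_j(log beta_{t+1}(j) + log p(j at t+1 | i at t)
#' + log e_{t+1}(j))`, stabilised as in the forward pass.
#'
#' @inheritParams forward_pass
#' @return `T x N` matrix of log backward probabilities.
#' @export
backward_pass <- function(emissions, tracks, m = motion_model(), n,
                          log_trans = NULL, normalize_transitions = TRUE) {
  T_ <- dim(emissions)[[1L]]
  N_slots <- dim(emissions)[[2L]]
  if (is.null(log_trans)) {
    log_trans <- .log_transition_matrices(tracks, m, normalize_transitions)
  }
  lb <- matrix(NA_real_, nrow = T_, ncol = N_slots)
  lb[T_, ] <- 0
  for (t in rev(seq_len(T_ - 1L))) {
    # transition from slot i at t to slot j at t+1: log_trans[[t]][j, i]
    lb[t, ] <- .log_mat_vec(t(log_trans[[t]]),
                            lb[t + 1L, ] + emissions[t + 1L, , n])
  }
  lb
}

#' Posterior marginals of identity occupancy
#'
#' Runs the forward and backward passes for every identity (sharing the
#' transition matrices) and returns
#' `log_post[t, i, n] = log alpha + log beta`, normalised per `(t, n)` over
#' slots so each identity's posterior over slots sums to one in every
#' frame.
#'
#' @inheritParams forward_pass
#' @return Object of class `posterior_tensor`: list with the `T x N x N`
#'   arrays `log_post`, `log_alpha`, `log_beta`.
#' @export
posterior_marginals <- function(emissions, tracks, m = motion_model(),
                                normalize_transitions = TRUE) {
  dims <- dim(emissions)
  T_ <- dims[[1L]]; N_slots <- dims[[2L]]; N_id <- dims[[3L]]
  log_trans <- .log_transition_matrices(tracks, m, normalize_transitions)
  log_post <- array(NA_real_, dims)
  log_alpha <- array(NA_real_, dims)
  log_beta <- array(NA_real_, dims)
  for (n in seq_len(N_id)) {
    la <- forward_pass(emissions, tracks, m, n, log_trans)
    lb <- backward_pass(emissions, tracks, m, n, log_trans)
    lp <- la + lb
    lp <- lp - .row_lse(lp)  # normalise over slots per frame
    log_post[, , n] <- lp
    log_alpha[, , n] <- la
    log_beta[, , n] <- lb
  }
  structure(list(log_post = log_post, log_alpha = log_alpha,
                 log_beta = log_beta),
            class = "posterior_tensor")
}

# naive exp-space forward recursion, kept as the unstabilised reference
# that demonstrates why the log-sum-exp formulation is needed
.forward_pass_naive <- function(emissions, tracks, m, n, log_trans = NULL) {
  T_ <- dim(emissions)[[1L]]
  if (is.null(log_trans)) log_trans <- .log_transition_matrices(tracks, m)
  a <- matrix(NA_real_, nrow = T_, ncol = dim(emissions)[[2L]])
  a[1L, ] <- exp(emissions[1L, , n])
  for (t in seq_len(T_)[-1L]) {
    a[t, ] <- exp(emissions[t, , n]) *
      as.vector(exp(log_trans[[t - 1L]]) %*% a[t - 1L, ])
  }
  a
}

#' Per-frame identity assignment from posterior marginals
#'
#' For each frame, solves the N x N Hungarian assignment minimising the sum
#' of `-log_post[t, slot, identity]` over slot-identity bijections. With an
#' identity-symmetric posterior the assignment is the identity permutation
#' (deterministic tie-break toward lower slot index).
#'
#' @param post A `posterior_tensor` from [posterior_marginals()], or a bare
#'   `T x N x N` log posterior array.
#' @return `T x N` integer matrix; entry `[t, i]` is the identity assigned
#'   to slot i in frame t (a permutation of `1..N` per frame).
#' @export
assign_identities <- function(post) {
  lp <- if (inherits(post, "posterior_tensor")) post$log_post else post
  T_ <- dim(lp)[[1L]]
  N <- dim(lp)[[2L]]
  ids <- matrix(NA_integer_, nrow = T_, ncol = N)
  for (t in seq_len(T_)) {
    cost <- -lp[t, , ]
    # clamp infinities: a zero-probability cell must stay assignable
    cost[!is.finite(cost)] <- .Machine$double.xmax / (N + 1)
    ids[t, ] <- solve_assignment(cost)
  }
  ids
}

#' Track and identify all animals in a detection sequence
#'
#' End-to-end pipeline: prune each frame to at most N instances, build N
#' continuous tracks, assemble ear-tag emissions, smooth identity
#' posteriors with forward-backward, and assign per-frame identities by
#' Hungarian matching. Three scenarios are supported: `"location"` (tracks
#' only; slot indices stand in for identities), `"initialized"`
#' (first-frame identity annotations provided) and `"uninitialized"`
#' (identities must be inferred from intermittent tag sightings alone).
#'
#' @param frames List of `frame_detections` (see
#'   [read_detection_sequence()]).
#' @param N Number of housed animals.
#' @param scenario One of `"location"`, `"initialized"`,
#'   `"uninitialized"`.
#' @param m A [motion_model()].
#' @param init First-frame ground-truth annotations; required for (and
#'   only used by) the initialized scenario.
#' @param keep_posterior Keep the posterior tensor in the result (memory
#'   grows as `T N^2`).
#' @param floor_prob Emission probability floor.
#' @param normalize_transitions See [forward_pass()].
#' @return Object of class `pentrack_result`: list with `tracks`
#'   (`track_set`), `ids` (`T x N` identity matrix), `scenario`, `N`, `T`
#'   and optionally `posterior`.
#' @examples
#' sim <- simulate_pen(simulation_config(N = 4, T = 40, seed = 1))
#' res <- track_identities(sim$frames, N = 4, scenario = "uninitialized")
#' res
#' @export
track_identities <- function(frames, N,
                             scenario = c("uninitialized", "initialized",
                                          "location"),
                             m = motion_model(), init = NULL,
                             keep_posterior = FALSE, floor_prob = 1e-6,
                             normalize_transitions = TRUE) {
  scenario <- match.arg(scenario)
  if (scenario == "initialized" && is.null(init)) {
    stop("the initialized scenario requires first-frame annotations (init)")
  }
  pruned <- lapply(frames, prune_frame, N = N)
  tracks <- build_tracks(pruned, N)
  T_ <- tracks$T
  if (scenario == "location") {
    ids <- matrix(rep(seq_len(N), each = T_), nrow = T_)
    res <- list(tracks = tracks, ids = ids, scenario = scenario,
                N = tracks$N, T = T_)
    class(res) <- "pentrack_result"
    return(res)
  }
  emis <- build_emissions(tracks, pruned, N,
                          init = if (scenario == "initialized") init,
                          floor_prob = floor_prob)
  post <- posterior_marginals(emis, tracks, m, normalize_transitions)
  ids <- assign_identities(post)
  res <- list(tracks = tracks, ids = ids, scenario = scenario,
              N = tracks$N, T = T_)
  if (keep_posterior) res$posterior <- post
  class(res) <- "pentrack_result"
  res
}

#' @export
print.pentrack_result <- function(x, ...) {
  cat("pentrack result (", x$scenario, " scenario): ", x$N,
      " animals x ", x$T, " frames\n", sep = "")
  print(x$tracks)
  if (x$scenario != "location") {
    swaps <- sum(x$ids[-1L, , drop = FALSE] !=
                   x$ids[-nrow(x$ids), , drop = FALSE]) / 2
    cat("identity relabelling events between adjacent frames:", swaps, "\n")
  }
  invisible(x)
}

#' @export
summary.pentrack_result <- function(object, ...) {
  interp_per_slot <- colMeans(object$tracks$origin != "detected")
  out <- list(scenario = object$scenario, N = object$N, T = object$T,
              interpolated_fraction = mean(interp_per_slot),
              interpolated_per_slot = interp_per_slot)
  class(out) <- "summary.pentrack_result"
  out
}

#' @export
print.summary.pentrack_result <- function(x, ...) {
  cat("Scenario:", x$scenario, "\n")
  cat("Animals:", x$N, "  Frames:", x$T, "\n")
  cat("Interpolated entries:",
      format(100 * x$interpolated_fraction, digits = 3), "%\n")
  invisible(x)
}

#' Predicted identified poses from a tracking result
#'
#' Re-orders each frame's slots by assigned identity so row n holds the
#' pose predicted for animal n, in the layout [read_ground_truth()] uses.
#'
#' @param res A `pentrack_result`.
#' @return List of frames with `t`, `identity`, `shoulders`, `tails`.
#' @export
identified_poses <- function(res) {
  stopifnot(inherits(res, "pentrack_result"))
  tr <- res$tracks
  lapply(seq_len(res$T), function(t) {
    ord <- order(res$ids[t, ])  # slot occupied by identity n
    list(t = t,
         identity = seq_len(res$N),
         shoulders = cbind(tr$shoulder_x[t, ord], tr$shoulder_y[t, ord]),
         tails = cbind(tr$tail_x[t, ord], tr$tail_y[t, ord]))
  })
}
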