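#' @title Synthetic pen simulator
#' @description
#' Generates ground-truth trajectories for N animals in a rectangular pen
#' together with corrupted detector-like observations, so the whole
#' tracking pipeline is testable without cameras or networks. Trajectories
#' are correlated random walks whose per-frame pose displacement follows
#' the stay-put exponential mixture exactly by construction; observations
#' are the true poses subjected to dropout, false positives, occasional
#' shoulder/tail reversal, Gaussian noise on association vectors, and an
#' intermittent, configurable-confusion ear-tag classifier.
#' @name synthetic
NULL

#' Uniform-off-diagonal tag-confusion matrix
#'
#' @param N Number of identities.
#' @param accuracy Probability mass on the true identity; the remainder is
#'   spread evenly over the other identities.
#' @return `N x N` row-stochastic matrix.
#' @export
confusion_matrix <- function(N, accuracy = 0.9) {
  stopifnot(N >= 1, accuracy >= 0, accuracy <= 1)
  if (N == 1L) return(matrix(1, 1, 1))
  m <- matrix((1 - accuracy) / (N - 1), N, N)
  diag(m) <- accuracy
  m
}

#' Simulation configuration
#'
#' Defaults mirror the recorded-pen setting the tracker was designed for:
#' 16 animals filmed top-down at 5 fps, working resolution 1024 x 576
#' pixels, body length about 60 px at that scale, and the default
#' [motion_model()] as the per-frame displacement law.
#'
#' @param N Number of animals.
#' @param T Number of frames.
#' @param pen Pen width and height in pixels, `c(width, height)`.
#' @param body_length Mean and standard deviation of shoulder-tail length
#'   in pixels, `c(mean, sd)`.
#' @param step_model [motion_model()] for per-frame pose displacements.
#' @param heading_persistence In `[0, 1]`; 1 means headings never turn.
#' @param dropout_prob Per-animal per-frame probability the detector
#'   misses it.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @param reversal_prob Probability a detection swaps shoulder and tail.
#' @param assoc_noise_sd Pixel standard deviation of noise on association
#'   vector estimates.
#' @param ear_visibility_prob Per-ear per-frame visibility probability.
#' @param tag_confusion `N x N` row-stochastic classifier confusion
#'   matrix; row n is reported when animal n's tag is read.
#' @param unknown_tag_prob Probability a visible tag is reported as the
#'   uniform ("unknown tag") vector instead.
#' @param pile_attraction Strength in `[0, 1)` of a pull toward the pen
#'   centre, emulating animals piling together (0 disables).
#' @param seed Integer RNG seed; simulation is deterministic given it.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(N = 16, T = 9000,
                              pen = c(width = 1024, height = 576),
                              body_length = c(mean = 60, sd = 6),
                              step_model = motion_model(),
                              heading_persistence = 0.9,
                              dropout_prob = 0.05,
                              fp_rate = 0.2,
                              reversal_prob = 0.01,
                              assoc_noise_sd = 2,
                              ear_visibility_prob = 0.3,
                              tag_confusion = confusion_matrix(N, 0.9),
                              unknown_tag_prob = 0.2,
                              pile_attraction = 0,
                              seed = 1) {
  cfg <- list(N = as.integer(N), T = as.integer(T),
              pen = as.numeric(pen), body_length = as.numeric(body_length),
              step_model = step_model,
              heading_persistence = heading_persistence,
              dropout_prob = dropout_prob, fp_rate = fp_rate,
              reversal_prob = reversal_prob,
              assoc_noise_sd = assoc_noise_sd,
              ear_visibility_prob = ear_visibility_prob,
              tag_confusion = as.matrix(tag_confusion),
              unknown_tag_prob = unknown_tag_prob,
              pile_attraction = pile_attraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(N >= 1, T >= 1, length(pen) == 2, all(pen > 0),
              length(body_length) == 2, body_length[[1L]] > 0,
              body_length[[2L]] >= 0,
              inherits(step_model, "motion_model"),
              heading_persistence >= 0, heading_persistence <= 1,
              dropout_prob >= 0, dropout_prob <= 1,
              fp_rate >= 0, reversal_prob >= 0, reversal_prob <= 1,
              assoc_noise_sd >= 0,
              ear_visibility_prob >= 0, ear_visibility_prob <= 1,
              unknown_tag_prob >= 0, unknown_tag_prob <= 1,
              pile_attraction >= 0, pile_attraction < 1)
    if (!all(dim(tag_confusion) == c(N, N))) {
      stop("tag_confusion must be N x N")
    }
    if (any(tag_confusion < 0) ||
        any(abs(rowSums(tag_confusion) - 1) > 1e-9)) {
      stop("tag_confusion rows must be non-negative and sum to 1")
    }
    # rough capacity check: each animal claims a body-length square
    if (N * body_length[[1L]]^2 > 0.5 * prod(pen)) {
      stop("pen too small to place ", N, " animals of this body length")
    }
  })
  structure(cfg, class = "simulation_config")
}

#' Scenario presets
#'
#' Qualitative analogues of the recorded video grid: activity level scales
#' the displacement mixture, and "night" (infrared) settings reduce ear
#' visibility and tag-classifier accuracy.
#'
#' @param name One of `"day_high"`, `"day_medium"`, `"day_low"`,
#'   `"night_medium"`, `"night_low"`.
#' @param ... Overrides passed on to [simulation_config()] (e.g. `N`, `T`,
#'   `seed`).
#' @return A `simulation_config`.
#' @export
scenario_presets <- function(name = c("day_high", "day_medium", "day_low",
                                      "night_medium", "night_low"), ...) {
  name <- match.arg(name)
  parts <- strsplit(name, "_")[[1L]]
  lighting <- parts[[1L]]
  activity <- parts[[2L]]
  # activity scales the mixture: rates / s gives mean displacement * s
  s <- switch(activity, high = 1.6, medium = 1.0, low = 0.5)
  m <- motion_model(rates = motion_model()$rates / s)
  base <- list(
    step_model = m,
    ear_visibility_prob = if (lighting == "day") 0.08 else 0.03,
    unknown_tag_prob = if (lighting == "day") 0.2 else 0.4,
    dropout_prob = 0.05, fp_rate = 0.2
  )
  dots <- list(...)
  N <- if (!is.null(dots$N)) dots$N else 16
  base$tag_confusion <- confusion_matrix(N, if (lighting == "day") 0.9 else 0.75)
  do.call(simulation_config, modifyList(base, dots))
}

# unit heading vector
.heading_vec <- function(theta) cbind(cos(theta), sin(theta))

#' Simulate a pen of animals and their detections
#'
#' Animals perform correlated random walks clipped to the pen: each frame a
#' target pose displacement is drawn from the step model, the heading
#' drifts by a persistence-controlled wrapped-Gaussian turn (capped so the
#' tail swing cannot exceed the drawn displacement), and the forward step
#' is solved so the realised shoulder-plus-tail displacement equals the
#' draw exactly. Detections are the true poses with dropout, Poisson false
#' positives uniform in the pen, occasional shoulder/tail reversal, and
#' association estimates equal to the true partner plus Gaussian noise;
#' part scores decay from 1 with the applied noise, never below 0.25.
#' Visible ears report the confusion row of the true identity, or the
#' uniform vector with probability `unknown_tag_prob`.
#'
#' @param config A [simulation_config()].
#' @return List with `gt` (ground-truth frames), `frames`
#'   (`frame_detections` list) and `config`. Deterministic given
#'   `config$seed`; the caller's RNG state is untouched.
#' @export
simulate_pen <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .simulate_pen_impl(config))
}

.simulate_pen_impl <- function(cfg) {
  N <- cfg$N; T_ <- cfg$T
  W <- cfg$pen[[1L]]; H <- cfg$pen[[2L]]
  Lmean <- cfg$body_length[[1L]]; Lsd <- cfg$body_length[[2L]]
  body_len <- pmax(Lmean / 4, rnorm(N, Lmean, Lsd))
  margin <- Lmean / 2
  turn_sd <- pi * (1 - cfg$heading_persistence)

  # state
  sx <- runif(N, margin, W - margin)
  sy <- runif(N, margin, H - margin)
  theta <- runif(N, -pi, pi)
  ear_off_fwd <- 0.15; ear_off_lat <- 0.2  # fractions of body length

  gt <- vector("list", T_)
  frames <- vector("list", T_)

  snap_gt <- function(t) {
    u <- .heading_vec(theta)
    list(t = t, identity = seq_len(N),
         shoulders = cbind(sx, sy),
         tails = cbind(sx - body_len * u[, 1L], sy - body_len * u[, 2L]))
  }

  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

  step_all <- function() {
    delta <- simulate(cfg$step_model, N)
    if (cfg$pile_attraction > 0) {
      # bias headings toward the pen centre
      to_c <- atan2(H / 2 - sy, W / 2 - sx)
      d <- to_c - theta
      theta <<- theta + cfg$pile_attraction * atan2(sin(d), cos(d))
    }
    phi <- rnorm(N, 0, turn_sd)
    # cap the turn so the tail swing is at most 60% of the drawn step
    max_phi <- 2 * asin(pmin(1, 0.6 * delta / (2 * body_len)))
    phi <- sign(phi) * pmin(abs(phi), max_phi)
    u_old <- .heading_vec(theta)
    theta_new <- theta + phi
    u_new <- .heading_vec(theta_new)
    w <- body_len * (u_old - u_new)           # tail swing vector
    c2 <- rowSums(w^2)
    b <- rowSums(u_new * w)
    disc <- pmax(b^2 + 2 * (delta^2 - c2), 0)
    d <- pmax((-b + sqrt(disc)) / 2, 0)       # forward step length
    sx_new <- clamp(sx + d * u_new[, 1L], margin, W - margin)
    sy_new <- clamp(sy + d * u_new[, 2L], margin, H - margin)
    # on wall contact, bounce the heading back toward the interior
    hit <- (sx_new != sx + d * u_new[, 1L]) | (sy_new != sy + d * u_new[, 2L])
    if (any(hit)) {
      theta_new[hit] <- atan2(H / 2 - sy_new[hit], W / 2 - sx_new[hit]) +
        rnorm(sum(hit), 0, 0.3)
    }
    sx <<- sx_new; sy <<- sy_new; theta <<- theta_new
  }

  noisy <- function(p, sd) p + rnorm(2, 0, sd)
  score_from_noise <- function(err, sd) {
    if (sd <= 0) return(1)
    max(0.25, exp(-err / (2 * sd)))
  }

  make_instance <- function(s, tl, le, re, sd, reversed, score_lo = NULL) {
    est_st <- noisy(s, sd); est_ts <- noisy(tl, sd)
    est_le <- noisy(le, sd); est_re <- noisy(re, sd)
    ss <- if (is.null(score_lo)) {
      score_from_noise(.pt_dist(est_st, s), sd)
    } else runif(1, score_lo[1L], score_lo[2L])
    ts <- if (is.null(score_lo)) {
      score_from_noise(.pt_dist(est_ts, tl), sd)
    } else runif(1, score_lo[1L], score_lo[2L])
    if (reversed) {
      instance_detection(shoulder = tl, tail = s,
                         shoulder_score = ts, tail_score = ss,
                         est_shoulder_from_tail = est_ts,
                         est_tail_from_shoulder = est_st,
                         est_left_ear = est_re, est_right_ear = est_le)
    } else {
      instance_detection(shoulder = s, tail = tl,
                         shoulder_score = ss, tail_score = ts,
                         est_shoulder_from_tail = est_st,
                         est_tail_from_shoulder = est_ts,
                         est_left_ear = est_le, est_right_ear = est_re)
    }
  }

  for (t in seq_len(T_)) {
    if (t > 1L) step_all()
    g <- snap_gt(t)
    gt[[t]] <- g
    u <- .heading_vec(theta)
    perp <- cbind(-u[, 2L], u[, 1L])
    head_pt <- g$shoulders + ear_off_fwd * body_len * u
    ear_l <- head_pt + ear_off_lat * body_len * perp
    ear_r <- head_pt - ear_off_lat * body_len * perp

    instances <- list()
    ears <- list()
    detected <- runif(N) >= cfg$dropout_prob
    for (n in seq_len(N)) {
      if (detected[[n]]) {
        reversed <- runif(1) < cfg$reversal_prob
        instances[[length(instances) + 1L]] <- make_instance(
          g$shoulders[n, ], g$tails[n, ], ear_l[n, ], ear_r[n, ],
          cfg$assoc_noise_sd, reversed
        )
      }
      for (side in c("left", "right")) {
        if (runif(1) >= cfg$ear_visibility_prob) next
        loc <- if (side == "left") ear_l[n, ] else ear_r[n, ]
        probs <- if (runif(1) < cfg$unknown_tag_prob) {
          rep(1 / N, N)
        } else cfg$tag_confusion[n, ]
        ears[[length(ears) + 1L]] <- ear_observation(
          side = side, location = loc,
          tag_probs = probs,
          est_shoulder = noisy(g$shoulders[n, ], cfg$assoc_noise_sd)
        )
      }
    }
    n_fp <- rpois(1, cfg$fp_rate)
    for (k in seq_len(n_fp)) {
      fs <- c(runif(1, margin, W - margin), runif(1, margin, H - margin))
      ang <- runif(1, -pi, pi)
      fl <- max(Lmean / 4, rnorm(1, Lmean, Lsd))
      ft <- fs - fl * c(cos(ang), sin(ang))
      fhead <- fs + ear_off_fwd * fl * c(cos(ang), sin(ang))
      fperp <- c(-sin(ang), cos(ang))
      instances[[length(instances) + 1L]] <- make_instance(
        fs, ft, fhead + ear_off_lat * fl * fperp,
        fhead - ear_off_lat * fl * fperp,
        5 * cfg$assoc_noise_sd + 5, reversed = FALSE,
        score_lo = c(0.25, 0.5)
      )
    }
    frames[[t]] <- frame_detections(t, instances, ears)
  }
  list(gt = gt, frames = frames, config = cfg)
}
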