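#' @title Detection data model and file formats
#' @description
#' Raw detector output for one video is a sequence of per-frame records: a
#' variable number of animal instances (paired shoulder/tail keypoints with
#' part scores and part-association estimates) plus a variable number of ear
#' observations (ear keypoint, side, estimated shoulder position and a
#' tag-classifier probability vector over the N housed identities). On disk
#' this is JSON-lines, one frame per line; tracks and ground truth are CSV.
#' Coordinates are real-valued pixels, origin top-left, x = column, y = row.
#' @name detections_io
NULL

.SCORE_MIN <- 0.25

#' Construct a single animal instance detection
#'
#' @param shoulder,tail Length-2 numeric shoulder/tail coordinates; must
#'   differ (a zero body length breaks the cost normalisation).
#' @param shoulder_score,tail_score Part detection scores in `[0.25, 1]`
#'   (parts scoring below 0.25 are not detected and never reach this stage).
#' @param est_shoulder_from_tail Shoulder position estimated from the tail
#'   keypoint's association vector; defaults to `shoulder` (a perfect
#'   estimate) when the detector supplies none.
#' @param est_tail_from_shoulder Tail position estimated from the shoulder;
#'   defaults to `tail`.
#' @param est_left_ear,est_right_ear Optional estimated ear positions from
#'   the shoulder's association vectors.
#' @return A list of class `instance_detection`.
#' @export
instance_detection <- function(shoulder, tail,
                               shoulder_score = 1, tail_score = 1,
                               est_shoulder_from_tail = NULL,
                               est_tail_from_shoulder = NULL,
                               est_left_ear = NULL,
                               est_right_ear = NULL) {
  shoulder <- .as_point(shoulder, "shoulder")
  tail <- .as_point(tail, "tail")
  if (all(shoulder == tail)) {
    stop("shoulder and tail must differ")
  }
  for (s in c(shoulder_score, tail_score)) {
    if (!is.numeric(s) || length(s) != 1L || is.na(s) ||
        s < .SCORE_MIN || s > 1) {
      stop("part scores must lie in [0.25, 1]")
    }
  }
  est_st <- if (is.null(est_shoulder_from_tail)) shoulder else
    .as_point(est_shoulder_from_tail, "est_shoulder_from_tail")
  est_ts <- if (is.null(est_tail_from_shoulder)) tail else
    .as_point(est_tail_from_shoulder, "est_tail_from_shoulder")
  if (!is.null(est_left_ear)) est_left_ear <- .as_point(est_left_ear)
  if (!is.null(est_right_ear)) est_right_ear <- .as_point(est_right_ear)
  structure(
    list(shoulder = shoulder, tail = tail,
         shoulder_score = as.numeric(shoulder_score),
         tail_score = as.numeric(tail_score),
         est_shoulder_from_tail = est_st,
         est_tail_from_shoulder = est_ts,
         est_left_ear = est_left_ear,
         est_right_ear = est_right_ear),
    class = "instance_detection"
  )
}

#' Construct an ear-tag observation
#'
#' @param side `"left"` or `"right"`.
#' @param location Length-2 numeric ear coordinates.
#' @param tag_probs Probability vector over the N housed identities produced
#'   by the tag classifier (an upstream "unknown tag" class is expected to
#'   arrive already spread uniformly); non-negative, summing to 1.
#' @param est_shoulder Optional estimated shoulder position from the ear's
#'   association vector.
#' @return A list of class `ear_observation`.
#' @export
ear_observation <- function(side, location, tag_probs, est_shoulder = NULL) {
  side <- match.arg(side, c("left", "right"))
  location <- .as_point(location, "ear location")
  tag_probs <- as.numeric(tag_probs)
  if (length(tag_probs) < 1L || anyNA(tag_probs) || any(tag_probs < 0)) {
    stop("tag_probs must be non-negative")
  }
  if (abs(sum(tag_probs) - 1) > 1e-9) {
    stop("tag_probs must sum to 1 (got ", format(sum(tag_probs)), ")")
  }
  if (!is.null(est_shoulder)) {
    est_shoulder <- .as_point(est_shoulder, "est_shoulder")
  }
  structure(
    list(side = side, location = location, est_shoulder = est_shoulder,
         tag_probs = tag_probs),
    class = "ear_observation"
  )
}

#' Construct one frame of detections
#'
#' @param t Frame index, integer `>= 1`.
#' @param instances List of [instance_detection()] objects (any count; the
#'   detector may over- or under-detect relative to the true N).
#' @param ears List of [ear_observation()] objects.
#' @return A list of class `frame_detections`.
#' @export
frame_detections <- function(t, instances = list(), ears = list()) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 1 ||
      t != round(t)) {
    stop("t must be an integer >= 1")
  }
  stopifnot(is.list(instances), is.list(ears))
  for (d in instances) {
    if (!inherits(d, "instance_detection")) {
      stop("instances must be instance_detection objects")
    }
  }
  for (e in ears) {
    if (!inherits(e, "ear_observation")) {
      stop("ears must be ear_observation objects")
    }
  }
  structure(list(t = as.integer(t), instances = instances, ears = ears),
            class = "frame_detections")
}

.parse_instance_json <- function(obj, line) {
  get_pt <- function(name, default = NULL) {
    if (is.null(obj[[name]])) return(default)
    .as_point(obj[[name]], name)
  }
  tryCatch(
    instance_detection(
      shoulder = .as_point(obj$shoulder, "shoulder"),
      tail = .as_point(obj$tail, "tail"),
      shoulder_score = if (is.null(obj$shoulder_score)) 1 else obj$shoulder_score,
      tail_score = if (is.null(obj$tail_score)) 1 else obj$tail_score,
      est_shoulder_from_tail = get_pt("est_shoulder_from_tail"),
      est_tail_from_shoulder = get_pt("est_tail_from_shoulder"),
      est_left_ear = get_pt("est_left_ear"),
      est_right_ear = get_pt("est_right_ear")
    ),
    error = function(e) {
      stop(sprintf("line %d: invalid instance: %s", line,
                   conditionMessage(e)), call. = FALSE)
    }
  )
}

.parse_ear_json <- function(obj, line) {
  tryCatch(
    ear_observation(
      side = obj$side,
      location = .as_point(obj$location, "location"),
      tag_probs = unlist(obj$tag_probs, use.names = FALSE),
      est_shoulder = if (is.null(obj$est_shoulder)) NULL else
        .as_point(obj$est_shoulder, "est_shoulder")
    ),
    error = function(e) {
      stop(sprintf("line %d: invalid ear observation: %s", line,
                   conditionMessage(e)), call. = FALSE)
    }
  )
}

#' Read a detection sequence from a JSON-lines file
#'
#' One JSON object per line, each with fields `t`, `instances` and `ears`
#' mirroring [frame_detections()] (coordinates as `[x, y]` arrays). Frames
#' are returned sorted by `t`, with any missing frame in `1..max(t)` filled
#' by an empty frame, so downstream code can rely on a contiguous sequence.
#'
#' @param path Path to a JSON-lines detection file.
#' @return List of `frame_detections`, one per frame `1..T`, in order. The
#'   optional per-file `resolution` metadata (a `[width, height]` array on
#'   any line) is attached as an attribute.
#' @export
read_detection_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  frames <- list()
  seen_t <- integer(0)
  resolution <- NULL
  for (i in lines_keep) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("parse error on line %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
    if (is.null(obj$t)) stop(sprintf("line %d: missing frame index 't'", i))
    t <- obj$t
    if (t %in% seen_t) stop(sprintf("line %d: duplicate frame index t=%s", i, t))
    seen_t <- c(seen_t, as.integer(t))
    if (!is.null(obj$resolution)) {
      resolution <- as.numeric(unlist(obj$resolution))
    }
    instances <- lapply(obj$instances, .parse_instance_json, line = i)
    ears <- lapply(obj$ears, .parse_ear_json, line = i)
    frames[[length(frames) + 1L]] <- frame_detections(t, instances, ears)
  }
  if (length(frames) == 0L) stop("no frames in ", path)
  tmax <- max(seen_t)
  out <- vector("list", tmax)
  for (f in frames) out[[f$t]] <- f
  for (t in seq_len(tmax)) {
    if (is.null(out[[t]])) out[[t]] <- frame_detections(t)
  }
  if (!is.null(resolution)) attr(out, "resolution") <- resolution
  out
}

#' Write a detection sequence to a JSON-lines file
#'
#' Inverse of [read_detection_sequence()]; used by the simulator and the
#' command-line interface.
#'
#' @param frames List of `frame_detections`.
#' @param path Output path.
#' @param resolution Optional `[width, height]` metadata written on the
#'   first line.
#' @return `path`, invisibly.
#' @export
write_detection_sequence <- function(frames, path, resolution = NULL) {
  enc_pt <- function(p) if (is.null(p)) NULL else as.numeric(p)
  lines <- vapply(seq_along(frames), function(idx) {
    f <- frames[[idx]]
    obj <- list(
      t = f$t,
      instances = lapply(f$instances, function(d) {
        x <- list(shoulder = enc_pt(d$shoulder), tail = enc_pt(d$tail),
                  shoulder_score = d$shoulder_score,
                  tail_score = d$tail_score,
                  est_shoulder_from_tail = enc_pt(d$est_shoulder_from_tail),
                  est_tail_from_shoulder = enc_pt(d$est_tail_from_shoulder))
        if (!is.null(d$est_left_ear)) x$est_left_ear <- enc_pt(d$est_left_ear)
        if (!is.null(d$est_right_ear)) x$est_right_ear <- enc_pt(d$est_right_ear)
        x
      }),
      ears = lapply(f$ears, function(e) {
        x <- list(side = e$side, location = enc_pt(e$location),
                  tag_probs = e$tag_probs)
        if (!is.null(e$est_shoulder)) x$est_shoulder <- enc_pt(e$est_shoulder)
        x
      })
    )
    if (idx == 1L && !is.null(resolution)) obj$resolution <- as.numeric(resolution)
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write tracks and identities to CSV
#'
#' One row per frame per track slot, with columns `frame`, `identity`,
#' `slot`, `shoulder_x`, `shoulder_y`, `tail_x`, `tail_y`,
#' `interpolated_flag` (1 for positions fabricated by duplication or
#' interpolation). Coordinates are written with six decimal places.
#'
#' @param tracks A `track_set` from [build_tracks()].
#' @param ids Identity assignment: a `T x N` integer matrix mapping track
#'   slots to identities (e.g. from [assign_identities()]), or `NULL` to
#'   report slot indices as identities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, ids = NULL, path) {
  stopifnot(inherits(tracks, "track_set"))
  T_ <- tracks$T
  N <- tracks$N
  if (is.null(ids)) {
    ids <- matrix(rep(seq_len(N), each = T_), nrow = T_)
  }
  ids <- as.matrix(ids)
  if (!all(dim(ids) == c(T_, N))) {
    stop("ids must cover the same frames and slots as tracks")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("frame", "identity", "slot", "shoulder_x", "shoulder_y",
                   "tail_x", "tail_y", "interpolated_flag", sep = ","), con)
  if (T_ == 0L || N == 0L) return(invisible(path))
  frame_col <- rep(seq_len(T_), each = N)
  slot_col <- rep(seq_len(N), times = T_)
  idx <- cbind(frame_col, slot_col)
  rows <- sprintf(
    "%d,%d,%d,%.6f,%.6f,%.6f,%.6f,%d",
    frame_col, as.integer(ids[idx]), slot_col,
    tracks$shoulder_x[idx], tracks$shoulder_y[idx],
    tracks$tail_x[idx], tracks$tail_y[idx],
    as.integer(tracks$origin[idx] != "detected")
  )
  writeLines(rows, con)
  invisible(path)
}

#' Read ground-truth (or predicted) identified tracks from CSV
#'
#' Expects the [write_tracks()] layout. The number of housed animals N is
#' inferred from the first frame; every frame must then contain each
#' identity `1..N` exactly once.
#'
#' @param path CSV path.
#' @return List of ground-truth frames, each a list with elements `t`,
#'   `identity` (1..N), `shoulders` and `tails` (N x 2 matrices, row n =
#'   identity n).
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  need <- c("frame", "identity", "shoulder_x", "shoulder_y",
            "tail_x", "tail_y")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no rows in ", path)
  ts <- sort(unique(df$frame))
  n_first <- sum(df$frame == ts[[1L]])
  lapply(ts, function(t) {
    sub <- df[df$frame == t, , drop = FALSE]
    if (nrow(sub) != n_first) {
      stop("frame ", t, ": expected ", n_first, " targets, found ", nrow(sub))
    }
    if (!setequal(sub$identity, seq_len(n_first)) ||
        anyDuplicated(sub$identity)) {
      stop("frame ", t, ": identities must be 1..", n_first,
           ", each exactly once")
    }
    sub <- sub[order(sub$identity), , drop = FALSE]
    list(t = as.integer(t),
         identity = as.integer(sub$identity),
         shoulders = cbind(sub$shoulder_x, sub$shoulder_y),
         tails = cbind(sub$tail_x, sub$tail_y))
  })
}

#' Write ground-truth frames to CSV
#'
#' @param gt List of ground-truth frames as returned by
#'   [read_ground_truth()] or produced by [simulate_pen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("frame", "identity", "slot", "shoulder_x", "shoulder_y",
                   "tail_x", "tail_y", "interpolated_flag", sep = ","), con)
  for (f in gt) {
    rows <- sprintf("%d,%d,%d,%.6f,%.6f,%.6f,%.6f,0",
                    f$t, f$identity, f$identity,
                    f$shoulders[, 1L], f$shoulders[, 2L],
                    f$tails[, 1L], f$tails[, 2L])
    writeLines(rows, con)
  }
  invisible(path)
}
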