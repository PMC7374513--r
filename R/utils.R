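#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(values)))` with the usual max-shift so that long
#' chains of very small probabilities do not underflow. Used throughout the
#' forward-backward smoother.
#'
#' @param values Numeric vector of log-scale values; must be non-empty.
#'   `-Inf` entries (zero probability) are absorbed.
#' @return A single numeric value, `log(sum(exp(values)))`.
#' @examples
#' log_sum_exp(c(-1000, -1000))  # -1000 + log(2)
#' @export
log_sum_exp <- function(values) {
  if (length(values) == 0L) {
    stop("log_sum_exp() requires a non-empty input")
  }
  if (anyNA(values)) stop("log_sum_exp() input contains NA")
  m <- max(values)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(values - m)))
}

# row-wise log-sum-exp of a matrix, stabilised per row
.row_lse <- function(x) {
  m <- do.call(pmax, c(lapply(seq_len(ncol(x)), function(j) x[, j]),
                       list(na.rm = FALSE)))
  fin <- is.finite(m)
  out <- m
  if (any(fin)) {
    out[fin] <- m[fin] + log(rowSums(exp(x[fin, , drop = FALSE] - m[fin])))
  }
  out
}

# Euclidean distance between two length-2 points
.pt_dist <- function(a, b) {
  sqrt((a[[1L]] - b[[1L]])^2 + (a[[2L]] - b[[2L]])^2)
}

.is_point <- function(p) {
  is.numeric(p) && length(p) == 2L && all(is.finite(p))
}

.as_point <- function(p, what = "point") {
  p <- as.numeric(unlist(p, use.names = FALSE))
  if (!.is_point(p)) stop(sprintf("%s must be two finite coordinates", what))
  p
}

# run an expression with a private RNG stream and restore the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
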