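#' Minimum-cost bipartite assignment
#'
#' Solves the linear sum assignment problem with a dense Jonker-Volgenant
#' shortest-augmenting-path algorithm (O(n^3)). Every row is matched to a
#' distinct column so that the total cost is minimal; the matrix may be
#' rectangular with `nrow(cost) <= ncol(cost)`. Ties between equally cheap
#' assignments resolve deterministically toward lower column indices, so a
#' constant matrix yields the identity matching.
#'
#' @param cost Numeric matrix of finite costs, `nrow <= ncol`.
#' @return Integer vector of length `nrow(cost)`; element `i` is the column
#'   assigned to row `i`.
#' @examples
#' solve_assignment(rbind(c(1, 2), c(2, 1)))  # 1, 2
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!is.numeric(cost)) stop("cost must be a numeric matrix")
  if (anyNA(cost) || any(!is.finite(cost))) {
    stop("cost matrix must be finite")
  }
  if (nrow(cost) > ncol(cost)) {
    stop("cost matrix must have nrow <= ncol; transpose for the other case")
  }
  if (nrow(cost) == 0L) return(integer(0))
  .lsap_cpp(cost)
}
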