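#' Plug-in mutual information of a contingency table
#'
#' Computes the maximum-likelihood ("plug-in") estimate of mutual
#' information, in bits, from a table of cell counts:
#' \deqn{I = \sum_{ij} p_{ij} \log_2\frac{p_{ij}}{p_{i\cdot} p_{\cdot j}}}
#' with the convention \eqn{0 \log 0 = 0}.
#'
#' @param counts A matrix of non-negative cell counts with positive total.
#' @return Mutual information in bits (non-negative scalar).
#' @examples
#' mutual_information(matrix(c(5, 0, 0, 5), 2))  # 1 bit
#' mutual_information(matrix(c(2, 2, 2, 2), 2))  # 0 bits
#' @export
mutual_information <- function(counts) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be a matrix of finite non-negative values")
  n <- sum(counts)
  if (n <= 0) stop("`counts` must have a positive total")
  p <- counts / n
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' MIC grid resolution bound
#'
#' The maximal grid size \eqn{B(n) = \max(4, \lfloor n^\alpha \rfloor)}
#' searched by [mic()]: only grids with `n_x * n_y <= B(n)` enter the
#' characteristic matrix. The default exponent `alpha = 0.6` is the MINE
#' convention.
#'
#' @param n Sample size.
#' @param alpha Resolution exponent in (0, 1].
#' @return Integer grid-size bound.
#' @export
mic_resolution <- function(n, alpha = 0.6) {
  stopifnot(n >= 1, alpha > 0, alpha <= 1)
  max(4L, as.integer(floor(n^alpha)))
}

check_mic_input <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y)) stop("`x` and `y` must be numeric")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("`x` and `y` must be finite with no missing values")
  if (length(x) < min_n)
    stop(sprintf("need at least %d paired observations, got %d", min_n,
                 length(x)))
  invisible(length(x))
}

#' Best normalized mutual information for one grid dimension
#'
#' The characteristic-matrix entry for the dimension pair `(n_x, n_y)`:
#' the maximum over axis-aligned `n_x` by `n_y` grids of
#' \eqn{I(x;y) / \log_2 \min(n_x, n_y)}. Cuts are placed only between
#' distinct consecutive order statistics, so equal data values are never
#' split across bins.
#'
#' `mode = "exhaustive"` enumerates every admissible cut placement (feasible
#' for small samples and is used as the oracle in the package's tests);
#' `mode = "heuristic"` equipartitions one axis into equal-count bins and
#' optimizes the other axis by dynamic programming, taking the better of the
#' two axis orderings (the MINE approximation, a lower bound on the
#' exhaustive value).
#'
#' @param x,y Numeric vectors of equal length (at least 4).
#' @param n_x,n_y Number of bins on each axis (each at least 2).
#' @param mode `"heuristic"` or `"exhaustive"`.
#' @return Normalized mutual information in `[0, 1]`.
#' @export
characteristic_value <- function(x, y, n_x, n_y,
                                 mode = c("heuristic", "exhaustive")) {
  mode <- match.arg(mode)
  check_mic_input(x, y, 4L)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_x < 2L || n_y < 2L) stop("`n_x` and `n_y` must each be at least 2")
  if (mode == "exhaustive") .mine_exhaustive_cv(x, y, n_x, n_y)
  else .mine_heuristic_cv(x, y, n_x, n_y)
}

#' Maximal information coefficient
#'
#' The MIC of paired samples: the maximum, over all grid dimensions
#' `(n_x, n_y)` with `n_x * n_y <= B(n)` and both counts at least 2, of the
#' mutual information of the best `n_x` by `n_y` grid normalized by
#' \eqn{\log_2 \min(n_x, n_y)}. MIC lies in `[0, 1]`, is symmetric in its
#' arguments, detects linear and nonlinear dependence alike, and depends on
#' the data only through the two orderings, so it is invariant under
#' strictly increasing transforms of either variable (exactly so in
#' exhaustive mode).
#'
#' @inheritParams characteristic_value
#' @param alpha Resolution exponent; the grid bound is
#'   `B(n) = max(4, floor(n^alpha))`.
#' @param c Clump factor of the heuristic search: the dynamic program runs
#'   over at most `c` times the allowed column count of candidate cut
#'   points. Larger values search more grids; `c = 15` is the MINE default.
#' @param mode `"heuristic"` (MINE approximation, scales to thousands of
#'   timepoints) or `"exhaustive"` (exact grid enumeration, small `n` only).
#' @return MIC in `[0, 1]`.
#' @examples
#' x <- 1:16
#' mic(x, 2 * x + 3)            # exactly 1: noiseless monotone relation
#' @export
mic <- function(x, y, alpha = 0.6, c = 15,
                mode = c("heuristic", "exhaustive")) {
  mode <- match.arg(mode)
  n <- check_mic_input(x, y, 8L)
  B <- mic_resolution(n, alpha)
  if (mode == "exhaustive") .mine_exhaustive(x, y, B)
  else .mine_heuristic(x, y, B, as.integer(c))
}

#' MIC connectivity matrix of a node time-series set
#'
#' Computes the MIC between every unordered pair of node time series and
#' assembles the symmetric connectivity matrix. The diagonal is set to 0:
#' although MIC(x, x) = 1, self-connections carry no information for the
#' weighted-graph measures computed downstream. A node whose series is
#' constant has no well-defined dependence with any other node; its row and
#' column are set to 0 with a warning.
#'
#' @param series A numeric matrix with one row per node and one column per
#'   timepoint (as produced by [generate_time_series()] or
#'   [read_time_series()]), with at least 2 nodes and 8 timepoints. Row
#'   names are used as node labels when present.
#' @inheritParams mic
#' @return An `N x N` symmetric matrix of MIC values with zero diagonal and
#'   node labels as dimnames.
#' @export
mic_matrix <- function(series, alpha = 0.6, c = 15,
                       mode = c("heuristic", "exhaustive")) {
  mode <- match.arg(mode)
  series <- as.matrix(series)
  if (!is.numeric(series) || anyNA(series) || any(!is.finite(series)))
    stop("`series` must be a finite numeric node x time matrix")
  n_nodes <- nrow(series)
  if (n_nodes < 2L) stop("need at least 2 node series")
  if (ncol(series) < 8L) stop("need at least 8 timepoints")
  labels <- rownames(series)
  if (is.null(labels)) labels <- paste0("node_", seq_len(n_nodes))
  const <- apply(series, 1L, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant node series (", paste(labels[const], collapse = ", "),
            "): connectivity set to 0")
  m <- matrix(0, n_nodes, n_nodes, dimnames = list(labels, labels))
  for (i in seq_len(n_nodes - 1L)) {
    for (j in seq.int(i + 1L, n_nodes)) {
      if (const[i] || const[j]) next
      v <- mic(series[i, ], series[j, ], alpha = alpha, c = c, mode = mode)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
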