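#' Weighted graph from a connectivity matrix
#'
#' Validates a symmetric non-negative weight matrix with zero diagonal (the
#' form produced by [mic_matrix()]) and attaches node labels. All graph
#' measures in this package operate on such matrices directly; no
#' thresholding or binarization is applied — connectivity matrices are
#' analysed as fully weighted networks.
#'
#' @param weights An `N x N` symmetric numeric matrix, entries `>= 0`,
#'   zero diagonal. Symmetry is required within `1e-12`.
#' @param node_labels Optional character vector of `N` node names; defaults
#'   to the matrix dimnames or `node_1 ... node_N`.
#' @return The validated weight matrix with dimnames set, classed
#'   `"weighted_graph"`.
#' @export
weighted_graph <- function(weights, node_labels = NULL) {
  w <- as.matrix(weights)
  if (!is.numeric(w) || nrow(w) != ncol(w))
    stop("`weights` must be a square numeric matrix")
  if (anyNA(w) || any(!is.finite(w))) stop("`weights` must be finite")
  if (any(w < 0)) stop("`weights` must be non-negative")
  if (max(abs(w - t(w))) > 1e-12) stop("`weights` must be symmetric")
  if (any(diag(w) != 0)) stop("`weights` must have a zero diagonal")
  w <- (w + t(w)) / 2
  if (is.null(node_labels)) node_labels <- rownames(w)
  if (is.null(node_labels)) node_labels <- paste0("node_", seq_len(nrow(w)))
  if (length(node_labels) != nrow(w)) stop("wrong number of node labels")
  dimnames(w) <- list(node_labels, node_labels)
  class(w) <- c("weighted_graph", "matrix", "array")
  w
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(unclass(g), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Nodal strength
#'
#' The sum of all edge weights between a node and every other node — the
#' simplest weighted centrality measure.
#'
#' @param g A [weighted_graph()] (or a matrix acceptable to it).
#' @return Named numeric vector, one entry per node.
#' @export
nodal_strength <- function(g) {
  g <- weighted_graph(g)
  rowSums(g)
}

#' Edge weights to path lengths
#'
#' Maps connection weights to travel lengths for shortest-path computations:
#' `length = 1 / weight`, so strong functional coupling reads as a short
#' path; an absent edge (`weight = 0`) has infinite length. This is the
#' Brain Connectivity Toolbox convention.
#'
#' @inheritParams nodal_strength
#' @return Matrix of pairwise edge lengths (`Inf` where no edge, including
#'   the diagonal).
#' @export
weight_to_length <- function(g) {
  g <- weighted_graph(g)
  len <- ifelse(g > 0, 1 / g, Inf)
  dimnames(len) <- dimnames(g)
  len
}

#' Betweenness centrality on a weighted graph
#'
#' The fraction of all shortest paths between other node pairs that pass
#' through a given node, with path lengths `1/weight` and every co-optimal
#' path counted (Brandes accumulation; no arbitrary tie-breaking). The
#' normalized value divides the raw pair-dependency sum by
#' `(N - 1)(N - 2) / 2`, the number of ordered-source unordered pairs, so
#' it lies in `[0, 1]`.
#'
#' @inheritParams nodal_strength
#' @param normalized If `FALSE`, return the raw dependency sums.
#' @return Named numeric vector; all zeros when `N < 3`.
#' @export
betweenness_centrality <- function(g, normalized = TRUE) {
  g <- weighted_graph(g)
  n <- nrow(g)
  out <- stats::setNames(numeric(n), rownames(g))
  if (n < 3) return(out)
  ig <- as_igraph(g)
  if (igraph::ecount(ig) > 0) {
    b <- igraph::betweenness(ig, directed = FALSE,
                             weights = 1 / igraph::E(ig)$weight)
    out[names(b)] <- b
  }
  if (normalized) out <- out / ((n - 1) * (n - 2) / 2)
  out
}

#' Weighted clustering coefficient (Onnela geometric-mean form)
#'
#' Local segregation: the geometric mean of the weights of all triangles
#' around a node, with weights first normalized by the largest weight in
#' the network,
#' \deqn{C_i = \frac{\sum_{jh} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}}
#'                  {k_i (k_i - 1)},}
#' where \eqn{k_i} counts the node's nonzero-weight neighbours. Nodes with
#' fewer than two neighbours have `C = 0`.
#'
#' @inheritParams nodal_strength
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  g <- weighted_graph(g)
  w <- unclass(g)
  mx <- max(w)
  out <- stats::setNames(numeric(nrow(w)), rownames(w))
  if (mx == 0) return(out)
  w3 <- (w / mx)^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(w > 0)
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Local efficiency
#'
#' The global efficiency of the subgraph formed by a node's neighbours:
#' restrict the network to the node's nonzero-weight neighbours, compute
#' all pairwise shortest-path lengths on `1/weight` within that subgraph,
#' and average the inverse lengths over distinct ordered pairs
#' (disconnected pairs contribute 0). Nodes with fewer than two neighbours
#' have local efficiency 0.
#'
#' @inheritParams nodal_strength
#' @return Named numeric vector (in `[0, 1]` when all weights are `<= 1`).
#' @export
local_efficiency <- function(g) {
  g <- weighted_graph(g)
  w <- unclass(g)
  n <- nrow(w)
  out <- stats::setNames(numeric(n), rownames(w))
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    ig <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
    inv <- 1 / d
    diag(inv) <- 0
    out[v] <- sum(inv) / (k * (k - 1))
  }
  out
}

#' Local graph measures of a connectivity matrix
#'
#' Computes the four local measures used throughout the package —
#' [nodal_strength()], [clustering_coefficient()], [local_efficiency()] and
#' [betweenness_centrality()] (normalized and raw) — for every node.
#'
#' @inheritParams nodal_strength
#' @return A data frame with one row per node and columns `node`,
#'   `strength`, `clustering`, `local_efficiency`, `betweenness`,
#'   `betweenness_raw`.
#' @export
local_metrics <- function(g) {
  g <- weighted_graph(g)
  data.frame(
    node = rownames(g),
    strength = as.numeric(nodal_strength(g)),
    clustering = as.numeric(clustering_coefficient(g)),
    local_efficiency = as.numeric(local_efficiency(g)),
    betweenness = as.numeric(betweenness_centrality(g)),
    betweenness_raw = as.numeric(betweenness_centrality(g, normalized = FALSE)),
    stringsAsFactors = FALSE
  )
}

#' Global graph measures
#'
#' Whole-network summaries defined as the arithmetic mean over nodes of the
#' local strength, local clustering coefficient and local efficiency.
#' Betweenness has no global counterpart in this set.
#'
#' @param local A data frame from [local_metrics()], or a
#'   [weighted_graph()] (in which case local measures are computed first).
#' @return Named numeric vector `global_strength`, `global_clustering`,
#'   `global_efficiency`.
#' @export
global_metrics <- function(local) {
  if (is.matrix(local)) local <- local_metrics(local)
  stopifnot(all(c("strength", "clustering", "local_efficiency") %in%
                  names(local)))
  c(global_strength = mean(local$strength),
    global_clustering = mean(local$clustering),
    global_efficiency = mean(local$local_efficiency))
}
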