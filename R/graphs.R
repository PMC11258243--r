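#' Interaction graphs
#'
#' A directed interaction graph over `n_nodes` nodes. The edge (i, j) means
#' "node j acts on node i"; `edges` stores receivers in column 1 and actors
#' in column 2. Ground-truth edge types, when known (simulated systems), are
#' kept alongside for evaluation only and are never visible to the inference
#' procedure.
#'
#' @param n_nodes number of nodes.
#' @param edges two-column integer matrix (receiver, actor); self-edges are
#'   rejected.
#' @param true_types optional integer vector of ground-truth types in
#'   `1..K`, aligned with the rows of `edges`.
#' @param K number of interaction types.
#' @return an `interaction_graph`: list with `n_nodes`, `edges`,
#'   `true_types`, `K` and `neighbors` (list of actor sets per receiver,
#'   sorted; the slot order used by realization tables).
#' @export
interaction_graph <- function(n_nodes, edges, true_types = NULL, K = 1L) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) && any(edges[, 1L] == edges[, 2L])) {
    stop("self-edges are not allowed")
  }
  stopifnot(all(edges >= 1L), all(edges <= n_nodes))
  if (!is.null(true_types)) {
    stopifnot(length(true_types) == nrow(edges),
              all(true_types >= 1L), all(true_types <= K))
  }
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  if (!is.null(true_types)) true_types <- as.integer(true_types)[ord]
  neighbors <- lapply(seq_len(n_nodes), function(i) {
    sort(edges[edges[, 1L] == i, 2L])
  })
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 true_types = true_types, K = as.integer(K),
                 neighbors = neighbors),
            class = "interaction_graph")
}

#' Fully connected interaction graph with symmetric random edge types
#'
#' Every ordered pair is an edge; the two directions of a pair share one
#' type, drawn uniformly over `1..K` (the heterogeneous-spring setting).
#'
#' @inheritParams interaction_graph
#' @param seed integer seed for the type draw.
#' @export
full_graph <- function(n_nodes, K, seed = NULL) {
  pairs <- t(utils::combn(n_nodes, 2L))
  draw <- function() sample.int(K, nrow(pairs), replace = TRUE)
  pt <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  edges <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  interaction_graph(n_nodes, edges, true_types = c(pt, pt), K = K)
}

#' k-nearest-neighbour directed graph at one configuration
#'
#' Each node receives exactly `n_neighbors` incoming edges from its nearest
#' neighbours by Euclidean distance. Distance ties are broken by the lower
#' node index, making the construction deterministic.
#'
#' @param positions numeric matrix (nodes x dims).
#' @param n_neighbors neighbours per node; must be `< nrow(positions)`.
#' @return two-column integer matrix (receiver, actor), ordered by receiver
#'   then actor.
#' @export
build_knn_graph <- function(positions, n_neighbors) {
  N <- nrow(positions)
  if (n_neighbors >= N) stop("n_neighbors must be smaller than the number of nodes")
  D <- as.matrix(stats::dist(positions))
  edges <- matrix(0L, N * n_neighbors, 2L)
  for (i in seq_len(N)) {
    d <- D[i, ]
    d[i] <- Inf
    # order() is stable on the index, giving the lowest-index tie-break
    nb <- order(d)[seq_len(n_neighbors)]
    edges[(i - 1L) * n_neighbors + seq_len(n_neighbors), ] <-
      cbind(i, sort(as.integer(nb)))
  }
  edges
}
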