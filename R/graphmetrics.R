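#' Weighted in- and out-degree
#'
#' Out-degree of node `i` is the summed weight of its outgoing connections
#' (column `i` under the row-target orientation); in-degree is the summed
#' weight of its incoming connections (row `i`). For a weighted graph these
#' are the total connective strength a node releases or receives.
#'
#' @param C a `connectome`.
#' @return A list with numeric vectors `out_degree` and `in_degree`.
#' @export
degrees <- function(C) {
  validate_connectome(C)
  list(out_degree = unname(colSums(C$weights)),
       in_degree = unname(rowSums(C$weights)))
}

#' Eigenvector centrality by power iteration
#'
#' Leading-eigenvector centrality of the weighted directed connectome,
#' normalized so the maximum entry is exactly 1. Under the default
#' outgoing-influence orientation a node's centrality aggregates the
#' centralities of the nodes it projects *to* — the relevant direction when
#' the question is whether activity starting at a node can spread. The
#' `direction = "in"` switch aggregates over incoming connections instead.
#'
#' @param C a `connectome`.
#' @param direction `"out"` (default) or `"in"`.
#' @param tol convergence tolerance in the sup norm (default 1e-10).
#' @param max_iter maximum power iterations (default 1000).
#' @return Numeric vector of nonnegative centralities with maximum 1.
#' @export
eigenvector_centrality <- function(C, direction = c("out", "in"),
                                   tol = 1e-10, max_iter = 1000L) {
  direction <- match.arg(direction)
  validate_connectome(C)
  # row-target storage: t(W) %*% x aggregates over outgoing connections
  A <- if (direction == "out") t(C$weights) else C$weights
  n <- nrow(A)
  x <- rep(1 / n, n)
  # a nonnegative matrix has Perron root 0 exactly when it is nilpotent
  # (no directed cycle of positive weight): A^n annihilates any vector
  z <- x
  for (i in seq_len(n)) z <- drop(A %*% z)
  if (max(z) <= tol)
    stop("centrality undefined: leading eigenvalue is (numerically) zero",
         call. = FALSE)
  # power iteration on A + cI: same eigenvectors, but the shift makes the
  # Perron eigenvalue strictly dominant (a 2-cycle alone would oscillate)
  shift <- max(A)
  for (it in seq_len(max_iter)) {
    y <- drop(A %*% x) + shift * x
    y <- y / max(y)
    if (max(abs(y - x)) < tol) {
      return(unname(y / max(y)))
    }
    x <- y
  }
  stop("eigenvector centrality did not converge in ", max_iter,
       " iterations", call. = FALSE)
}

#' Inverted-weight shortest path lengths
#'
#' Every ordered node pair is treated as an edge of length
#' `l_ji = c_m - c_ji`, with `c_m` the largest weight in the matrix, so that
#' the strongest connection has length zero and absent connections have the
#' maximal length `c_m` — the graph is complete by construction. Pairwise
#' shortest paths are computed with Dijkstra's algorithm, and each node's
#' summary `L_i` is the sum of shortest path lengths from `i` to every node
#' (including the zero self-distance) divided by the node count.
#'
#' @param C a `connectome`.
#' @return A list with the pairwise matrix `lengths` (entry `[i, j]` =
#'   shortest path length from `i` to `j`) and the per-node vector
#'   `avg_shortest_path`.
#' @export
shortest_path_lengths <- function(C) {
  validate_connectome(C)
  W <- C$weights
  n <- nrow(W)
  cm <- max(W)
  # edge i -> j costs c_m - c_ji; row-target storage puts c_ji at W[j, i]
  cost <- cm - t(W)
  diag(cost) <- 0
  if (n == 1 || cm == 0) {
    D <- matrix(0, n, n)
  } else {
    g <- igraph::graph_from_adjacency_matrix(cost + 1, mode = "directed",
                                             weighted = TRUE, diag = FALSE)
    igraph::E(g)$weight <- igraph::E(g)$weight - 1 # keep zero-length edges
    D <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
    dimnames(D) <- list(C$labels, C$labels)
  }
  list(lengths = D, avg_shortest_path = unname(rowSums(D) / n))
}

#' Strongest outgoing connection weight of a node
#'
#' @param C a `connectome`.
#' @param node node index (or vector of indices).
#' @return Maximum outgoing weight per requested node; 0 for a node with no
#'   outgoing connections.
#' @export
max_outgoing_weight <- function(C, node) {
  validate_connectome(C)
  node <- as.integer(node)
  if (any(node < 1 | node > n_nodes(C)))
    stop("node index out of range", call. = FALSE)
  vapply(node, function(i) max(C$weights[, i]), numeric(1))
}

#' Normalize per-node measures to their maximum
#'
#' Divides each measure by its maximum across nodes, so the most extreme
#' node scores exactly 1 and ordering is preserved.
#'
#' @param raw numeric vector, or a data frame / named list of numeric
#'   vectors.
#' @return Object of the same shape with each measure scaled to max 1.
#' @export
normalize_measures <- function(raw) {
  norm1 <- function(v) {
    m <- max(v)
    if (m <= 0) stop("cannot normalize an all-zero measure", call. = FALSE)
    v / m
  }
  if (is.numeric(raw) && is.null(dim(raw))) return(norm1(raw))
  out <- raw
  for (nm in names(out)) out[[nm]] <- norm1(out[[nm]])
  out
}

#' All node-level graph measures of a connectome
#'
#' Convenience wrapper computing weighted degrees, eigenvector centrality,
#' inverted-weight average shortest path length and the strongest outgoing
#' weight, together with their max-normalized variants.
#'
#' @param C a `connectome`.
#' @param centrality_direction passed to [eigenvector_centrality()].
#' @return A data frame with one row per node: `node`, `label`,
#'   `out_degree`, `in_degree`, `eig_centrality`, `avg_shortest_path`,
#'   `max_out_weight`, and `norm_`-prefixed normalized columns.
#' @export
node_measures <- function(C, centrality_direction = "out") {
  deg <- degrees(C)
  # acyclic toy graphs have no defined centrality; report NA there rather
  # than aborting a whole sweep
  ec <- tryCatch(eigenvector_centrality(C, direction = centrality_direction),
                 error = function(e) rep(NA_real_, n_nodes(C)))
  sp <- shortest_path_lengths(C)$avg_shortest_path
  mow <- max_outgoing_weight(C, seq_len(n_nodes(C)))
  df <- data.frame(
    node = seq_len(n_nodes(C)), label = C$labels,
    out_degree = deg$out_degree, in_degree = deg$in_degree,
    eig_centrality = ec, avg_shortest_path = sp, max_out_weight = mow,
    row.names = NULL
  )
  for (nm in c("out_degree", "in_degree", "eig_centrality",
               "avg_shortest_path", "max_out_weight")) {
    m <- suppressWarnings(max(df[[nm]]))
    df[[paste0("norm_", nm)]] <-
      if (is.finite(m) && m > 0) df[[nm]] / m else rep(NA_real_, nrow(df))
  }
  df
}
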