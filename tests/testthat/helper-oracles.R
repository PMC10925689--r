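# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately use naive loops / exhaustive
# enumeration so they share no code path with the package implementation.

random_connectome <- function(n, seed, density = 0.7) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n) *
    (matrix(stats::runif(n * n), n, n) < density)
  diag(W) <- 0
  connectome(W)
}

# degrees by explicit double loop (row j, col i holds weight i -> j)
oracle_degrees <- function(W) {
  n <- nrow(W)
  out_deg <- numeric(n)
  in_deg <- numeric(n)
  for (i in 1:n) {
    for (j in 1:n) {
      out_deg[i] <- out_deg[i] + W[j, i]
      in_deg[i] <- in_deg[i] + W[i, j]
    }
  }
  list(out_degree = out_deg, in_degree = in_deg)
}

oracle_max_out <- function(W) {
  vapply(seq_len(ncol(W)), function(i) {
    m <- 0
    for (j in seq_len(nrow(W))) if (W[j, i] > m) m <- W[j, i]
    m
  }, numeric(1))
}

# exhaustive shortest paths on the complete inverted-weight graph:
# enumerate every simple path from i to j by depth-first search (n <= 7)
oracle_shortest_paths <- function(W) {
  n <- nrow(W)
  cm <- max(W)
  len <- function(i, j) cm - W[j, i] # cost of edge i -> j
  D <- matrix(0, n, n)
  for (s in 1:n) {
    for (t in 1:n) {
      if (s == t) next
      best <- Inf
      dfs <- function(node, visited, acc) {
        if (acc >= best) return()
        if (node == t) {
          best <<- acc
          return()
        }
        for (nxt in setdiff(1:n, visited)) {
          dfs(nxt, c(visited, nxt), acc + len(node, nxt))
        }
      }
      dfs(s, s, 0)
      D[s, t] <- best
    }
  }
  D
}

# one deterministic 2-node connectome used by several hand examples
two_node_connectome <- function(w01, w10) {
  W <- matrix(0, 2, 2)
  W[2, 1] <- w01 # from node 1 to node 2
  W[1, 2] <- w10 # from node 2 to node 1
  connectome(W)
}

# fast parameter set for small deterministic simulations in tests
quick_params <- function(..., dt_out = 1) {
  epileptor_params(sigma = 0, ic_jitter = 0, dt_out = dt_out, ...)
}
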