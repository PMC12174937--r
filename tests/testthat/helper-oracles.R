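# Independent oracles used to freeze expected values.

# Breadth-first-search shortest path length between two real cells, over
# the adjacency graph given by the neighbour lists (independent of the
# cube-coordinate distance formula).
bfs_distance <- function(a, b, grid) {
  key <- function(i, j) paste(i, j)
  target <- key(b[1L], b[2L])
  seen <- new.env(parent = emptyenv())
  assign(key(a[1L], a[2L]), TRUE, envir = seen)
  frontier <- list(a)
  d <- 0L
  while (length(frontier) > 0L) {
    if (any(vapply(frontier, function(c_) key(c_[1L], c_[2L]), "") == target))
      return(d)
    nxt <- list()
    for (c_ in frontier) {
      nb <- moore_neighbors(c_, grid)
      nb <- nb[nb[, "aux"] == 0L, , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        k <- key(nb[r, 1L], nb[r, 2L])
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- c(nb[r, 1L], nb[r, 2L])
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  Inf
}

# Union-find grouping of affected cells by pairwise hex distance <= 3
# (brute force over all pairs).
group_by_distance <- function(cells, grid, dmax = 3L) {
  n <- nrow(cells)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (hex_distance(cells[a, ], cells[b, ]) <= dmax) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Boundary edges by pairwise adjacency counting (independent of the
# package's neighbour enumeration).
brute_boundary_edges <- function(cells) {
  n <- nrow(cells)
  adj <- 0L
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
      if (hex_distance(cells[a, ], cells[b, ]) == 1L) adj <- adj + 1L
  }
  6L * n - 2L * adj
}

# Deterministic drift recursion of the birth-death chain.
bd_drift <- function(n0, b, d, C, N, steps = 1L) {
  n <- n0
  for (s in seq_len(N * steps))
    n <- n + (n * b * (1 - n / C) - d * n) / N
  n
}

random_affected_set <- function(grid, n_max = 12L) {
  n <- sample(seq_len(n_max), 1L)
  idx <- sample(grid$m * grid$n, n)
  cbind(i = (idx - 1L) %% grid$m + 1L, j = (idx - 1L) %/% grid$m + 1L)
}

worked_example <- function() {
  g <- hex_grid(5, 5)
  f <- matrix(0, 5, 5)
  f[2, 2] <- 1
  inc <- matrix(0, 5, 5)
  inc[cbind(c(1, 2, 2, 2, 3), c(1, 1, 2, 3, 2))] <- 1
  sur <- matrix(1, 5, 5)
  sur[3, 2] <- 0
  list(grid = g, field = f,
       draws = list(inclusion = inc, survival = sur),
       params = sca_params(gamma1 = 0.8, gamma2 = 0.8))
}
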