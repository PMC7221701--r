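# Independent brute-force oracles used across the suite. These stay
# deliberately naive (BFS, path enumeration, literal formulas) so they never
# share code with the implementation they check.

# all-pairs shortest paths by plain breadth-first search on the heavy graph
bfs_distance_oracle <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  n <- length(heavy)
  map <- integer(nrow(mol$atoms)); map[heavy] <- seq_len(n)
  nbr <- lapply(seq_len(n), function(i) integer())
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$a1[k] %in% heavy && b$a2[k] %in% heavy) {
      i <- map[b$a1[k]]; j <- map[b$a2[k]]
      nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in nbr[[u]]) {
        if (is.infinite(d[s, v])) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}

# count simple paths with m edges by exhaustive DFS enumeration
path_count_oracle <- function(mol, m) {
  d <- bfs_distance_oracle(mol) # also gives adjacency via d == 1
  n <- nrow(d)
  adj <- d == 1
  count <- 0L
  extend <- function(path) {
    last <- path[length(path)]
    if (length(path) == m + 1L) {
      count <<- count + 1L
      return()
    }
    for (v in which(adj[last, ])) {
      if (!(v %in% path)) extend(c(path, v))
    }
  }
  for (s in seq_len(n)) extend(s)
  count %/% 2L # each path enumerated from both ends
}

# literal Balaban formula from the BFS distance matrix
balaban_oracle <- function(mol) {
  d <- bfs_distance_oracle(mol)
  a <- nrow(d)
  if (a < 2) return(0)
  adj <- d == 1
  q <- sum(adj) / 2
  mu <- q - a + 1
  s <- rowSums(d)
  tot <- 0
  for (i in seq_len(a - 1)) for (j in seq(i + 1, a)) {
    if (adj[i, j]) tot <- tot + 1 / sqrt(s[i] * s[j])
  }
  q / (mu + 1) * tot
}

# rebuild a molecule with its atoms in permuted order
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  b <- mol$bonds
  b$a1 <- inv[b$a1]; b$a2 <- inv[b$a2]
  new_molecule(mol$id, mol$atoms$element[perm], b,
               formal_charge = mol$atoms$formal_charge[perm],
               explicit_h = mol$atoms$implicit_h[perm],
               coords = if (!is.null(mol$coords))
                 mol$coords[perm, , drop = FALSE])
}

# small helper: dataset wrapper around a plain data frame + response
make_dataset <- function(X, y) {
  qsar_dataset(sprintf("c%04d", seq_len(nrow(X))), X, y)
}
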