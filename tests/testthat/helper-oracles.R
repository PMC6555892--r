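# Independent brute-force oracles used to check the package's algorithms.
# Everything here is deliberately naive: exhaustive enumeration and
# label-merging, no shared code with the implementation under test.

# Is the induced subgraph on `subset` (integer ids) connected?
# adj: logical adjacency matrix.
connectedSubset <- function(adj, subset) {
  if (length(subset) <= 1L) return(TRUE)
  n <- nrow(adj)
  insub <- logical(n); insub[subset] <- TRUE
  seen <- logical(n); seen[subset[1L]] <- TRUE
  frontier <- subset[1L]
  while (length(frontier)) {
    nb <- which(rowSums(adj[, frontier, drop = FALSE]) > 0)
    nb <- nb[insub[nb] & !seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen[subset])
}

# Exhaustive optimum of the connector objective: maximize placed seeds,
# then minimize connectors, over all connected node subsets within the
# budget. Returns list(nPlaced, nConnectors).
bruteForceOptimum <- function(adj, seedIdx, maxNodes) {
  n <- nrow(adj)
  nonSeeds <- setdiff(seq_len(n), seedIdx)
  for (np in rev(seq_along(seedIdx))) {
    seedSubsets <- utils::combn(seedIdx, np, simplify = FALSE)
    for (nc in 0:(maxNodes - np)) {
      if (nc > length(nonSeeds)) break
      connSets <- if (nc == 0L) list(integer(0))
      else utils::combn(nonSeeds, nc, simplify = FALSE)
      for (ss in seedSubsets) for (cs in connSets) {
        if (connectedSubset(adj, c(ss, cs)))
          return(list(nPlaced = np, nConnectors = nc))
      }
    }
  }
  list(nPlaced = 1L, nConnectors = 0L)
}

# Connected components by naive label merging; edges: 2-column matrix of
# integer indices, n nodes. Returns the number of components.
componentCountOracle <- function(n, edges) {
  lab <- seq_len(n)
  if (length(edges)) for (r in seq_len(nrow(edges))) {
    la <- lab[edges[r, 1L]]; lb <- lab[edges[r, 2L]]
    if (la != lb) lab[lab == lb] <- la
  }
  length(unique(lab))
}

# Upper-tail hypergeometric P(X >= k) by exhaustive subset enumeration.
hyperTailOracle <- function(k, K, N, n) {
  subsets <- utils::combn(N, n, simplify = FALSE)
  hits <- vapply(subsets, function(s) sum(s <= K) >= k, logical(1))
  mean(hits)
}

# Deterministic Erdos-Renyi-ish random graph as a logical adjacency matrix
# with uppercase letter names (uses the session RNG; seed it first).
randomAdjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- TRUE
  nm <- sprintf("N%02d", seq_len(n))
  dimnames(adj) <- list(nm, nm)
  adj
}

# Interactome from a logical adjacency matrix (all edges direct).
adjacencyToInteractome <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  Interactome(rownames(adj)[idx[, 1L]], colnames(adj)[idx[, 2L]],
              kind = "direct", extraNodes = rownames(adj))
}

# A 5-seed / 1-hub star interactome used across tests.
starInteractome <- function() {
  Interactome(from = c("A", "B", "C", "HUB"), to = c("HUB", "HUB", "HUB", "Z"),
              kind = "direct")
}
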