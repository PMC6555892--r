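## Connector-gene subnetwork search.
##
## The objective: within a node budget, include as many seed genes as
## possible (primary) through as few connector genes as possible
## (secondary), using only direct interaction edges. The search is a greedy
## Steiner-tree heuristic on the unweighted direct subgraph: starting from
## each seed in turn, repeatedly attach the nearest unplaced seed along a
## breadth-first shortest path, then drop connectors whose removal leaves
## the placed seeds connected, and keep the best run. Every choice point
## breaks ties lexicographically on gene symbol, so results are
## bit-reproducible.

## internal: integer-indexed adjacency over the direct subgraph.
## nodes are sorted, so ascending index order == lexicographic symbol order.
.netIndex <- function(net) {
  nodes <- net@nodes
  ed <- net@edges[net@edges$kind == "direct", , drop = FALSE]
  n <- length(nodes)
  adj <- vector("list", n)
  if (nrow(ed)) {
    i <- match(ed$from, nodes); j <- match(ed$to, nodes)
    sp <- split(c(j, i), c(i, j))
    at <- as.integer(names(sp))
    for (k in seq_along(at)) adj[[at[k]]] <- sort(unique(sp[[k]]))
  }
  list(nodes = nodes, adj = adj, deg = lengths(adj), n = n)
}

## internal: multi-source BFS; parent of a newly reached node is the
## smallest-index frontier neighbour (frontier kept sorted).
.bfs <- function(G, sources) {
  dist <- rep.int(NA_integer_, G$n)
  parent <- integer(G$n)
  frontier <- sort(sources)
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- G$adj[[u]]
      if (!length(nb)) next
      new <- nb[is.na(dist[nb])]
      if (length(new)) {
        dist[new] <- d + 1L
        parent[new] <- u
        nxt <- c(nxt, new)
      }
    }
    frontier <- sort(nxt)
    d <- d + 1L
  }
  list(dist = dist, parent = parent)
}

## internal: are all `placed` nodes mutually connected within `subset`?
.allConnected <- function(G, subset, placed) {
  if (length(placed) <= 1L) return(TRUE)
  inset <- logical(G$n); inset[subset] <- TRUE
  if (!all(inset[placed])) return(FALSE)
  seen <- logical(G$n)
  frontier <- placed[1L]; seen[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- G$adj[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  all(seen[placed])
}

## internal: group seed indices by connected component (BFS reachability)
.seedComponents <- function(G, seeds) {
  groups <- list(); left <- seeds
  while (length(left)) {
    b <- .bfs(G, left[1L])
    grp <- left[!is.na(b$dist[left])]
    groups[[length(groups) + 1L]] <- grp
    left <- setdiff(left, grp)
  }
  groups
}

## internal: one greedy run from a start seed (nearest-terminal attachment)
.greedyRun <- function(G, seeds, start, maxNodes) {
  tree <- start
  remaining <- setdiff(seeds, tree)
  while (length(remaining) && length(tree) < maxNodes) {
    b <- .bfs(G, tree)
    dd <- b$dist[remaining]
    reach <- which(!is.na(dd))
    if (!length(reach)) break
    ord <- reach[order(dd[reach], remaining[reach])]
    added <- FALSE
    for (t in remaining[ord]) {
      if (length(tree) + b$dist[t] > maxNodes) next
      path <- integer(0); v <- t
      while (b$dist[v] > 0L) { path <- c(path, v); v <- b$parent[v] }
      tree <- sort(c(tree, path))
      remaining <- setdiff(seeds, tree)
      added <- TRUE
      break
    }
    if (!added) break
  }
  tree
}

## internal: remove connectors whose removal keeps placed seeds connected;
## candidates tried in lexicographic order until a fixed point.
.pruneConnectors <- function(G, tree, placed) {
  repeat {
    connectors <- setdiff(tree, placed)
    removed <- FALSE
    for (cn in connectors) {
      cand <- setdiff(tree, cn)
      if (.allConnected(G, cand, placed)) { tree <- cand; removed <- TRUE; break }
    }
    if (!removed) return(tree)
  }
}

## internal: TRUE if tree summary a beats b under
## (more seeds, fewer connectors, lexicographically smaller member set)
.betterTree <- function(a, b) {
  if (a$np != b$np) return(a$np > b$np)
  if (a$nc != b$nc) return(a$nc < b$nc)
  m <- min(length(a$tree), length(b$tree))
  d <- which(a$tree[seq_len(m)] != b$tree[seq_len(m)])
  if (length(d)) return(a$tree[d[1L]] < b$tree[d[1L]])
  length(a$tree) < length(b$tree)
}

## internal: fill spare budget with highest-degree neighbours of members
.padNetwork <- function(G, tree, maxNodes) {
  while (length(tree) < maxNodes) {
    inset <- logical(G$n); inset[tree] <- TRUE
    nb <- unique(unlist(G$adj[tree]))
    nb <- nb[!inset[nb]]
    if (!length(nb)) return(tree)
    pick <- nb[order(-G$deg[nb], nb)][1L]
    tree <- sort(c(tree, pick))
  }
  tree
}

## internal search on an indexed graph; returns integer ids
.searchConnectors <- function(G, sidx, maxNodes, pad = TRUE) {
  groups <- .seedComponents(G, sidx)
  sizes <- lengths(groups)
  if (max(sizes) < length(sidx))
    warning("seed genes are mutually unreachable; using the largest ",
            "reachable seed component (", max(sizes), " of ",
            length(sidx), " seeds)")
  best <- NULL
  # components tied on seed count compete on connector cost
  for (grp in groups[sizes == max(sizes)]) {
    grp <- sort(grp)
    for (s in grp) {
      tree <- .greedyRun(G, grp, s, maxNodes)
      placed <- intersect(grp, tree)
      tree <- .pruneConnectors(G, tree, placed)
      cand <- list(np = length(placed), nc = length(tree) - length(placed),
                   tree = tree)
      if (is.null(best) || .betterTree(cand, best)) best <- cand
    }
  }
  tree <- best$tree
  if (pad) tree <- .padNetwork(G, tree, maxNodes)
  list(tree = tree, placed = intersect(sidx, tree))
}

#' Find a seed-connector subnetwork within a node budget
#'
#' Searches the direct-interaction subgraph for a connected subnetwork of at
#' most \code{maxNodes} genes that links together the maximum number of seed
#' genes with a minimal number of connecting genes. The heuristic is a
#' deterministic greedy Steiner-tree construction (see the methods
#' vignette); ties are broken lexicographically on gene symbol. When
#' \code{pad = TRUE} (the default, matching the fixed-size networks the
#' approach was designed around) leftover budget is filled with the
#' highest-degree neighbours of current members, so a saturated run returns
#' exactly \code{maxNodes} genes.
#'
#' Seeds absent from the interactome are reported and excluded from
#' scoring; if the present seeds fall in several components, the largest
#' reachable seed component is used with a warning.
#'
#' @param net an [Interactome-class]; only its direct edges are used.
#' @param seeds character vector of seed gene symbols (case-insensitive).
#' @param maxNodes node budget (default 35).
#' @param pad fill spare budget with high-degree neighbours (default TRUE).
#' @return a [CandidateNetwork-class] with its enrichment score set.
#' @examples
#' net <- exampleInteractome()
#' findConnectorNetwork(net, c("A", "B", "C"), maxNodes = 4, pad = FALSE)
#' @export
findConnectorNetwork <- function(net, seeds, maxNodes = 35L, pad = TRUE) {
  if (maxNodes < 2L) stop("maxNodes must be at least 2")
  seeds <- unique(toupper(seeds))
  G <- .netIndex(net)
  sidx <- match(seeds, G$nodes)
  absent <- seeds[is.na(sidx)]
  if (length(absent) == length(seeds)) stop("no seeds in interactome")
  if (length(absent))
    message("seed gene(s) absent from interactome, excluded: ",
            paste(absent, collapse = ", "))
  sidx <- sort(sidx[!is.na(sidx)])
  res <- .searchConnectors(G, sidx, as.integer(maxNodes), pad)
  nodes <- G$nodes[res$tree]
  seedNames <- intersect(nodes, seeds)
  sc <- enrichmentScore(length(nodes), length(seedNames), G$n,
                        length(sidx))
  .candidateNetwork(nodes, seedNames, .induceEdges(net, nodes),
                    score = sc@score, rank = 1L)
}

#' Iteratively extract score-ranked seed-connector networks
#'
#' Repeats [findConnectorNetwork()]: after each extraction the connectors of
#' the network are removed from the working graph, seeds already placed are
#' retired, and the remaining seeds re-seed the next search. All networks
#' are scored against the original interactome universe and returned sorted
#' by score (descending); the top-ranked network is element 1.
#'
#' @inheritParams findConnectorNetwork
#' @param maxNetworks maximum number of networks to extract.
#' @return list of [CandidateNetwork-class], scores non-increasing, with
#'   1-based \code{rank} filled in.
#' @export
rankNetworks <- function(net, seeds, maxNodes = 35L, maxNetworks = 10L,
                         pad = TRUE) {
  if (maxNetworks < 1L) stop("maxNetworks must be at least 1")
  seeds <- unique(toupper(seeds))
  nUniverse <- length(net@nodes)
  kTotal <- sum(seeds %in% net@nodes)
  work <- directSubgraph(net)
  remaining <- seeds
  out <- list()
  for (k in seq_len(maxNetworks)) {
    if (!length(remaining)) break
    cn <- if (k == 1L) findConnectorNetwork(work, remaining, maxNodes, pad)
    else tryCatch(
      suppressWarnings(suppressMessages(
        findConnectorNetwork(work, remaining, maxNodes, pad))),
      error = function(e) NULL)
    if (is.null(cn)) break
    sc <- enrichmentScore(length(cn@nodes), length(cn@seedNodes),
                          nUniverse, kTotal)
    cn@score <- sc@score
    out[[k]] <- cn
    remaining <- setdiff(remaining, cn@seedNodes)
    keep <- setdiff(work@nodes, cn@connectorNodes)
    ed <- work@edges[work@edges$from %in% keep & work@edges$to %in% keep, ,
                     drop = FALSE]
    rownames(ed) <- NULL
    work <- new("Interactome", nodes = keep, edges = ed)
  }
  out <- out[order(-vapply(out, function(x) x@score, numeric(1)))]
  for (i in seq_along(out)) out[[i]]@rank <- i
  out
}

#' Degree report with hub flags for a candidate network
#'
#' A hub is a member selected for its high connectivity in the whole
#' interactome rather than biological similarity to other members: a node
#' whose interactome degree exceeds the given percentile of the
#' interactome-wide direct-degree distribution (percentile 0 flags every
#' member).
#'
#' @param network a [CandidateNetwork-class].
#' @param net the [Interactome-class] it was drawn from.
#' @param percentile hub threshold on the interactome degree distribution,
#'   in [0, 1] (default 0.95).
#' @return data.frame (gene, role, degreeInNetwork, degreeInInteractome,
#'   isHub), sorted by interactome degree descending.
#' @export
hubReport <- function(network, net, percentile = 0.95) {
  if (!all(network@nodes %in% net@nodes))
    stop("network members must belong to the interactome")
  degAll <- interactomeDegree(net)
  degN <- table(factor(c(network@edges$from, network@edges$to),
                       levels = network@nodes))
  degI <- degAll[network@nodes]
  isHub <- if (percentile <= 0) rep(TRUE, length(degI))
  else degI > stats::quantile(degAll, percentile, names = FALSE)
  df <- data.frame(
    gene = network@nodes,
    role = ifelse(network@nodes %in% network@seedNodes, "seed", "connector"),
    degreeInNetwork = as.integer(degN),
    degreeInInteractome = as.integer(degI),
    isHub = unname(isHub),
    stringsAsFactors = FALSE)
  df <- df[order(-df$degreeInInteractome, df$gene), ]
  rownames(df) <- NULL
  df
}
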