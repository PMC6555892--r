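#' Construct an Interactome from an edge table
#'
#' Normalises gene symbols to uppercase, canonicalises each undirected pair,
#' drops self-loops (with a warning), maps unknown interaction kinds to
#' \code{"indirect"} (with a warning, since only direct edges are analysed),
#' and collapses duplicate pair/kind rows, summing reference counts.
#'
#' @param from,to character vectors of gene symbols.
#' @param kind interaction kind per edge (\code{"direct"}/\code{"indirect"});
#'   recycled if length 1.
#' @param action free-text action label per edge (e.g. "binding").
#' @param nrefs integer provenance reference count per edge.
#' @param extraNodes gene symbols to include even if they touch no edge.
#' @return an [Interactome-class].
#' @examples
#' Interactome(c("tnf", "il6"), c("IL6", "STAT3"), kind = "direct")
#' @export
Interactome <- function(from, to, kind = "direct", action = "", nrefs = 1L,
                        extraNodes = character()) {
  stopifnot(length(from) == length(to))
  n <- length(from)
  edges <- data.frame(
    from = toupper(as.character(from)), to = toupper(as.character(to)),
    kind = rep_len(as.character(kind), n), action = rep_len(as.character(action), n),
    nrefs = rep_len(as.integer(nrefs), n), stringsAsFactors = FALSE)

  self <- edges$from == edges$to
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  bad <- !(edges$kind %in% c("direct", "indirect"))
  if (any(bad)) {
    warning(sum(bad), " edge(s) with unknown interaction kind treated as indirect")
    edges$kind[bad] <- "indirect"
  }
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp

  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, edges$kind, sep = "\r")
    agg <- rowsum(edges$nrefs, key, reorder = FALSE)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$nrefs <- as.integer(agg[match(paste(edges$from, edges$to, edges$kind,
                                              sep = "\r"), rownames(agg)), 1L])
    edges <- edges[order(edges$from, edges$to, edges$kind), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(edges$from, edges$to, toupper(extraNodes))))
  new("Interactome", nodes = nodes, edges = edges)
}

#' @describeIn networkNodes genes of the interactome
#' @export
setMethod("networkNodes", "Interactome", function(x) x@nodes)

#' @describeIn edgeTable edges of the interactome
#' @export
setMethod("edgeTable", "Interactome", function(x) x@edges)

#' @describeIn directSubgraph keep only direct edges; all nodes retained
#' @export
setMethod("directSubgraph", "Interactome", function(x) {
  ed <- x@edges[x@edges$kind == "direct", , drop = FALSE]
  rownames(ed) <- NULL
  new("Interactome", nodes = x@nodes, edges = ed)
})

setMethod("show", "Interactome", function(object) {
  nd <- sum(object@edges$kind == "direct")
  cat("Interactome with", length(object@nodes), "genes and",
      nrow(object@edges), "edges (", nd, "direct,",
      nrow(object@edges) - nd, "indirect )\n")
})

setMethod("show", "CandidateNetwork", function(object) {
  cat("CandidateNetwork:", length(object@nodes), "genes (",
      length(object@seedNodes), "seeds,", length(object@connectorNodes),
      "connectors ),", nrow(object@edges), "edges\n")
  if (!is.na(object@score)) cat("  score:", format(object@score, digits = 4),
                                " rank:", object@rank, "\n")
})

setMethod("show", "NetworkScore", function(object) {
  cat("NetworkScore: score", format(object@score, digits = 4),
      "( p_enrichment", format(object@pEnrichment, digits = 3), ")\n")
  if (length(object@pEmpirical))
    cat("  empirical p", format(object@pEmpirical, digits = 3), "from",
        object@nPermutations, "permutations\n")
})

setMethod("show", "LdTable", function(object) {
  cat("LdTable with", nrow(object@pairs), "SNP pairs\n")
})

#' @describeIn networkNodes member genes of a candidate network
#' @export
setMethod("networkNodes", "CandidateNetwork", function(x) x@nodes)

#' @describeIn edgeTable induced direct edges of a candidate network
#' @export
setMethod("edgeTable", "CandidateNetwork", function(x) x@edges)

#' @describeIn seedNodes seed members
#' @export
setMethod("seedNodes", "CandidateNetwork", function(x) x@seedNodes)

#' @describeIn connectorNodes connector members
#' @export
setMethod("connectorNodes", "CandidateNetwork", function(x) x@connectorNodes)

#' @describeIn networkScore score slot of a candidate network
#' @export
setMethod("networkScore", "CandidateNetwork", function(x) x@score)

#' @describeIn networkScore -log10 enrichment p of a NetworkScore
#' @export
setMethod("networkScore", "NetworkScore", function(x) x@score)

#' Node degrees in an interactome
#'
#' @param net an [Interactome-class].
#' @param directOnly count only direct edges (default TRUE).
#' @return named integer vector over all nodes (isolated nodes get 0).
#' @export
interactomeDegree <- function(net, directOnly = TRUE) {
  ed <- net@edges
  if (directOnly) ed <- ed[ed$kind == "direct", , drop = FALSE]
  deg <- table(factor(c(ed$from, ed$to), levels = net@nodes))
  stats::setNames(as.integer(deg), net@nodes)
}

#' A tiny built-in example interactome
#'
#' Nine genes: a hub H bound by seeds-like genes plus an indirect arm.
#' Used in documentation examples.
#' @return an [Interactome-class].
#' @export
exampleInteractome <- function() {
  Interactome(
    from = c("A", "B", "C", "H", "H", "D"),
    to   = c("H", "H", "H", "D", "E", "E"),
    kind = c("direct", "direct", "direct", "direct", "indirect", "indirect"),
    action = c("binding", "binding", "binding", "binding", "activate", "inhibit"))
}

## internal: igraph view of the direct subgraph (used by search + export)
.asIgraph <- function(x, directOnly = TRUE) {
  if (is(x, "Interactome")) {
    ed <- x@edges
    if (directOnly) ed <- ed[ed$kind == "direct", , drop = FALSE]
    igraph::graph_from_data_frame(ed, directed = FALSE,
      vertices = data.frame(name = x@nodes))
  } else {
    igraph::graph_from_data_frame(x@edges, directed = FALSE,
      vertices = data.frame(name = x@nodes))
  }
}
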