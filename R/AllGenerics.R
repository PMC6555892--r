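#' Member genes of a network object
#'
#' @param x an [Interactome-class] or [CandidateNetwork-class].
#' @return character vector of gene symbols.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a network object
#'
#' @param x an [Interactome-class] or [CandidateNetwork-class].
#' @return data.frame of edges (one row per undirected edge).
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Seed genes of a candidate network
#' @param x a [CandidateNetwork-class].
#' @return character vector.
#' @export
setGeneric("seedNodes", function(x) standardGeneric("seedNodes"))

#' Connector (non-seed) genes of a candidate network
#' @param x a [CandidateNetwork-class].
#' @return character vector.
#' @export
setGeneric("connectorNodes", function(x) standardGeneric("connectorNodes"))

#' Network score accessor
#' @param x a [CandidateNetwork-class] or [NetworkScore-class].
#' @return numeric score (-log10 enrichment p).
#' @export
setGeneric("networkScore", function(x) standardGeneric("networkScore"))

#' Restrict an interactome to its direct interactions
#'
#' Physical (direct) molecular relations -- binding, cleavage,
#' phosphorylation -- are kept; indirect regulatory relations are dropped.
#' Isolated nodes are retained: a gene with no direct partner remains a
#' zero-degree candidate. Idempotent.
#'
#' @param x an [Interactome-class].
#' @return an [Interactome-class] whose edges all have kind \code{"direct"}.
#' @examples
#' net <- exampleInteractome()
#' directSubgraph(net)
#' @export
setGeneric("directSubgraph", function(x) standardGeneric("directSubgraph"))
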