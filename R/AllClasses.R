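#' @import methods
NULL

#' Interactome: a whole-genome molecular interaction network
#'
#' An undirected labelled graph of genes. Nodes are gene symbols (stored
#' uppercase); each edge carries an interaction kind (\code{"direct"} for
#' physical relations such as binding, cleavage or phosphorylation;
#' \code{"indirect"} for regulatory relations such as activation or
#' inhibition), a free-text action label, and a provenance reference count.
#' Downstream connector search operates on the direct subgraph only.
#'
#' @slot nodes character vector of unique uppercase gene symbols.
#' @slot edges data.frame with columns \code{from}, \code{to} (uppercase
#'   symbols, stored with \code{from < to}), \code{kind}
#'   (\code{"direct"}/\code{"indirect"}), \code{action} (free text) and
#'   \code{nrefs} (integer reference count, >= 1).
#'
#' @seealso [readEdgeList()], [directSubgraph()], [writeNetwork()]
#' @export
setClass("Interactome",
  representation(nodes = "character", edges = "data.frame"))

setValidity("Interactome", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  need <- c("from", "to", "kind", "action", "nrefs")
  if (!all(need %in% names(ed)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (length(nd) < 1L) msg <- c(msg, "interactome must contain at least one node")
  if (anyDuplicated(nd)) msg <- c(msg, "duplicate node symbols")
  if (any(nd != toupper(nd))) msg <- c(msg, "node symbols must be uppercase")
  if (nrow(ed)) {
    if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(ed$from > ed$to)) msg <- c(msg, "edges must be stored with from < to")
    if (!all(c(ed$from, ed$to) %in% nd))
      msg <- c(msg, "every edge endpoint must be a node")
    if (anyDuplicated(ed[c("from", "to", "kind")]))
      msg <- c(msg, "duplicate edges for the same interaction kind")
    if (!all(ed$kind %in% c("direct", "indirect")))
      msg <- c(msg, "interaction kind must be 'direct' or 'indirect'")
    if (any(ed$nrefs < 1L)) msg <- c(msg, "reference counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' CandidateNetwork: a node-bounded seed-connector subnetwork
#'
#' A subnetwork of at most \code{maxNodes} genes partitioned into seed genes
#' (previously established disease genes that anchored the search) and
#' connector genes (non-seed genes added to link the seeds; the novel
#' disease-gene candidates). The score is -log10 of the hypergeometric
#' enrichment p-value of the seed content (see [enrichmentScore()]).
#'
#' @slot nodes character vector of member genes.
#' @slot seedNodes subset of \code{nodes} that are seeds.
#' @slot connectorNodes \code{nodes} minus \code{seedNodes}.
#' @slot edges data.frame (\code{from}, \code{to}) of induced direct edges.
#' @slot score numeric network score (-log10 enrichment p), NA before scoring.
#' @slot rank integer 1-based rank among extracted networks.
#'
#' @seealso [findConnectorNetwork()], [rankNetworks()]
#' @export
setClass("CandidateNetwork",
  representation(nodes = "character", seedNodes = "character",
    connectorNodes = "character", edges = "data.frame",
    score = "numeric", rank = "integer"))

setValidity("CandidateNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate member genes")
  if (!all(object@seedNodes %in% object@nodes))
    msg <- c(msg, "seed genes must be members")
  if (length(intersect(object@seedNodes, object@connectorNodes)))
    msg <- c(msg, "a gene cannot be both seed and connector")
  if (!setequal(c(object@seedNodes, object@connectorNodes), object@nodes))
    msg <- c(msg, "seeds and connectors must partition the members")
  ed <- object@edges
  if (nrow(ed) && !all(c(ed$from, ed$to) %in% object@nodes))
    msg <- c(msg, "edge endpoints must be members")
  if (length(msg)) msg else TRUE
})

#' NetworkScore: enrichment score with optional permutation null
#'
#' @slot pEnrichment upper-tail hypergeometric probability in (0, 1].
#' @slot score -log10(pEnrichment).
#' @slot pEmpirical empirical permutation p (add-one rule); length 0 if the
#'   permutation null was not run.
#' @slot nPermutations number of permutations behind \code{pEmpirical}.
#' @slot nullScores the permuted scores (may be length 0).
#'
#' @seealso [enrichmentScore()], [permutationNull()]
#' @export
setClass("NetworkScore",
  representation(pEnrichment = "numeric", score = "numeric",
    pEmpirical = "numeric", nPermutations = "integer",
    nullScores = "numeric"))

setValidity("NetworkScore", function(object) {
  msg <- character()
  p <- object@pEnrichment
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    msg <- c(msg, "pEnrichment must be a single value in (0, 1]")
  else if (abs(object@score + log10(p)) > 1e-12)
    msg <- c(msg, "score must equal -log10(pEnrichment)")
  if (length(object@pEmpirical)) {
    lo <- 1 / (object@nPermutations + 1)
    if (object@pEmpirical < lo - 1e-12 || object@pEmpirical > 1)
      msg <- c(msg, "pEmpirical outside [1/(n_permutations+1), 1]")
  }
  if (length(msg)) msg else TRUE
})

#' LdTable: symmetric pairwise D-prime values
#'
#' Stores pairwise linkage-disequilibrium D' values in [0, 1] for SNP pairs.
#' Pairs are stored once in canonical order (\code{snpA < snpB}); lookup via
#' [ldDprime()] is symmetric. Missing pairs are treated as D' = 0 (or an
#' error) by consumers, per their \code{missingAs} argument.
#'
#' @slot pairs data.frame with columns \code{snpA}, \code{snpB},
#'   \code{dprime}.
#'
#' @seealso [readLdTable()], [countIndependent()]
#' @export
setClass("LdTable", representation(pairs = "data.frame"))

setValidity("LdTable", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("snpA", "snpB", "dprime") %in% names(p)))
    return("pairs must have columns snpA, snpB, dprime")
  if (nrow(p)) {
    if (any(p$snpA >= p$snpB))
      msg <- c(msg, "pairs must be stored with snpA < snpB (no self-pairs)")
    if (any(p$dprime < 0 | p$dprime > 1)) msg <- c(msg, "D' must lie in [0, 1]")
    if (anyDuplicated(p[c("snpA", "snpB")])) msg <- c(msg, "duplicate SNP pairs")
  }
  if (length(msg)) msg else TRUE
})
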