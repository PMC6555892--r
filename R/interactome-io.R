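#' Read a molecular interaction network from an edge list
#'
#' Two dialects are supported. \code{"tsv"}: tab-separated columns
#' \code{geneA}, \code{geneB}, \code{kind} and an optional fourth
#' \code{action} column; lines starting with \code{#} are comments; an
#' optional header line naming the columns is skipped. \code{"sif"}:
#' whitespace-separated \code{nodeA relation nodeB [nodeC ...]}; the relation
#' word is kept as the action label and mapped to an interaction kind through
#' \code{sifMapping}; a line holding a single token declares an isolated
#' node. Duplicate edge lines are collapsed and their provenance reference
#' counts summed.
#'
#' @param path file to read.
#' @param dialect \code{"tsv"} or \code{"sif"}.
#' @param sifMapping named character vector mapping SIF relation types to
#'   \code{"direct"}/\code{"indirect"} (e.g. \code{c(pp = "direct")}), or the
#'   path of a YAML file holding such a map. Unmapped relations become
#'   indirect with a warning.
#' @return an [Interactome-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("TNF\tIL6\tdirect\tbinding", "IL6\tSTAT3\tdirect"), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path, dialect = c("tsv", "sif"),
                         sifMapping = c(pp = "direct", pd = "indirect")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  lines <- raw[keep]
  if (dialect == "tsv" && length(lines) &&
      grepl("^gene", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  if (!length(lines)) stop("empty interactome")

  if (dialect == "tsv") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf < 3L)
    if (length(bad))
      stop("malformed line ", lineno[bad[1L]], ": expected at least 3 ",
           "tab-separated fields, got ", nf[bad[1L]])
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 2L)
    kind <- vapply(parts, `[[`, "", 3L)
    action <- vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "", "")
    Interactome(from, to, kind = kind, action = action)
  } else {
    if (is.character(sifMapping) && length(sifMapping) == 1L &&
        is.null(names(sifMapping)) && file.exists(sifMapping))
      sifMapping <- unlist(yaml::read_yaml(sifMapping))
    parts <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(parts)
    bad <- which(nf == 2L)
    if (length(bad))
      stop("malformed line ", lineno[bad[1L]],
           ": SIF needs 'nodeA relation nodeB...' or a lone node name")
    iso <- vapply(parts[nf == 1L], `[[`, "", 1L)
    parts <- parts[nf >= 3L]
    from <- character(); to <- character(); rel <- character()
    for (p in parts) {
      tgt <- p[-(1:2)]
      from <- c(from, rep(p[[1L]], length(tgt)))
      to <- c(to, tgt)
      rel <- c(rel, rep(p[[2L]], length(tgt)))
    }
    kind <- unname(sifMapping[rel])
    unknown <- is.na(kind)
    if (any(unknown)) {
      warning("unmapped SIF relation(s) treated as indirect: ",
              paste(unique(rel[unknown]), collapse = ", "))
      kind[unknown] <- "indirect"
    }
    Interactome(from, to, kind = kind, action = rel, extraNodes = iso)
  }
}

#' Write a network to disk
#'
#' \code{"graphml"} preserves everything: node attributes \code{seed}
#' (logical) and \code{role} (\code{"seed"}/\code{"connector"}) for candidate
#' networks, edge attributes \code{kind}, \code{action}, \code{nrefs};
#' reading the file back with [readNetwork()] reproduces nodes, edges and
#' seed/connector flags exactly. \code{"tsv"} and \code{"sif"} write the edge
#' list (SIF also writes isolated nodes as single-token lines; TSV lists them
#' in a comment).
#'
#' @param net an [Interactome-class] or [CandidateNetwork-class].
#' @param path output file.
#' @param dialect \code{"graphml"}, \code{"tsv"} or \code{"sif"}.
#' @return invisibly, \code{path}.
#' @export
writeNetwork <- function(net, path, dialect = c("graphml", "tsv", "sif")) {
  dialect <- match.arg(dialect)
  isCand <- is(net, "CandidateNetwork")
  ed <- if (isCand) {
    data.frame(from = net@edges$from, to = net@edges$to, kind = "direct",
               action = "", nrefs = 1L, stringsAsFactors = FALSE)
  } else net@edges
  nodes <- if (isCand) net@nodes else net@nodes

  if (dialect == "graphml") {
    vattr <- data.frame(name = nodes, stringsAsFactors = FALSE)
    if (isCand) {
      vattr$seed <- nodes %in% net@seedNodes
      vattr$role <- ifelse(vattr$seed, "seed", "connector")
    }
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vattr)
    igraph::write_graph(g, path, format = "graphml")
  } else if (dialect == "tsv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("geneA\tgeneB\tkind\taction", con)
    iso <- setdiff(nodes, c(ed$from, ed$to))
    if (length(iso))
      writeLines(paste0("# isolated nodes: ", paste(iso, collapse = ",")), con)
    if (nrow(ed)) {
      rep_rows <- rep(seq_len(nrow(ed)), ed$nrefs)
      e2 <- ed[rep_rows, , drop = FALSE]
      writeLines(paste(e2$from, e2$to, e2$kind, e2$action, sep = "\t"), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    if (nrow(ed)) {
      rel <- ifelse(nzchar(ed$action), ed$action, ed$kind)
      writeLines(paste(ed$from, rel, ed$to), con)
    }
    iso <- setdiff(nodes, c(ed$from, ed$to))
    if (length(iso)) writeLines(iso, con)
  }
  invisible(path)
}

#' Read a network written by [writeNetwork()] in GraphML
#'
#' Returns a [CandidateNetwork-class] when the file carries seed/connector
#' roles, otherwise an [Interactome-class].
#'
#' @param path GraphML file.
#' @return [CandidateNetwork-class] or [Interactome-class].
#' @export
readNetwork <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nm <- igraph::V(g)$name
  eds <- igraph::as_data_frame(g, what = "edges")
  if ("seed" %in% igraph::vertex_attr_names(g)) {
    seeds <- nm[as.logical(igraph::V(g)$seed)]
    .candidateNetwork(nodes = nm, seeds = seeds,
      edges = data.frame(from = pmin(eds$from, eds$to),
                         to = pmax(eds$from, eds$to), stringsAsFactors = FALSE))
  } else {
    kind <- if ("kind" %in% names(eds)) eds$kind else "direct"
    action <- if ("action" %in% names(eds)) eds$action else ""
    nrefs <- if ("nrefs" %in% names(eds)) as.integer(eds$nrefs) else 1L
    Interactome(eds$from, eds$to, kind = kind, action = action, nrefs = nrefs,
                extraNodes = nm)
  }
}

#' Read a seed gene list (one symbol per line, '#' comments allowed)
#'
#' @param path text file.
#' @return character vector of unique uppercase symbols, input order kept.
#' @export
readSeeds <- function(path) {
  raw <- readLines(path, warn = FALSE)
  s <- toupper(trimws(raw[!grepl("^\\s*(#|$)", raw)]))
  if (!length(s)) stop("no seed genes in ", path)
  unique(s)
}

## internal constructor: sorts members, derives connectors, induces edges
.candidateNetwork <- function(nodes, seeds, edges, score = NA_real_,
                              rank = NA_integer_) {
  nodes <- sort(unique(nodes))
  seeds <- sort(intersect(seeds, nodes))
  if (nrow(edges)) {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("CandidateNetwork", nodes = nodes, seedNodes = seeds,
      connectorNodes = setdiff(nodes, seeds), edges = edges,
      score = score, rank = rank)
}

## internal: induced direct edges among a node set
.induceEdges <- function(net, nodes) {
  ed <- net@edges
  ed <- ed[ed$kind == "direct" & ed$from %in% nodes & ed$to %in% nodes,
           c("from", "to"), drop = FALSE]
  ed <- unique(ed)
  rownames(ed) <- NULL
  ed
}
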