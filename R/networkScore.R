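#' Hypergeometric enrichment score of a candidate network
#'
#' The probability that a random draw of \code{nNetwork} genes from a
#' universe of \code{nUniverse} genes containing \code{kSeedsTotal} seeds
#' would capture at least \code{kSeedsIn} seeds -- the upper-tail
#' hypergeometric probability -- and its negative decimal logarithm, the
#' network score. A score of 2 corresponds to a 1-in-100 chance that the
#' observed seed content arises at random.
#'
#' @param nNetwork number of genes in the network.
#' @param kSeedsIn number of seed genes among them.
#' @param nUniverse number of genes in the universe (the loaded
#'   interactome).
#' @param kSeedsTotal number of seed genes in the universe.
#' @return a [NetworkScore-class].
#' @examples
#' enrichmentScore(35, 9, 10000, 9)
#' networkScore(enrichmentScore(1, 1, 100, 1))  # p = 1/100 -> score 2
#' @export
enrichmentScore <- function(nNetwork, kSeedsIn, nUniverse, kSeedsTotal) {
  if (kSeedsIn < 0 || kSeedsIn > min(nNetwork, kSeedsTotal))
    stop("kSeedsIn must lie in [0, min(nNetwork, kSeedsTotal)]")
  if (nNetwork > nUniverse || kSeedsTotal > nUniverse)
    stop("network and seed set cannot exceed the universe")
  p <- if (kSeedsIn == 0) 1
  else stats::phyper(kSeedsIn - 1, kSeedsTotal, nUniverse - kSeedsTotal,
                     nNetwork, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  new("NetworkScore", pEnrichment = p, score = -log10(p),
      pEmpirical = numeric(0), nPermutations = 0L, nullScores = numeric(0))
}

#' Network score from a chance probability
#'
#' The score transform alone: score = -log10(p).
#'
#' @param p probability in (0, 1].
#' @return a [NetworkScore-class].
#' @examples
#' networkScore(scoreFromProbability(0.01))  # 2
#' @export
scoreFromProbability <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("p must be a single probability in (0, 1]")
  new("NetworkScore", pEnrichment = p, score = -log10(p),
      pEmpirical = numeric(0), nPermutations = 0L, nullScores = numeric(0))
}

## internal: score (numeric) of the network found for integer seed ids
.scoreSeedSet <- function(G, sidx, maxNodes, pad) {
  res <- suppressWarnings(.searchConnectors(G, sidx, maxNodes, pad))
  n <- length(res$tree); k <- length(res$placed)
  p <- if (k == 0) 1
  else stats::phyper(k - 1, length(sidx), G$n - length(sidx), n,
                     lower.tail = FALSE)
  -log10(min(max(p, .Machine$double.xmin), 1))
}

## internal: draw a seed set matched on degree deciles of `sidx`
.drawMatched <- function(G, sidx, decile) {
  want <- table(decile[sidx])
  picked <- integer(0)
  for (b in names(want)) {
    pool <- setdiff(which(decile == as.integer(b)), picked)
    k <- want[[b]]
    if (length(pool) >= k) picked <- c(picked, sample(pool, k))
    else picked <- c(picked, pool)
  }
  short <- length(sidx) - length(picked)
  if (short > 0)
    picked <- c(picked, sample(setdiff(seq_len(G$n), picked), short))
  sort(picked)
}

#' Permutation null for the network score
#'
#' Estimates how often randomly matched seed sets produce a network score at
#' least as high as the observed one. Each permutation draws
#' \code{length(seeds)} genes from the interactome -- uniformly, or
#' stratified by degree decile of the observed seeds
#' (\code{"degree_matched"}, the conservative default for interactome
#' nulls) -- reruns the connector search, and records the resulting score.
#' The empirical p-value uses the add-one rule
#' \eqn{(1 + \#\{score_{perm} \ge score_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param net an [Interactome-class].
#' @param seeds observed seed gene symbols (must have >= 1 present in
#'   \code{net}).
#' @param nPermutations number of random seed sets (default 99).
#' @param matching \code{"degree_matched"} or \code{"uniform"}.
#' @param rngSeed integer seed for reproducible draws.
#' @param maxNodes,pad passed to the connector search (padding is off by
#'   default here; the score depends only on seed capture and network
#'   size).
#' @return a [NetworkScore-class] carrying the observed enrichment score,
#'   the permuted scores and the empirical p-value.
#' @export
permutationNull <- function(net, seeds, nPermutations = 99L,
                            matching = c("degree_matched", "uniform"),
                            rngSeed = 1L, maxNodes = 35L, pad = FALSE) {
  matching <- match.arg(matching)
  if (nPermutations < 1L) stop("nPermutations must be >= 1")
  seeds <- unique(toupper(seeds))
  G <- .netIndex(net)
  sidx <- sort(match(seeds, G$nodes))
  sidx <- sidx[!is.na(sidx)]
  if (!length(sidx)) stop("no seeds in interactome")
  if (length(sidx) > G$n) stop("more seeds than interactome nodes")

  observed <- .scoreSeedSet(G, sidx, as.integer(maxNodes), pad)

  decile <- NULL
  if (matching == "degree_matched") {
    br <- unique(stats::quantile(G$deg, probs = seq(0, 1, 0.1)))
    decile <- as.integer(cut(G$deg, breaks = br, include.lowest = TRUE))
  }
  set.seed(as.integer(rngSeed))
  nullScores <- vapply(seq_len(nPermutations), function(i) {
    draw <- if (matching == "uniform") sort(sample(G$n, length(sidx)))
    else .drawMatched(G, sidx, decile)
    .scoreSeedSet(G, draw, as.integer(maxNodes), pad)
  }, numeric(1))

  pEmp <- (1 + sum(nullScores >= observed)) / (nPermutations + 1)
  new("NetworkScore", pEnrichment = 10^(-observed), score = observed,
      pEmpirical = pEmp, nPermutations = as.integer(nPermutations),
      nullScores = nullScores)
}

#' Generic gene-set annotation enrichment
#'
#' One-sided Fisher exact test per annotation term on the 2x2 table
#' (membership in the gene set x membership in the term), with
#' Benjamini-Hochberg adjustment across terms. Purely generic: results
#' depend entirely on the annotation map supplied by the user.
#'
#' @param geneSet character vector of genes (must be within
#'   \code{universe}).
#' @param annotation named list mapping term -> character vector of genes.
#' @param universe character vector of all genes under consideration.
#' @return data.frame (term, nTerm, overlap, pFisher, pBH), sorted by
#'   pFisher.
#' @export
annotationEnrichment <- function(geneSet, annotation, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  geneSet <- unique(toupper(geneSet))
  if (!all(geneSet %in% universe))
    stop("geneSet must be a subset of the universe")
  rows <- lapply(names(annotation), function(term) {
    tg <- intersect(unique(toupper(annotation[[term]])), universe)
    a <- length(intersect(geneSet, tg))
    b <- length(geneSet) - a
    c <- length(tg) - a
    d <- length(universe) - a - b - c
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2L),
                            alternative = "greater")$p.value
    data.frame(term = term, nTerm = length(tg), overlap = a, pFisher = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pBH <- stats::p.adjust(out$pFisher, method = "BH")
  out <- out[order(out$pFisher, out$term), ]
  rownames(out) <- NULL
  out
}
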