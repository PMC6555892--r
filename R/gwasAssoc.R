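## Candidate-gene association against GWAS summary statistics:
## flanking-window SNP-to-gene assignment, LD-based independent-test
## counting, per-gene Bonferroni correction, and a replication pass.

#' Read gene coordinates from a BED3+1 file
#'
#' Columns: chrom, start, end, symbol. BED's 0-based half-open intervals
#' are converted to the internal 1-based inclusive convention on read.
#'
#' @param path BED file ('#' and 'track' lines skipped).
#' @return a \code{GRanges} with metadata column \code{symbol} (uppercase).
#' @export
readGenesBed <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|track|$)", raw)]
  if (!length(raw)) stop("no gene records in ", path)
  parts <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    stop("BED3+1 requires 4 columns: chrom, start, end, symbol")
  chrom <- vapply(parts, `[[`, "", 1L)
  start0 <- as.numeric(vapply(parts, `[[`, "", 2L))
  end0 <- as.numeric(vapply(parts, `[[`, "", 3L))
  sym <- toupper(vapply(parts, `[[`, "", 4L))
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1, end = end0))
  S4Vectors::mcols(gr)$symbol <- sym
  gr
}

#' Extend gene bodies into SNP-attribution windows
#'
#' Each gene body is extended \code{windowKb} kilobases upstream and
#' downstream; the window is clipped at position 1.
#'
#' @param genes \code{GRanges} of gene bodies with a \code{symbol} column.
#' @param windowKb flank size in kilobases (default 100).
#' @return \code{GRanges} of windows, same metadata.
#' @export
geneWindows <- function(genes, windowKb = 100) {
  if (windowKb < 0) stop("windowKb must be non-negative")
  w <- round(windowKb * 1000)
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(
      start = pmax(1, GenomicRanges::start(genes) - w),
      end = GenomicRanges::end(genes) + w))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(genes)
  gr
}

#' Read GWAS summary statistics
#'
#' Tab-separated with a header containing columns SNP, CHR, POS, P
#' (case-insensitive; extra columns ignored). P-values recorded as 0 are
#' floored at the smallest positive p in the table, with a warning, so that
#' downstream log and correction arithmetic stays finite.
#'
#' @param path TSV file.
#' @return \code{GRanges} (one position per SNP) with metadata columns
#'   \code{snp} and \code{p}.
#' @export
readGwasTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  names(df) <- toupper(names(df))
  need <- c("SNP", "CHR", "POS", "P")
  if (!all(need %in% names(df)))
    stop("GWAS table needs columns SNP, CHR, POS, P; missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  p <- as.numeric(df$P)
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    floorP <- min(p[p > 0])
    warning(sum(p == 0), " p-value(s) of 0 floored at ", floorP)
    p[p == 0] <- floorP
  }
  gr <- GenomicRanges::GRanges(as.character(df$CHR),
    IRanges::IRanges(start = as.numeric(df$POS), width = 1))
  S4Vectors::mcols(gr)$snp <- as.character(df$SNP)
  S4Vectors::mcols(gr)$p <- p
  gr
}

#' Assign SNPs to genes by flanking windows
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within
#' the gene's window (gene body plus \code{windowKb} kb either side). A SNP
#' inside two overlapping windows is assigned to both genes.
#'
#' @param genes \code{GRanges} of gene bodies with \code{symbol}.
#' @param snps \code{GRanges} of SNPs with \code{snp} and \code{p} (as from
#'   [readGwasTable()]).
#' @param windowKb flank in kilobases (default 100).
#' @return named list: gene symbol -> data.frame (snp, chrom, pos, p). Genes
#'   with no assigned SNP get a zero-row data.frame.
#' @export
assignSnps <- function(genes, snps, windowKb = 100) {
  win <- geneWindows(genes, windowKb)
  shared <- intersect(as.character(unique(GenomicRanges::seqnames(win))),
                      as.character(unique(GenomicRanges::seqnames(snps))))
  if (!length(shared) && length(snps) && length(win))
    warning("gene and SNP chromosome names share no values; ",
            "check assembly/naming compatibility")
  ov <- suppressWarnings(GenomicRanges::findOverlaps(snps, win))
  sym <- S4Vectors::mcols(win)$symbol
  out <- stats::setNames(vector("list", length(sym)), sym)
  empty <- data.frame(snp = character(), chrom = character(),
                      pos = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  for (i in seq_along(sym)) out[[i]] <- empty
  if (length(ov)) {
    hitdf <- data.frame(
      gene = sym[S4Vectors::subjectHits(ov)],
      snp = S4Vectors::mcols(snps)$snp[S4Vectors::queryHits(ov)],
      chrom = as.character(GenomicRanges::seqnames(snps))[
        S4Vectors::queryHits(ov)],
      pos = GenomicRanges::start(snps)[S4Vectors::queryHits(ov)],
      p = S4Vectors::mcols(snps)$p[S4Vectors::queryHits(ov)],
      stringsAsFactors = FALSE)
    for (g in unique(hitdf$gene)) {
      sub <- hitdf[hitdf$gene == g, c("snp", "chrom", "pos", "p")]
      sub <- sub[order(sub$pos, sub$snp), ]
      rownames(sub) <- NULL
      out[[g]] <- sub
    }
  }
  out
}

#' Normalised linkage disequilibrium D' from haplotype counts
#'
#' For two biallelic loci with haplotype counts \code{nAB, nAb, naB, nab}:
#' D = p(AB) - p(A)p(B); D' = |D| / Dmax, where Dmax = min(p(A)p(b),
#' p(a)p(B)) when D > 0 and min(p(A)p(B), p(a)p(b)) when D < 0; D' = 0 when
#' D = 0. Undefined (an error) when either locus is monomorphic.
#'
#' @param nAB,nAb,naB,nab haplotype counts (AB = both major alleles).
#' @return D' in [0, 1].
#' @examples
#' dprime(50, 0, 0, 50)  # complete coupling: 1
#' dprime(25, 25, 25, 25)  # independence: 0
#' @export
dprime <- function(nAB, nAb, naB, nab) {
  tot <- nAB + nAb + naB + nab
  if (tot < 1) stop("total haplotype count must be >= 1")
  pAB <- nAB / tot
  pA <- (nAB + nAb) / tot
  pB <- (nAB + naB) / tot
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("undefined D-prime: monomorphic locus")
  D <- pAB - pA * pB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  abs(D) / dmax
}

#' Build an LdTable
#'
#' @param snpA,snpB SNP identifier vectors (pairs).
#' @param dprimeValues D' per pair, in [0, 1].
#' @return an [LdTable-class]. Pairs are canonicalised (unordered);
#'   duplicate pairs keep the maximum D' (the conservative choice: more
#'   clustering, fewer independent tests).
#' @export
LdTable <- function(snpA = character(), snpB = character(),
                    dprimeValues = numeric()) {
  a <- as.character(snpA); b <- as.character(snpB)
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  d <- as.numeric(dprimeValues)[keep]
  if (length(a2)) {
    key <- paste(a2, b2, sep = "\r")
    mx <- tapply(d, key, max)
    first <- !duplicated(key)
    df <- data.frame(snpA = a2[first], snpB = b2[first],
                     dprime = as.numeric(mx[key[first]]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$snpA, df$snpB), ]
    rownames(df) <- NULL
  } else {
    df <- data.frame(snpA = character(), snpB = character(),
                     dprime = numeric(), stringsAsFactors = FALSE)
  }
  new("LdTable", pairs = df)
}

#' Read a pairwise D' table (TSV: SNP_A, SNP_B, DPRIME)
#' @param path TSV file with header.
#' @return an [LdTable-class].
#' @export
readLdTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  need <- c("SNP_A", "SNP_B", "DPRIME")
  if (!all(need %in% names(df)))
    stop("LD table needs columns SNP_A, SNP_B, DPRIME")
  LdTable(df$SNP_A, df$SNP_B, as.numeric(df$DPRIME))
}

#' Pairwise D' table from a haplotype matrix
#'
#' @param hap 0/1 matrix, rows = haplotypes, columns = SNPs (named).
#' @return an [LdTable-class] over all SNP pairs with defined D'
#'   (monomorphic columns are skipped with a warning).
#' @export
ldFromHaplotypes <- function(hap) {
  if (is.null(colnames(hap))) stop("haplotype matrix needs SNP column names")
  mono <- apply(hap, 2L, function(x) length(unique(x)) < 2L)
  if (any(mono))
    warning("monomorphic SNP(s) skipped: ",
            paste(colnames(hap)[mono], collapse = ", "))
  hap <- hap[, !mono, drop = FALSE]
  ids <- colnames(hap)
  if (length(ids) < 2L) return(LdTable())
  pr <- utils::combn(seq_along(ids), 2L)
  dd <- apply(pr, 2L, function(ij) {
    x <- hap[, ij[1L]]; y <- hap[, ij[2L]]
    dprime(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
           sum(x == 0 & y == 1), sum(x == 0 & y == 0))
  })
  LdTable(ids[pr[1L, ]], ids[pr[2L, ]], dd)
}

#' Symmetric D' lookup
#'
#' @param ld an [LdTable-class].
#' @param a,b SNP identifiers (vectorised).
#' @return numeric D' values; NA for pairs not in the table.
#' @export
ldDprime <- function(ld, a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- stats::setNames(ld@pairs$dprime,
                         paste(ld@pairs$snpA, ld@pairs$snpB, sep = "\r"))
  unname(tab[key])
}

#' Count independent SNPs by LD clustering
#'
#' SNPs are clustered by the transitive closure of the relation
#' D' >= \code{threshold} (connected components of the LD graph); the number
#' of components is the number of independent tests. Inclusive threshold;
#' invariant to SNP input order.
#'
#' @param snpIds character vector of SNP identifiers.
#' @param ld an [LdTable-class].
#' @param threshold D' threshold in [0, 1] (default 0.8).
#' @param missingAs treat pairs absent from \code{ld} as D' = 0
#'   (\code{"zero"}, default) or raise an error (\code{"error"}).
#' @return list with \code{nIndependent} (integer) and \code{clusters}
#'   (named integer vector; clusters numbered by their lexicographically
#'   smallest member).
#' @export
countIndependent <- function(snpIds, ld, threshold = 0.8,
                             missingAs = c("zero", "error")) {
  missingAs <- match.arg(missingAs)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  ids <- sort(unique(as.character(snpIds)))
  if (!length(ids))
    return(list(nIndependent = 0L, clusters = stats::setNames(integer(0),
                                                              character(0))))
  if (missingAs == "error" && length(ids) > 1L) {
    pr <- utils::combn(ids, 2L)
    dd <- ldDprime(ld, pr[1L, ], pr[2L, ])
    if (anyNA(dd))
      stop("missing D' for pair(s): ",
           paste(pr[1L, is.na(dd)], pr[2L, is.na(dd)], sep = "-",
                 collapse = ", "))
  }
  p <- ld@pairs
  p <- p[p$snpA %in% ids & p$snpB %in% ids & p$dprime >= threshold, ,
         drop = FALSE]
  # union-find over the LD graph; roots kept at the smallest member index
  parent <- seq_along(ids)
  findRoot <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(p)) {
    ia <- match(p$snpA, ids); ib <- match(p$snpB, ids)
    for (r in seq_along(ia)) {
      ra <- findRoot(ia[r]); rb <- findRoot(ib[r])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_along(ids), findRoot, integer(1))
  cl <- stats::setNames(match(root, sort(unique(root))), ids)
  list(nIndependent = length(unique(root)), clusters = cl)
}

#' Per-gene association summary with LD-aware Bonferroni correction
#'
#' Reports, for one gene and its assigned SNPs: the total SNP count, the
#' count with raw p < 0.05, the number of independent SNPs (LD clusters at
#' the D' threshold), the smallest raw p, and the smallest Bonferroni
#' corrected p where the correction multiplies by the gene's independent-SNP
#' count and is capped at 1.
#'
#' @param symbol gene symbol.
#' @param snps data.frame with at least columns \code{snp} and \code{p}
#'   (as returned by [assignSnps()]); may have zero rows.
#' @param ld an [LdTable-class].
#' @param threshold D' threshold (default 0.8).
#' @param missingAs passed to [countIndependent()].
#' @return one-row data.frame (symbol, nSnpsTotal, nSnpsP05, nIndependent,
#'   minPRaw, minPCorrected, significant, noSnps).
#' @export
summarizeGene <- function(symbol, snps, ld, threshold = 0.8,
                          missingAs = "zero") {
  if (is.null(snps) || nrow(snps) == 0L)
    return(data.frame(symbol = symbol, nSnpsTotal = 0L, nSnpsP05 = 0L,
                      nIndependent = 0L, minPRaw = NA_real_,
                      minPCorrected = NA_real_, significant = FALSE,
                      noSnps = TRUE, stringsAsFactors = FALSE))
  ci <- countIndependent(snps$snp, ld, threshold, missingAs)
  minP <- min(snps$p)
  corr <- min(1, minP * ci$nIndependent)
  data.frame(symbol = symbol, nSnpsTotal = nrow(snps),
             nSnpsP05 = sum(snps$p < 0.05),
             nIndependent = ci$nIndependent,
             minPRaw = minP, minPCorrected = corr,
             significant = corr < 0.05, noSnps = FALSE,
             stringsAsFactors = FALSE)
}

#' Summarise association for every gene in an assignment
#'
#' @param assignments named list from [assignSnps()].
#' @inheritParams summarizeGene
#' @return data.frame, one row per gene (see [summarizeGene()]), in
#'   assignment order.
#' @export
summarizeGenes <- function(assignments, ld, threshold = 0.8,
                           missingAs = "zero") {
  out <- do.call(rbind, lapply(names(assignments), function(g)
    summarizeGene(g, assignments[[g]], ld, threshold, missingAs)))
  rownames(out) <- NULL
  out
}

#' Replication of candidate SNPs in a second dataset
#'
#' Looks up each candidate SNP (significant in the primary dataset) in a
#' second GWAS dataset and applies a Bonferroni correction over the number
#' of independent candidate SNPs carried forward. A SNP absent from the
#' second dataset is recorded as \code{"untested"}, not an error.
#'
#' @param candidates data.frame with columns \code{snp} and \code{gene}
#'   (one row per candidate SNP; a SNP in two genes may appear twice).
#' @param secondDataset \code{GRanges} from [readGwasTable()], or a
#'   data.frame with columns \code{snp} and \code{p}.
#' @param ld an [LdTable-class] (for the independent-candidate count).
#' @param threshold D' threshold (default 0.8).
#' @param alpha replication significance level (default 0.05).
#' @return list with \code{perSnp} (snp, gene, pSecond, pCorrected, status),
#'   \code{perGene} (gene, nTested, nReplicated, replicated) and
#'   \code{nIndependent}.
#' @export
replicateCandidates <- function(candidates, secondDataset, ld,
                                threshold = 0.8, alpha = 0.05) {
  if (methods::is(secondDataset, "GRanges"))
    secondDataset <- data.frame(
      snp = S4Vectors::mcols(secondDataset)$snp,
      p = S4Vectors::mcols(secondDataset)$p, stringsAsFactors = FALSE)
  m <- if (nrow(candidates))
    countIndependent(unique(candidates$snp), ld, threshold)$nIndependent
  else 0L
  p2 <- secondDataset$p[match(candidates$snp, secondDataset$snp)]
  corr <- pmin(1, p2 * m)
  status <- ifelse(is.na(p2), "untested",
                   ifelse(corr < alpha, "replicated", "not_replicated"))
  perSnp <- data.frame(snp = candidates$snp, gene = candidates$gene,
                       pSecond = p2, pCorrected = corr, status = status,
                       stringsAsFactors = FALSE)
  genes <- unique(candidates$gene)
  perGene <- data.frame(
    gene = genes,
    nTested = vapply(genes, function(g)
      sum(perSnp$gene == g & perSnp$status != "untested"), integer(1)),
    nReplicated = vapply(genes, function(g)
      sum(perSnp$gene == g & perSnp$status == "replicated"), integer(1)),
    stringsAsFactors = FALSE)
  perGene$replicated <- perGene$nReplicated > 0L
  rownames(perGene) <- NULL
  list(perSnp = perSnp, perGene = perGene, nIndependent = m)
}
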