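## Synthetic inputs with planted ground truth: a scale-free interactome in
## which designated seed genes are wired to a connected scaffold of planted
## connector genes, gene coordinates on synthetic chromosomes, and GWAS
## summary statistics with LD-block structure and one planted causal gene.
## Everything is reproducible from a single integer seed, so the whole
## pipeline is testable offline.

#' Parameters for the synthetic-data generator
#'
#' Defaults describe the study conditions the package is exercised under:
#' nine seed genes (the number shared across two or more of the seven
#' autoimmune diseases that motivated the approach), a scale-free
#' interactome of 400 genes grown by preferential attachment, six planted
#' connector genes, a 5\% noise-edge fraction, eight SNPs per gene in LD
#' blocks of four with within-block D' 0.9, and a causal p of 1e-8 at the
#' index SNP of the causal gene's first block.
#'
#' @param nGenes total genes in the interactome.
#' @param attachment edges per new node in preferential-attachment growth.
#' @param nSeeds number of seed genes.
#' @param nPlantedConnectors planted connectors wiring the seeds together.
#' @param noiseEdgeFraction extra uniformly random edges, as a fraction of
#'   the background edge count.
#' @param nSnpsPerGene SNPs simulated in each gene's window.
#' @param ldBlockSize consecutive SNPs per LD block.
#' @param withinBlockDprime D' shared by SNP pairs within a block (across
#'   blocks D' = 0).
#' @param causalGene symbol of the causal gene, NULL for the first planted
#'   connector, or NA to plant no signal (a fully null GWAS).
#' @param causalP association p planted at the causal gene's index SNP.
#' @param rngSeed integer seed.
#' @return a list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nGenes = 400L, attachment = 2L, nSeeds = 9L,
                          nPlantedConnectors = 6L, noiseEdgeFraction = 0.05,
                          nSnpsPerGene = 8L, ldBlockSize = 4L,
                          withinBlockDprime = 0.9, causalGene = NULL,
                          causalP = 1e-8, rngSeed = 1L) {
  spec <- list(nGenes = as.integer(nGenes), attachment = as.integer(attachment),
               nSeeds = as.integer(nSeeds),
               nPlantedConnectors = as.integer(nPlantedConnectors),
               noiseEdgeFraction = noiseEdgeFraction,
               nSnpsPerGene = as.integer(nSnpsPerGene),
               ldBlockSize = as.integer(ldBlockSize),
               withinBlockDprime = withinBlockDprime,
               causalGene = causalGene, causalP = causalP,
               rngSeed = as.integer(rngSeed))
  if (spec$nSeeds + spec$nPlantedConnectors > spec$nGenes)
    stop("nSeeds + nPlantedConnectors must not exceed nGenes")
  if (spec$withinBlockDprime < 0 || spec$withinBlockDprime > 1)
    stop("withinBlockDprime must lie in [0, 1]")
  if (spec$noiseEdgeFraction < 0) stop("noiseEdgeFraction must be >= 0")
  if (spec$nSeeds < 1L || spec$nPlantedConnectors < 1L)
    stop("need at least one seed and one planted connector")
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a synthetic interactome with a planted seed-connector module
#'
#' Background genes form a scale-free graph (preferential attachment).
#' Planted connectors form a connected scaffold (a path), each anchored to
#' the background; every seed attaches to at least one planted connector
#' (round-robin, so each connector carries a seed whenever
#' \code{nSeeds >= nPlantedConnectors}). Uniform noise edges are then
#' added. All planted edges are direct; noise edges are split between
#' direct and indirect so the direct-interaction filter is exercised.
#'
#' @param spec a [syntheticSpec()].
#' @return list: \code{net} ([Interactome-class]), \code{seeds},
#'   \code{connectors} (character vectors of planted truth).
#' @export
makeInteractome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$rngSeed)
  nBg <- spec$nGenes - spec$nSeeds - spec$nPlantedConnectors
  if (nBg < spec$attachment + 1L)
    stop("infeasible spec: too few background genes")
  bg <- sprintf("G%04d", seq_len(nBg))
  conn <- sprintf("CONN%02d", seq_len(spec$nPlantedConnectors))
  seeds <- sprintf("SEED%02d", seq_len(spec$nSeeds))

  g <- igraph::sample_pa(nBg, power = 1, m = spec$attachment,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- bg[el[, 1L]]; to <- bg[el[, 2L]]

  # connector scaffold: a path, each connector also anchored to background
  if (spec$nPlantedConnectors > 1L) {
    from <- c(from, conn[-length(conn)])
    to <- c(to, conn[-1L])
  }
  anchor <- sample(bg, spec$nPlantedConnectors, replace = TRUE)
  from <- c(from, conn); to <- c(to, anchor)

  # seeds: round-robin over connectors guarantees full connector coverage
  host <- conn[((seq_len(spec$nSeeds) - 1L) %% spec$nPlantedConnectors) + 1L]
  from <- c(from, seeds); to <- c(to, host)

  nNoise <- round(spec$noiseEdgeFraction * nrow(el))
  kinds <- rep("direct", length(from))
  if (nNoise > 0) {
    all <- c(bg, conn, seeds)
    na <- sample(all, nNoise, replace = TRUE)
    nb <- sample(all, nNoise, replace = TRUE)
    ok <- na != nb
    from <- c(from, na[ok]); to <- c(to, nb[ok])
    kinds <- c(kinds, sample(c("direct", "indirect"), sum(ok),
                             replace = TRUE))
  }
  net <- suppressWarnings(
    Interactome(from, to, kind = kinds, action = "synthetic",
                extraNodes = c(bg, conn, seeds)))
  list(net = net, seeds = seeds, connectors = conn)
}

#' Synthetic gene coordinates on non-overlapping windows
#'
#' Genes are laid out 400 kb apart (gene body 20 kb) on synthetic
#' chromosomes of 50 genes each, so the default 100-kb flanking windows
#' never overlap.
#'
#' @param symbols gene symbols.
#' @return \code{GRanges} with \code{symbol} metadata.
#' @export
makeGeneCoords <- function(symbols) {
  i <- seq_along(symbols)
  chrom <- paste0("chr", (i - 1L) %/% 50L + 1L)
  start <- ((i - 1L) %% 50L) * 400000 + 150001
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start, end = start + 19999))
  S4Vectors::mcols(gr)$symbol <- toupper(symbols)
  gr
}

#' Generate GWAS summary statistics with LD-block structure
#'
#' Each gene receives \code{nSnpsPerGene} SNPs evenly spaced across its
#' window, grouped into consecutive LD blocks of \code{ldBlockSize}; SNP
#' pairs within a block get D' = \code{withinBlockDprime}, across blocks
#' D' = 0 (absent from the table). Each block draws one association p from
#' Uniform(0,1) shared by its SNPs -- marginally every null SNP's p is
#' uniform, and the dependence mirrors the high within-block LD. The causal
#' gene's first-block index SNP is overridden with \code{causalP}.
#'
#' @param spec a [syntheticSpec()].
#' @param genes \code{GRanges} with \code{symbol} (e.g. [makeGeneCoords()]).
#' @param rngSeed seed for this dataset (default \code{spec$rngSeed}); pass
#'   a different value to draw an independent replication dataset with the
#'   same planted causal signal.
#' @return list: \code{gwas} (\code{GRanges} with \code{snp}, \code{p}),
#'   \code{ld} ([LdTable-class]), \code{truth} (causal gene/SNP and the
#'   per-gene block map).
#' @export
makeGwas <- function(spec, genes, rngSeed = spec$rngSeed) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  causal <- spec$causalGene
  sym <- S4Vectors::mcols(genes)$symbol
  if (is.null(causal)) causal <- grep("^CONN", sym, value = TRUE)[1L]
  causal <- as.character(causal)  # NA means: plant no causal signal
  if (!is.na(causal) && !(causal %in% sym))
    stop("causal gene not in gene coordinates: ", causal)
  set.seed(as.integer(rngSeed))

  win <- geneWindows(genes, 100)
  nS <- spec$nSnpsPerGene
  snpChrom <- character(0); snpPos <- numeric(0)
  snpId <- character(0); snpP <- numeric(0)
  ldA <- character(0); ldB <- character(0)
  blocks <- list()
  causalSnp <- NA_character_
  for (i in seq_along(win)) {
    g <- sym[i]
    pos <- round(seq(GenomicRanges::start(win)[i],
                     GenomicRanges::end(win)[i], length.out = nS))
    ids <- sprintf("rs_%s_%02d", g, seq_len(nS))
    blk <- (seq_len(nS) - 1L) %/% spec$ldBlockSize + 1L
    p <- stats::runif(max(blk))[blk]
    if (!is.na(causal) && g == causal) {
      p[1L] <- spec$causalP
      causalSnp <- ids[1L]
    }
    for (b in unique(blk)) {
      members <- ids[blk == b]
      if (length(members) > 1L) {
        pr <- utils::combn(members, 2L)
        ldA <- c(ldA, pr[1L, ]); ldB <- c(ldB, pr[2L, ])
      }
    }
    snpChrom <- c(snpChrom,
                  rep(as.character(GenomicRanges::seqnames(win))[i], nS))
    snpPos <- c(snpPos, pos); snpId <- c(snpId, ids); snpP <- c(snpP, p)
    blocks[[g]] <- blk
  }
  gwas <- GenomicRanges::GRanges(snpChrom,
    IRanges::IRanges(start = snpPos, width = 1))
  S4Vectors::mcols(gwas)$snp <- snpId
  S4Vectors::mcols(gwas)$p <- snpP
  ld <- LdTable(ldA, ldB, rep(spec$withinBlockDprime, length(ldA)))
  list(gwas = gwas, ld = ld,
       truth = list(causalGene = causal, causalSnp = causalSnp,
                    blocks = blocks))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Produces \code{edges.tsv}, \code{seeds.txt}, \code{genes.bed},
#' \code{gwas.tsv}, \code{gwas_replication.tsv}, \code{ld.tsv} and
#' \code{truth.json}, ready for [runPipeline()] or the \code{mina} command
#' line. The replication dataset redraws the null p-values (seed
#' \code{rngSeed + 1}) while keeping the planted causal signal.
#'
#' @param spec a [syntheticSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the truth list.
#' @export
writeSyntheticBundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  made <- makeInteractome(spec)
  genes <- makeGeneCoords(made$net@nodes)
  gw1 <- makeGwas(spec, genes, rngSeed = spec$rngSeed)
  gw2 <- makeGwas(spec, genes, rngSeed = spec$rngSeed + 1L)

  writeNetwork(made$net, file.path(dir, "edges.tsv"), "tsv")
  writeLines(made$seeds, file.path(dir, "seeds.txt"))
  writeGenesBed(genes, file.path(dir, "genes.bed"))
  writeGwasTable(gw1$gwas, file.path(dir, "gwas.tsv"))
  writeGwasTable(gw2$gwas, file.path(dir, "gwas_replication.tsv"))
  writeLdTable(gw1$ld, file.path(dir, "ld.tsv"))
  truth <- list(seeds = made$seeds, connectors = made$connectors,
                causalGene = gw1$truth$causalGene,
                causalSnp = gw1$truth$causalSnp)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(truth)
}

#' Write gene coordinates as BED3+1
#' @param genes \code{GRanges} with \code{symbol}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGenesBed <- function(genes, path) {
  writeLines(paste(as.character(GenomicRanges::seqnames(genes)),
                   GenomicRanges::start(genes) - 1L,
                   GenomicRanges::end(genes),
                   S4Vectors::mcols(genes)$symbol, sep = "\t"), path)
  invisible(path)
}

#' Write GWAS summary statistics as TSV (SNP, CHR, POS, P)
#' @param gwas \code{GRanges} with \code{snp}, \code{p}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGwasTable <- function(gwas, path) {
  df <- data.frame(SNP = S4Vectors::mcols(gwas)$snp,
                   CHR = as.character(GenomicRanges::seqnames(gwas)),
                   POS = GenomicRanges::start(gwas),
                   P = S4Vectors::mcols(gwas)$p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an LD table as TSV (SNP_A, SNP_B, DPRIME)
#' @param ld an [LdTable-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeLdTable <- function(ld, path) {
  df <- ld@pairs
  names(df) <- c("SNP_A", "SNP_B", "DPRIME")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
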