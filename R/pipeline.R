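## End-to-end orchestration: seeds -> ranked networks -> top network ->
## candidate genes/windows/SNPs -> validation in the primary GWAS dataset ->
## optional replication in a secondary dataset. The run report carries a
## provenance block (parameters + input checksums) so every number in it is
## traceable, and reruns on identical inputs are bit-identical.

#' Assemble and validate a pipeline run configuration
#'
#' @param edges path to the interaction edge list (TSV; see
#'   [readEdgeList()]).
#' @param seeds path to the seed gene list.
#' @param genes path to gene coordinates (BED3+1).
#' @param gwas path to primary GWAS summary statistics (TSV).
#' @param ld path to the pairwise D' table (TSV).
#' @param gwasReplication optional path to a secondary GWAS dataset.
#' @param maxNodes network node budget (default 35).
#' @param windowKb SNP-attribution flank in kb (default 100).
#' @param dprimeThreshold D' threshold for independent-SNP counting
#'   (default 0.8).
#' @param permutations permutation-null size (0 skips the empirical null).
#' @param matching permutation seed matching, \code{"degree_matched"} or
#'   \code{"uniform"}.
#' @param pad pad the network to the full budget (default TRUE).
#' @param rngSeed seed for the permutation null.
#' @return validated config list of class \code{"RunConfig"}.
#' @export
runConfig <- function(edges, seeds, genes, gwas, ld, gwasReplication = NULL,
                      maxNodes = 35L, windowKb = 100, dprimeThreshold = 0.8,
                      permutations = 0L,
                      matching = c("degree_matched", "uniform"),
                      pad = TRUE, rngSeed = 1L) {
  cfg <- list(edges = edges, seeds = seeds, genes = genes, gwas = gwas,
              ld = ld, gwasReplication = gwasReplication,
              maxNodes = as.integer(maxNodes), windowKb = windowKb,
              dprimeThreshold = dprimeThreshold,
              permutations = as.integer(permutations),
              matching = match.arg(matching), pad = isTRUE(pad),
              rngSeed = as.integer(rngSeed))
  files <- c(cfg$edges, cfg$seeds, cfg$genes, cfg$gwas, cfg$ld,
             cfg$gwasReplication)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (cfg$maxNodes < 2L) stop("maxNodes must be >= 2")
  if (cfg$windowKb < 0) stop("windowKb must be >= 0")
  if (cfg$dprimeThreshold < 0 || cfg$dprimeThreshold > 1)
    stop("dprimeThreshold must lie in [0, 1]")
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [runConfig()] (snake_case accepted).
#'
#' @param path YAML file.
#' @return a \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  nm <- names(y)
  map <- c(gwas_replication = "gwasReplication", max_nodes = "maxNodes",
           window_kb = "windowKb", dprime_threshold = "dprimeThreshold",
           rng_seed = "rngSeed")
  nm[nm %in% names(map)] <- map[nm[nm %in% names(map)]]
  names(y) <- nm
  do.call(runConfig, y)
}

.stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", label, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full discovery pipeline
#'
#' Steps, in order: read the seed genes; build and score-rank candidate
#' networks on the direct interactome; select the top-ranked network;
#' identify candidate genes, their windows and assigned SNPs; validate
#' per-gene association in the primary GWAS dataset (LD-aware Bonferroni);
#' replicate significant candidate SNPs in the secondary dataset when one
#' is configured. Outputs are written atomically (temp file + rename) when
#' \code{outDir} is given; a rerun with the same config and inputs is
#' bit-identical.
#'
#' @param config a \code{"RunConfig"} from [runConfig()] /
#'   [readRunConfig()], or the path of a YAML config.
#' @param outDir optional directory for \code{report.json}, the network
#'   GraphML and the per-gene/per-SNP TSV tables.
#' @return the run report (a list): \code{provenance}, \code{network},
#'   \code{score}, \code{association}, \code{replication}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))

  files <- c(edges = config$edges, seeds = config$seeds,
             genes = config$genes, gwas = config$gwas, ld = config$ld)
  if (!is.null(config$gwasReplication))
    files <- c(files, gwas_replication = config$gwasReplication)
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- names(files)

  seeds <- .stage("read seeds", readSeeds(config$seeds))
  net <- .stage("read interactome", readEdgeList(config$edges))
  dnet <- directSubgraph(net)

  nets <- .stage("rank networks",
                 rankNetworks(dnet, seeds, config$maxNodes, pad = config$pad))
  top <- nets[[1L]]

  sc <- enrichmentScore(length(top@nodes), length(top@seedNodes),
                        length(dnet@nodes), sum(seeds %in% dnet@nodes))
  scoreBlock <- list(score = sc@score, pEnrichment = sc@pEnrichment)
  if (config$permutations > 0L) {
    pn <- .stage("permutation null",
                 permutationNull(dnet, seeds, config$permutations,
                                 config$matching, config$rngSeed,
                                 config$maxNodes, pad = config$pad))
    scoreBlock$pEmpirical <- pn@pEmpirical
    scoreBlock$nPermutations <- pn@nPermutations
  }

  genes <- .stage("read gene coordinates", readGenesBed(config$genes))
  candGenes <- genes[S4Vectors::mcols(genes)$symbol %in% top@nodes]
  gwas <- .stage("read GWAS", readGwasTable(config$gwas))
  ld <- .stage("read LD table", readLdTable(config$ld))
  assignments <- .stage("assign SNPs",
                        assignSnps(candGenes, gwas, config$windowKb))
  assoc <- .stage("summarize association",
                  summarizeGenes(assignments, ld, config$dprimeThreshold))

  # candidate SNPs carried to replication: per significant gene, the SNPs
  # whose per-gene corrected p clears 0.05
  cands <- do.call(rbind, lapply(seq_len(nrow(assoc)), function(i) {
    if (!isTRUE(assoc$significant[i])) return(NULL)
    g <- assoc$symbol[i]
    sn <- assignments[[g]]
    sn <- sn[pmin(1, sn$p * assoc$nIndependent[i]) < 0.05, , drop = FALSE]
    if (!nrow(sn)) return(NULL)
    data.frame(snp = sn$snp, gene = g, pPrimary = sn$p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cands))
    cands <- data.frame(snp = character(), gene = character(),
                        pPrimary = numeric(), stringsAsFactors = FALSE)

  replication <- NULL
  if (!is.null(config$gwasReplication)) {
    gwas2 <- .stage("read replication GWAS",
                    readGwasTable(config$gwasReplication))
    replication <- .stage("replicate",
                          replicateCandidates(cands, gwas2, ld,
                                              config$dprimeThreshold))
  }

  report <- list(
    provenance = list(
      parameters = config[c("maxNodes", "windowKb", "dprimeThreshold",
                            "permutations", "matching", "pad", "rngSeed")],
      inputs = checksums),
    network = list(
      nNetworks = length(nets),
      nodes = top@nodes, seedNodes = top@seedNodes,
      connectorNodes = top@connectorNodes,
      allScores = vapply(nets, function(x) x@score, numeric(1))),
    score = scoreBlock,
    association = assoc,
    candidates = cands,
    replication = if (is.null(replication)) "not run" else replication)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .atomicWrite(outDir, "network.graphml",
                 function(p) writeNetwork(top, p, "graphml"))
    .atomicWrite(outDir, "association.tsv", function(p)
      utils::write.table(assoc, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    if (!is.null(replication))
      .atomicWrite(outDir, "replication.tsv", function(p)
        utils::write.table(replication$perSnp, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    .atomicWrite(outDir, "report.json", function(p)
      jsonlite::write_json(report, p, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, force = TRUE))
  }
  report
}

.atomicWrite <- function(dir, name, writer) {
  tmp <- tempfile(tmpdir = dir)
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  file.rename(tmp, file.path(dir, name))
  ok <- TRUE
}
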