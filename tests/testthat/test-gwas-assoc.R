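mkGenes <- function(chrom, start, end, symbol) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$symbol <- symbol
  gr
}

mkSnps <- function(chrom, pos, snp, p) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  S4Vectors::mcols(gr)$snp <- snp
  S4Vectors::mcols(gr)$p <- p
  gr
}

test_that("flanking-window assignment: 100 kb boundaries and clipping at 1", {
  genes <- mkGenes("chr1", 500000, 600000, "GENE1")
  snps <- mkSnps("chr1", c(450000, 399999, 400000, 700000, 700001),
                 paste0("rs", 1:5), rep(0.5, 5))
  asg <- assignSnps(genes, snps, windowKb = 100)
  expect_setequal(asg$GENE1$snp, c("rs1", "rs3", "rs4"))
  # window start clips at 1 when the gene sits near the chromosome start
  w <- geneWindows(mkGenes("chr1", 50000, 60000, "EDGE"), 100)
  expect_equal(GenomicRanges::start(w), 1L)
  expect_equal(GenomicRanges::end(w), 160000L)
  expect_error(geneWindows(genes, -1), "non-negative")
})

test_that("a SNP in two overlapping windows is assigned to both genes", {
  genes <- mkGenes("chr1", c(100000, 150000), c(120000, 170000),
                   c("GA", "GB"))
  snps <- mkSnps("chr1", 130000, "rsX", 0.01)
  asg <- assignSnps(genes, snps)
  expect_equal(asg$GA$snp, "rsX")
  expect_equal(asg$GB$snp, "rsX")
})

test_that("zero-width flank reduces assignment to gene-body containment", {
  genes <- mkGenes("chr2", 1000, 2000, "G")
  snps <- mkSnps("chr2", c(999, 1000, 2000, 2001), paste0("s", 1:4),
                 rep(0.5, 4))
  asg <- assignSnps(genes, snps, windowKb = 0)
  expect_setequal(asg$G$snp, c("s2", "s3"))
})

test_that("chromosomes are respected and incompatible naming warns", {
  genes <- mkGenes("chr1", 1000, 2000, "G")
  snps <- mkSnps("chr2", 1500, "s1", 0.5)
  expect_warning(asg <- assignSnps(genes, snps, windowKb = 0),
                 "chromosome")
  expect_equal(nrow(asg$G), 0L)
})

test_that("D-prime matches the normalised-LD formula", {
  expect_equal(dprime(50, 0, 0, 50), 1)   # complete coupling
  expect_equal(dprime(25, 25, 25, 25), 0) # independence
  # hand-computed: pAB=.4, pA=pB=.5, D=.15, Dmax=min(.25,.25)=.25
  expect_equal(dprime(40, 10, 10, 40), 0.6)
  # repulsion-phase counts: D<0 branch, hand-computed
  # pAB=.1, pA=pB=.5, D=-.15, Dmax=min(.25,.25)=.25 -> 0.6
  expect_equal(dprime(10, 40, 40, 10), 0.6)
  expect_error(dprime(50, 50, 0, 0), "monomorphic")
  expect_error(dprime(0, 0, 0, 0), "count")
})

test_that("LD tables symmetrise, deduplicate and read from TSV", {
  ld <- LdTable(c("b", "a", "a"), c("a", "b", "c"), c(0.9, 0.7, 0.2))
  expect_equal(ldDprime(ld, "a", "b"), 0.9)  # duplicates keep the max
  expect_equal(ldDprime(ld, "b", "a"), 0.9)  # symmetric lookup
  expect_true(is.na(ldDprime(ld, "b", "c")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLdTable(ld, f)
  expect_identical(readLdTable(f)@pairs, ld@pairs)
})

test_that("haplotype-derived D' agrees with direct counts", {
  hap <- cbind(A = c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0),
               B = c(1, 1, 1, 0, 0, 0, 0, 1, 1, 0),
               C = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0))
  ld <- ldFromHaplotypes(hap)
  nAB <- sum(hap[, "A"] == 1 & hap[, "B"] == 1)
  nAb <- sum(hap[, "A"] == 1 & hap[, "B"] == 0)
  naB <- sum(hap[, "A"] == 0 & hap[, "B"] == 1)
  nab <- sum(hap[, "A"] == 0 & hap[, "B"] == 0)
  expect_equal(ldDprime(ld, "A", "B"), dprime(nAB, nAb, naB, nab))
  expect_warning(ldFromHaplotypes(cbind(M = rep(1, 4), N = c(0, 1, 0, 1))),
                 "monomorphic")
})

test_that("independent-SNP counting is LD-graph component counting", {
  ld <- LdTable(c("s1", "s1", "s2"), c("s2", "s3", "s3"), c(0.9, 0.1, 0.1))
  ci <- countIndependent(c("s1", "s2", "s3"), ld)
  expect_equal(ci$nIndependent, 2L)
  expect_equal(unname(ci$clusters["s1"]), unname(ci$clusters["s2"]))
  # all pairs below threshold: every SNP independent
  ld0 <- LdTable("a", "b", 0.2)
  expect_equal(countIndependent(letters[1:5], ld0)$nIndependent, 5L)
  # single SNP
  expect_equal(countIndependent("solo", ld0)$nIndependent, 1L)
  # inclusive threshold: D' exactly at the threshold clusters
  ldEq <- LdTable("x", "y", 0.8)
  expect_equal(countIndependent(c("x", "y"), ldEq, 0.8)$nIndependent, 1L)
  expect_error(countIndependent("a", ld0, threshold = 1.2), "0, 1")
  expect_error(countIndependent(c("a", "z"), ld0, missingAs = "error"),
               "missing")
})

test_that("independent-SNP counting is invariant to input order", {
  set.seed(5)
  ids <- sprintf("rs%02d", 1:8)
  pr <- t(utils::combn(ids, 2))
  ld <- LdTable(pr[, 1], pr[, 2], stats::runif(nrow(pr)))
  ref <- countIndependent(ids, ld, 0.6)
  for (i in 1:10) {
    perm <- sample(ids)
    out <- countIndependent(perm, ld, 0.6)
    expect_equal(out$nIndependent, ref$nIndependent)
    expect_identical(out$clusters, ref$clusters)
  }
})

test_that("per-gene summary arithmetic and the Bonferroni cap", {
  ld <- LdTable()  # no LD: every SNP its own test
  snps <- data.frame(snp = c("a", "b", "c"), p = c(0.001, 0.2, 0.04))
  s <- summarizeGene("G", snps, ld)
  expect_equal(s$nIndependent, 3L)
  expect_equal(s$minPRaw, 0.001)
  expect_equal(s$minPCorrected, 0.003)
  expect_equal(s$nSnpsP05, 2L)
  expect_true(s$significant)
  # single SNP: correction is the identity
  s1 <- summarizeGene("G", data.frame(snp = "a", p = 0.5), ld)
  expect_equal(s1$nIndependent, 1L)
  expect_equal(s1$minPCorrected, 0.5)
  # cap at 1
  snps10 <- data.frame(snp = sprintf("s%02d", 1:10), p = c(0.2, rep(0.9, 9)))
  expect_equal(summarizeGene("G", snps10, ld)$minPCorrected, 1)
  # corrected minimum is monotone in the independent-test count
  expect_true(all(diff(vapply(1:5, function(m)
    min(1, 0.01 * m), numeric(1))) >= 0))
  # empty assignment: zero counts, flagged
  s0 <- summarizeGene("G", NULL, ld)
  expect_true(s0$noSnps)
  expect_equal(s0$nSnpsTotal, 0L)
  expect_true(is.na(s0$minPRaw))
})

test_that("replication corrects over independent candidates and marks untested", {
  ld <- LdTable()
  second <- data.frame(snp = c("a", "b", "c", "d", "e"),
                       p = c(0.01, 0.02, 0.5, 0.5, 0.5))
  # one candidate, m = 1: corrected equals raw, replicated
  r1 <- replicateCandidates(data.frame(snp = "a", gene = "G1"), second, ld)
  expect_equal(r1$nIndependent, 1L)
  expect_equal(r1$perSnp$pCorrected, 0.01)
  expect_equal(r1$perSnp$status, "replicated")
  # five independent candidates, p = 0.02 -> corrected 0.10, not replicated
  cands <- data.frame(snp = letters[1:5], gene = rep("G1", 5))
  second2 <- data.frame(snp = letters[1:5], p = rep(0.02, 5))
  r5 <- replicateCandidates(cands, second2, ld)
  expect_equal(r5$nIndependent, 5L)
  expect_equal(unique(r5$perSnp$pCorrected), 0.1)
  expect_false(any(r5$perSnp$status == "replicated"))
  expect_false(r5$perGene$replicated)
  # candidate missing from the second dataset
  rm <- replicateCandidates(data.frame(snp = "zz", gene = "G9"), second, ld)
  expect_equal(rm$perSnp$status, "untested")
})

test_that("GWAS reader floors p = 0 and validates columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS\tP\tEXTRA", "rs1\tchr1\t100\t0.5\tx",
               "rs2\tchr1\t200\t0\tx", "rs3\tchr1\t300\t1e-4\tx"), f)
  expect_warning(g <- readGwasTable(f), "floored")
  expect_equal(S4Vectors::mcols(g)$p[2], 1e-4)
  writeLines(c("SNP\tCHR\tP", "rs1\tchr1\t0.5"), f)
  expect_error(readGwasTable(f), "POS")
})

test_that("BED genes convert to 1-based inclusive coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tmygene", f)
  g <- readGenesBed(f)
  expect_equal(GenomicRanges::start(g), 1000L)
  expect_equal(GenomicRanges::end(g), 2000L)
  expect_equal(S4Vectors::mcols(g)$symbol, "MYGENE")
})
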