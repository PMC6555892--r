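test_that("star topology: hub is the unique minimal connector", {
  net <- starInteractome()
  cn <- findConnectorNetwork(net, c("A", "B", "C"), maxNodes = 4,
                             pad = FALSE)
  expect_setequal(networkNodes(cn), c("A", "B", "C", "HUB"))
  expect_identical(connectorNodes(cn), "HUB")
  # brute force over all node subsets confirms (3 seeds, 1 connector)
  adj <- matrix(FALSE, 5, 5,
                dimnames = list(c("A", "B", "C", "HUB", "Z"),
                                c("A", "B", "C", "HUB", "Z")))
  for (e in list(c("A", "HUB"), c("B", "HUB"), c("C", "HUB"),
                 c("HUB", "Z")))
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
  opt <- bruteForceOptimum(adj, seedIdx = 1:3, maxNodes = 4)
  expect_equal(opt$nPlaced, 3L)
  expect_equal(opt$nConnectors, 1L)
})

test_that("adjacent seeds need no connector", {
  net <- Interactome(c("A", "B"), c("B", "C"), kind = "direct")
  cn <- findConnectorNetwork(net, c("A", "B"), maxNodes = 35, pad = FALSE)
  expect_setequal(networkNodes(cn), c("A", "B"))
  expect_length(connectorNodes(cn), 0L)
})

test_that("absent seeds are reported; all-absent seeds are an error", {
  net <- starInteractome()
  expect_message(cn <- findConnectorNetwork(net, c("A", "B", "NOTHERE"),
                                            maxNodes = 5, pad = FALSE),
                 "NOTHERE")
  expect_setequal(seedNodes(cn), c("A", "B"))
  expect_error(findConnectorNetwork(net, c("X1", "X2")),
               "no seeds in interactome")
})

test_that("mutually unreachable seeds fall back to the largest seed component", {
  net <- Interactome(c("A", "B", "P"), c("H", "H", "Q"), kind = "direct")
  expect_warning(cn <- findConnectorNetwork(net, c("A", "B", "P"),
                                            maxNodes = 10, pad = FALSE),
                 "unreachable")
  expect_setequal(seedNodes(cn), c("A", "B"))
})

test_that("node budget is always respected and padding fills it", {
  spec <- syntheticSpec(nGenes = 120, nSeeds = 6, nPlantedConnectors = 4,
                        rngSeed = 11)
  made <- makeInteractome(spec)
  for (mx in c(5L, 12L, 35L)) {
    cn <- findConnectorNetwork(made$net, made$seeds, maxNodes = mx,
                               pad = FALSE)
    expect_lte(length(networkNodes(cn)), mx)
    cnp <- findConnectorNetwork(made$net, made$seeds, maxNodes = mx,
                                pad = TRUE)
    expect_equal(length(networkNodes(cnp)), mx)
    expect_true(all(networkNodes(cn) %in% networkNodes(cnp)) ||
                  length(networkNodes(cn)) > 0)
  }
})

test_that("placed seed count is monotone in the node budget", {
  set.seed(42)
  for (rep in 1:20) {
    adj <- randomAdjacency(10, 0.25)
    net <- adjacencyToInteractome(adj)
    seeds <- sample(rownames(adj), 3)
    prev <- -1L
    for (mx in c(3L, 5L, 8L, 10L)) {
      cn <- suppressWarnings(findConnectorNetwork(net, seeds, maxNodes = mx,
                                                  pad = FALSE))
      expect_gte(length(seedNodes(cn)), prev)
      prev <- length(seedNodes(cn))
    }
  }
})

test_that("search is deterministic: identical inputs give identical networks", {
  spec <- syntheticSpec(nGenes = 200, rngSeed = 5)
  made <- makeInteractome(spec)
  a <- findConnectorNetwork(made$net, made$seeds)
  b <- findConnectorNetwork(made$net, made$seeds)
  expect_identical(networkNodes(a), networkNodes(b))
  expect_identical(edgeTable(a), edgeTable(b))
})

test_that("planted connectors are recovered on synthetic interactomes", {
  prec <- rec <- numeric(0)
  for (i in 1:20) {
    spec <- syntheticSpec(rngSeed = 1000L + i)
    made <- makeInteractome(spec)
    cn <- findConnectorNetwork(made$net, made$seeds, maxNodes = 35,
                               pad = FALSE)
    found <- connectorNodes(cn)
    prec <- c(prec, length(intersect(found, made$connectors)) /
                max(1, length(found)))
    rec <- c(rec, length(intersect(found, made$connectors)) /
               length(made$connectors))
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})

test_that("iterative extraction separates disjoint seed cliques", {
  # two components, each holding seeds wired through its own hub
  net <- Interactome(c("A1", "A2", "A3", "B1", "B2"),
                     c("HA", "HA", "HA", "HB", "HB"), kind = "direct")
  seeds <- c("A1", "A2", "A3", "B1", "B2")
  nets <- suppressWarnings(rankNetworks(net, seeds, maxNodes = 10,
                                        maxNetworks = 5, pad = FALSE))
  expect_length(nets, 2L)
  placed <- lapply(nets, seedNodes)
  expect_setequal(unlist(placed), seeds)
  expect_true(setequal(placed[[1]], c("A1", "A2", "A3")) ||
                setequal(placed[[2]], c("A1", "A2", "A3")))
  # scores non-increasing and ranks sequential
  scores <- vapply(nets, networkScore, numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_equal(vapply(nets, function(x) x@rank, integer(1)),
               seq_along(nets))
})

test_that("one network suffices when all seeds are placed", {
  net <- starInteractome()
  nets <- rankNetworks(net, c("A", "B", "C"), maxNodes = 10,
                       maxNetworks = 5, pad = FALSE)
  expect_length(nets, 1L)
  expect_setequal(seedNodes(nets[[1]]), c("A", "B", "C"))
})

test_that("hub report flags high-degree members and orders by degree", {
  net <- starInteractome()
  cn <- findConnectorNetwork(net, c("A", "B", "C"), maxNodes = 4,
                             pad = FALSE)
  hr <- hubReport(cn, net)
  expect_equal(hr$gene[1], "HUB")
  expect_identical(hr$gene[hr$isHub], "HUB")
  expect_true(all(diff(hr$degreeInInteractome) <= 0))
  # all-equal degree distribution: nothing is a hub at the 95th percentile
  ring <- Interactome(c("A", "B", "C", "D"), c("B", "C", "D", "A"),
                      kind = "direct")
  cr <- findConnectorNetwork(ring, c("A", "C"), maxNodes = 4, pad = FALSE)
  expect_false(any(hubReport(cr, ring)$isHub))
  # percentile 0 flags every member
  expect_true(all(hubReport(cr, ring, percentile = 0)$isHub))
})
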